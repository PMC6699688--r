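---
title: "Line x tester analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line x tester analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linetester)
```

## The design and its model

A line x tester trial crosses `l` female lines with `t` male testers and
evaluates the `l + t` parents and `l * t` F1 hybrids (plus optional
commercial checks) in `r` complete replications. The plot model for a
cross is

$$y_{ijk} = \mu + g_i + g_j + s_{ij} + r_k + \varepsilon_{ijk},$$

where $g_i$, $g_j$ are the general combining abilities (GCA) of line $i$
and tester $j$, $s_{ij}$ is the specific combining ability (SCA) of the
cross, $r_k$ a block effect and $\varepsilon$ plot error. GCA reflects
additive gene action, SCA non-additive (dominance and epistatic) action.
Parents enter the same field layout; a parent's genotypic value is taken
as twice its GCA (both parent groups are effectively fully homozygous:
the female lines are backcross-stabilized male-sterile lines, the
testers doubled haploids), minus a uniform inbreeding depression in the
generator.

`lt_analysis()` is the single entry point: it runs the ANOVA, combining
ability, and variance-component chain per trait and returns a classed
object with the usual modelling methods.

## The ANOVA partition

The analysis is a randomized-complete-block ANOVA on the
`l + t + l*t` entries (checks are excluded), with the treatment sum of
squares partitioned into parents (itself into lines, testers, and the
1-df lines-vs-testers contrast), the 1-df parents-vs-crosses contrast
(the omnibus heterosis signal), and crosses (line effect, tester effect,
line x tester interaction). All sums of squares are computed from group
totals and the correction factor; error SS is obtained by subtraction
with $(l + t + lt - 1)(r - 1)$ df, and each mean square is tested
against the error mean square. For the 20 x 6 x 3 layout this gives the
familiar df column 2 / 145 / 25 / 19 / 5 / 1 / 1 / 119 / 19 / 5 / 95 /
290.

Field trials of this size are usually laid out as resolvable
incomplete-block (alpha lattice) designs. The package deliberately
analyses at the complete-block level and treats the incomplete block
label as informational only: the combining-ability formulas below are
balanced-data formulas, and the published df structure this package
reproduces is the RCBD one. Lattice adjustment is out of scope. For the
same reason the ANOVA refuses incomplete data rather than silently
switching to a different estimator class; missing plots are permitted at
I/O only.

## Combining ability and its uncertainty

With $\mu_c$ the grand mean of the cross cell means,
$g_i = \bar x_{i.} - \mu_c$, $g_j = \bar x_{.j} - \mu_c$ and
$s_{ij} = \bar x_{ij} - \bar x_{i.} - \bar x_{.j} + \mu_c$. These are
the least-squares estimates under the sum-to-zero parameterization; the
cell means are reconstructed exactly and the weighted effect sums of
squares reproduce the ANOVA partition ($rt\sum g_i^2 = SS_{line}$,
etc.), which the test suite asserts.

Standard errors of a single effect are $\sqrt{MSe/rt}$ (line GCA),
$\sqrt{MSe/rl}$ (tester GCA) and $\sqrt{MSe/r}$ (SCA). The critical
difference reported in the GCA tables is $t_{\alpha,df_e}$ times the
single-effect SE — this is the convention that reproduces the published
footer values (e.g. MSe 1.20, df 290 gives CD 0.51 for lines and 0.28
for testers); a `type = "difference"` flag provides the
$\sqrt2$-inflated comparison-of-two-effects CD for users who prefer it.
Effect significance uses two-sided t tests, since effects are signed and
the desirable direction is a trait-specific reporting concern, not part
of the statistic.

## Variance components

The default estimators subtract the **error** mean square:

$$\hat\sigma^2_{gca(line)} = \frac{MS_{line} - MS_e}{rt},\qquad
  \hat\sigma^2_{gca(tester)} = \frac{MS_{tester} - MS_e}{rl},\qquad
  \hat\sigma^2_{sca} = \frac{MS_{l\times t} - MS_e}{r}.$$

The textbook random-model expectation would subtract $MS_{l\times t}$
from the GCA mean squares instead; that form is available via
`form = "textbook"`. The error-subtraction form is the package default
because it is the estimator actually used in the reference analyses
this package reproduces, and it is unbiased whenever the realized SCA
effects are orthogonal to the line and tester margins — which is exactly
how the synthetic generator draws them (see below). The average GCA
variance weights each parent group by the number of crosses it enters,
$(t\,\hat\sigma^2_{line} + l\,\hat\sigma^2_{tester})/(l+t)$.

With both parent groups fully inbred ($F = 1$),
$\sigma^2_A = 2\,\sigma^2_{gca(avg)}$ and
$\sigma^2_D = \sigma^2_{sca}$. Derived parameters: degree of dominance
$\sqrt{\sigma^2_D/\sigma^2_A}$; narrow-sense heritability
$h^2_{ns} = \sigma^2_A / (\sigma^2_A + \sigma^2_D + MS_e/r)$ (the
denominator is the phenotypic variance of an entry mean, hence the
error term divided by $r$); genetic advance
$GA = h^2_{ns}\,\sqrt{V_P}\,K$ with $K = 2.06$, the standardized
selection differential at 5 % selection intensity; predictability ratio
$2\sigma^2_{gca}/(2\sigma^2_{gca}+\sigma^2_{sca})$. The GA formula uses
the narrow-sense fraction: the broad-sense variant circulates in the
literature under the same name, but only the narrow-sense form is
consistent with the published values this package validates against,
so `ga_heritability = "broad"` exists but is not the default.

Negative component estimates (possible whenever a mean square falls
below its subtrahend) are reported as computed; `clamp_negative = TRUE`
truncates at zero but is off by default, because silently clamping
biases means over simulations and hides estimation noise.

```{r}
d <- trial_design(paste0("L", 1:20), paste0("T", 1:6), 3)
vc <- estimate_variance_components(
  c(line = 1054.16, tester = 33.96, lxt = 85.61, error = 4.94), d)
print(vc)
```

## Heterosis

$MPH\% = 100\,(F_1 - MP)/MP$ with $MP = (P_1 + P_2)/2$, and
$BPH\% = 100\,(F_1 - BP)/BP$. The better parent is direction-aware: for
an earliness trait (desirable `-`) it is the *earlier* parent. The sign
of the percentages is never flipped by the direction — direction only
selects BP and orders the ranking. Significance uses t statistics with
$SE(F_1 - MP) = \sqrt{3MSe/2r}$ and $SE(F_1 - BP) = \sqrt{2MSe/r}$,
the variances of those contrasts of independent entry means; the
squared statistics are the equivalent 1-df F tests. Ranking keeps
significant crosses only and breaks ties by BPH, then cross label, so
output is deterministic.

## Marker diversity

Per locus: observed heterozygosity is the heterozygote fraction among
typed individuals; expected heterozygosity is $1 - \sum p_i^2$ (a
$2n/(2n-1)$ unbiased option exists); PIC defaults to Botstein's
$1 - \sum p_i^2 - \sum_{i<j} 2p_i^2p_j^2$. The simple form
$1 - \sum p_i^2$ is selectable, but cannot produce PIC < He, and
reference panels consistently show PIC strictly below He, so the
Botstein form is the default. Loci are classed highly informative
(PIC >= 0.5), reasonably informative (0.25-0.5) and slightly
informative (< 0.25).

The simple-matching dissimilarity of two individuals counts shared
alleles with multiplicity per locus (0, 1 or 2, divided by 2) and
averages over co-typed loci (pairwise deletion); it is a metric on
complete profiles. UPGMA trees come from average-linkage clustering;
bootstrap support resamples **loci** with replacement (the marker-tree
convention — individuals are the objects being clustered, loci the
replicated observations) and reports the fraction of replicate trees
containing each bipartition, with a mandatory seed. An unrooted
neighbour-joining tree is provided alongside, since both are customary
for SSR panels.

The Evanno summary takes externally produced model log-likelihoods
$L(K)$ (e.g. from a Bayesian admixture program, whose MCMC itself is
out of scope here), and computes
$\Delta K = |L''(K)|\,/\,\mathrm{sd}[L(K)]$ over interior $K$; the peak
locates the supported cluster number. A zero run-to-run standard
deviation at an interior $K$ is an error rather than an infinite
score.

## Distances and association with heterosis

Phenotypic distance is the Euclidean norm over **z-score standardized**
traits. Standardization is the package default for a reason one can
check analytically: for $p$ independent standardized traits the
expected distance between two random entries is about $\sqrt{2p}$
(5.66 at $p = 16$), the magnitude seen in practice for such panels,
whereas raw-scale distances are dominated by whichever trait is
measured in grams. Zero-variance traits are dropped with a warning.
PCA variance shares are eigenvalue shares of the trait correlation
matrix.

The association grid correlates per-cross parental genetic distance
(GD), phenotypic distance (PD) and SCA with per-cross MPH and BPH, one
trait at a time, aligned by cross identifier (never by position), with
pairwise deletion of crosses lacking a value and no multiple-testing
correction across the grid (matching how such tables are conventionally
presented). Pearson's $r$ is tested with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df.

## The synthetic generators

`simulate_trial()` draws GCA and SCA effects from zero-mean normals,
centres them to exact zero sums (SCA doubly, by rows and columns), and
rescales so the realized sum of squares over the effect degrees of
freedom equals the configured variance exactly. Centring alone would
leave the realized variance a noisy, slightly biased draw; the exact
rescaling makes the variance-component recovery experiments sharp and
unbiased, and it is also why the error-subtraction estimators above are
exactly right for generated data (the SCA margin sums are identically
zero). Parent plots get $\mu + 2g - \delta$ with $\delta$ an
inbreeding-depression offset that induces positive mid-parent heterosis
without an explicit locus model.

Generator defaults are fixed at the study scale: `l = 20`, `t = 6`,
`r = 3` and variance magnitudes of a days-to-maturity trait
(`var_gca_line = 58.29`, `var_gca_tester = 0.48`, `var_sca = 26.89`,
`var_error = 4.94`, replicate variance 0 — replicate mean squares of
that scale are null-level). The marker generator mirrors a 26-individual
panel at 87 loci carrying 2-10 alleles: per-locus base frequencies are
flat-Dirichlet, subpopulation frequencies are Dirichlet around the base
with a concentration knob for divergence, individuals are assigned to 4
subpopulations round-robin, and DH-flagged individuals (the last 6 by
default) get two copies of one sampled allele, so their heterozygosity
is exactly zero. The log-likelihood generator plants a piecewise-linear
elbow (default at K = 4, 15 runs for K = 1..10).

What the generators do **not** emulate: linkage between loci, map
positions, genuine admixture (assignment is hard, divergence
symmetric), spatial field trend, and trait-trait correlations.
Consequently, passing recovery tests show the estimators are correct
for the stated model, not that the model captures every feature of real
field or marker data.

## Numerical conventions and problem sizes

* Significance stars: `*`/`**`/`***`/`****` at p < 0.05 / 0.01 / 0.001 /
  0.0001 for ANOVA and combining ability; heterosis uses three levels
  (0.05 / 0.01 / 0.001). Codes switch strictly below the threshold, so
  an effect exactly at the critical difference is not starred.
* Constant data: all SS are zero and F statistics are reported absent
  rather than 0/0.
* Negative variance estimates propagate (dominance degree and
  heritability guard against non-positive additive variance with a
  warning/`NA`).
* Ties in rankings and in UPGMA merges are resolved deterministically
  (label order; `hclust`'s deterministic merge rule).
* The simulation-based test suite uses 500 recovery trials and 1000
  null trials at the 20 x 6 x 3 scale, 20 seeds for cluster recovery
  and 100 for elbow recovery — sizes chosen to keep Monte-Carlo error
  well below the asserted tolerances while the whole suite stays in the
  minutes range on a laptop.

## Known limitations

* Fixed-effects analysis only: no REML/BLUP shrinkage, no lattice
  recovery of inter-block information.
* Balanced data are required at the analysis stage by design.
* Variance components carry no standard errors or intervals.
* The Bayesian structure inference feeding the Evanno summary is
  external; only its log-likelihood output is consumed.
* Allele calls are compared as trimmed strings; fragment-size binning
  is a non-goal (panels are assumed pre-scored to discrete alleles).
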