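# draw n zero-centred effects whose sum of squares over (n - 1) equals
# `var` exactly; degenerate cases give zeros
centred_effects <- function(n, var) {
  if (var <= 0 || n < 2L) return(numeric(n))
  e <- stats::rnorm(n)
  e <- e - mean(e)
  ss <- sum(e^2)
  if (ss == 0) return(numeric(n))
  e * sqrt(var * (n - 1) / ss)
}

# l x t matrix with exact zero row/column sums and sum of squares over
# (l-1)(t-1) equal to `var`
centred_interaction <- function(l, t, var) {
  if (var <= 0) return(matrix(0, l, t))
  s <- matrix(stats::rnorm(l * t), l, t)
  s <- s - rowMeans(s)
  s <- sweep(s, 2, colMeans(s))
  ss <- sum(s^2)
  if (ss == 0) return(matrix(0, l, t))
  s * sqrt(var * (l - 1) * (t - 1) / ss)
}

#' Simulate a balanced line x tester trial
#'
#' Generates plot records for a complete `l x t x r` trial under the
#' additive/non-additive decomposition: a cross plot is
#' `mu + g_i + g_j + s_ij + rep_k + e`, and a parent plot is
#' `mu + 2 g - inbreeding_effect + rep_k + e` (the homozygous-parent
#' additive value minus a uniform inbreeding depression, which induces
#' positive mid-parent heterosis without modelling loci). GCA, SCA and
#' replicate effects are drawn normal, centred to exact zero sums, and
#' rescaled so their realized variance (sum of squares over effect
#' degrees of freedom) equals the configured component exactly, making
#' variance-component recovery unbiased. Defaults mirror a 20-line x
#' 6-tester, 3-replicate curd-maturity trial (GCA line variance 58.29,
#' tester 0.48, SCA 26.89, plot error 4.94, negligible replicate
#' variance).
#'
#' @param l,t,r Numbers of lines, testers and replications.
#' @param mu Overall mean.
#' @param var_gca_line,var_gca_tester,var_sca Genetic variance components.
#' @param var_rep,var_error Replicate and plot-error variances.
#' @param inbreeding_effect Depression subtracted from parent per se means.
#' @param n_checks Number of check entries to append (excluded from the
#'   line x tester analysis but carried through I/O).
#' @param trait Name of the simulated trait column.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A list with `design` ([trial_design()]), `records` (plot
#'   data.frame in the [read_phenotypes()] layout) and `truth` (drawn
#'   effects and the configuration).
#' @examples
#' sim <- simulate_trial(l = 4, t = 3, r = 2, seed = 42)
#' head(sim$records)
#' @export
simulate_trial <- function(l = 20, t = 6, r = 3, mu = 100,
                           var_gca_line = 58.29, var_gca_tester = 0.48,
                           var_sca = 26.89, var_rep = 0,
                           var_error = 4.94, inbreeding_effect = 0,
                           n_checks = 0, trait = "y", seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(l >= 2, t >= 2, r >= 2,
            var_gca_line >= 0, var_gca_tester >= 0, var_sca >= 0,
            var_rep >= 0, var_error >= 0, n_checks >= 0)
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(l))
  testers <- sprintf("T%d", seq_len(t))
  checks <- if (n_checks > 0) sprintf("CHK%d", seq_len(n_checks))
            else character()
  design <- trial_design(lines, testers, r, checks)

  g_l <- stats::setNames(centred_effects(l, var_gca_line), lines)
  g_t <- stats::setNames(centred_effects(t, var_gca_tester), testers)
  sca <- centred_interaction(l, t, var_sca)
  dimnames(sca) <- list(lines, testers)
  rep_eff <- centred_effects(r, var_rep)
  chk_eff <- if (n_checks > 0)
    stats::rnorm(n_checks, 0, sqrt(var_gca_line + var_sca)) else numeric()

  rows <- list()
  push <- function(entry, role, line, tester, genetic) {
    rows[[length(rows) + 1L]] <<- data.frame(
      entry = entry, role = role, line = line, tester = tester,
      rep = seq_len(r), block = 1L,
      y = mu + genetic + rep_eff +
        stats::rnorm(r, 0, sqrt(var_error)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(l))
    push(lines[i], "line_parent", lines[i], "",
         2 * g_l[i] - inbreeding_effect)
  for (j in seq_len(t))
    push(testers[j], "tester_parent", "", testers[j],
         2 * g_t[j] - inbreeding_effect)
  for (i in seq_len(l)) for (j in seq_len(t))
    push(paste0(lines[i], "x", testers[j]), "cross", lines[i], testers[j],
         g_l[i] + g_t[j] + sca[i, j])
  for (c in seq_along(checks))
    push(checks[c], "check", "", "", chk_eff[c])
  records <- do.call(rbind, rows)
  names(records)[names(records) == "y"] <- trait
  rownames(records) <- NULL
  truth <- list(mu = mu, gca_lines = g_l, gca_testers = g_t, sca = sca,
                rep_effects = rep_eff, check_effects = chk_eff,
                var_gca_line = var_gca_line,
                var_gca_tester = var_gca_tester,
                var_gca_avg = (t * var_gca_line + l * var_gca_tester) /
                  (l + t),
                var_sca = var_sca, var_rep = var_rep,
                var_error = var_error,
                inbreeding_effect = inbreeding_effect, seed = seed)
  list(design = design, records = records, truth = truth)
}

# Dirichlet draw via independent gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a structured codominant marker panel
#'
#' Generates an SSR-style diploid panel with population structure: each
#' locus gets base allele frequencies from a flat Dirichlet, each
#' subpopulation perturbs them by a Dirichlet draw with concentration
#' `differentiation * base` (smaller values = stronger divergence), and
#' individuals are assigned to subpopulations in round-robin order.
#' Individuals flagged as doubled haploids receive two copies of a single
#' sampled allele at every locus, so their heterozygosity is exactly
#' zero. Calls are masked at `missing_rate`. Defaults mirror a 26-line
#' panel (20 partially inbred female lines plus 6 DH testers) scored at
#' 87 loci carrying 2-10 alleles in 4 subpopulations.
#'
#' @param n_individuals,n_loci Panel dimensions.
#' @param alleles_per_locus Length-2 integer range of allele counts.
#' @param n_subpops Number of subpopulations.
#' @param differentiation Dirichlet concentration scaling; smaller =
#'   more divergence among subpopulations.
#' @param dh_flags Logical vector (length `n_individuals`) marking fully
#'   homozygous doubled-haploid individuals; default: the last 6 of 26,
#'   or all FALSE otherwise.
#' @param missing_rate Fraction of calls masked as missing.
#' @param seed Integer seed (mandatory).
#' @return A list with `genotypes` (a `"genotype_matrix"`) and `truth`
#'   (subpopulation assignments, per-subpop allele frequencies, config).
#' @export
simulate_markers <- function(n_individuals = 26, n_loci = 87,
                             alleles_per_locus = c(2, 10),
                             n_subpops = 4, differentiation = 5,
                             dh_flags = NULL, missing_rate = 0.02,
                             seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_individuals >= 2, n_loci >= 1, n_subpops >= 1,
            missing_rate >= 0, missing_rate <= 1,
            alleles_per_locus[1] >= 2, differentiation > 0)
  if (is.null(dh_flags))
    dh_flags <- if (n_individuals == 26)
      rep(c(FALSE, TRUE), c(20, 6)) else rep(FALSE, n_individuals)
  stopifnot(length(dh_flags) == n_individuals)
  set.seed(seed)
  ids <- ifelse(dh_flags,
                sprintf("DH%02d", cumsum(dh_flags)),
                sprintf("I%02d", cumsum(!dh_flags)))
  loci <- sprintf("M%03d", seq_len(n_loci))
  subpop <- rep_len(seq_len(n_subpops), n_individuals)
  a1 <- a2 <- matrix(NA_character_, n_individuals, n_loci,
                     dimnames = list(ids, loci))
  freqs <- vector("list", n_loci)
  for (jl in seq_len(n_loci)) {
    k <- sample(seq(alleles_per_locus[1], alleles_per_locus[2]), 1)
    base <- rdirichlet1(rep(1, k))
    pf <- lapply(seq_len(n_subpops), function(s)
      rdirichlet1(differentiation * k * base))
    freqs[[jl]] <- pf
    for (ind in seq_len(n_individuals)) {
      p <- pf[[subpop[ind]]]
      if (dh_flags[ind]) {
        a <- sample.int(k, 1, prob = p)
        a1[ind, jl] <- a2[ind, jl] <- paste0("a", a)
      } else {
        ab <- sample.int(k, 2, replace = TRUE, prob = p)
        a1[ind, jl] <- paste0("a", ab[1])
        a2[ind, jl] <- paste0("a", ab[2])
      }
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_individuals * n_loci) < missing_rate,
                   n_individuals, n_loci)
    a1[mask] <- NA_character_; a2[mask] <- NA_character_
  }
  gm <- structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
                  class = "genotype_matrix")
  list(genotypes = gm,
       truth = list(subpop = stats::setNames(subpop, ids),
                    frequencies = freqs, dh_flags = dh_flags,
                    missing_rate = missing_rate, seed = seed))
}

#' Simulate a structure log-likelihood profile
#'
#' Replicate log-likelihoods over K = 1..`k_max` with a piecewise-linear
#' mean that changes slope at `elbow_k` (steep gain up to the elbow,
#' shallow gain after) plus independent run noise; the classic input for
#' [evanno_delta_k()]. Defaults mirror a 10-K, 15-runs-per-K scan with an
#' elbow at K = 4.
#'
#' @param k_max Largest K (at least `elbow_k + 1`).
#' @param n_runs Replicate runs per K (at least 2).
#' @param elbow_k True number of clusters (slope change point).
#' @param base Mean log-likelihood at K = 1.
#' @param slope_before,slope_after Mean gain per K below/above the elbow.
#' @param noise_sd Run-to-run standard deviation.
#' @param seed Integer seed (mandatory).
#' @return Named list (names = K) of run log-likelihood vectors.
#' @export
simulate_loglik_profile <- function(k_max = 10, n_runs = 15, elbow_k = 4,
                                    base = -5000, slope_before = 50,
                                    slope_after = 5, noise_sd = 2,
                                    seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(elbow_k >= 2, elbow_k < k_max, n_runs >= 2)
  set.seed(seed)
  ks <- seq_len(k_max)
  mu <- base + slope_before * (pmin(ks, elbow_k) - 1) +
    slope_after * pmax(ks - elbow_k, 0)
  stats::setNames(lapply(seq_along(ks), function(i)
    mu[i] + stats::rnorm(n_runs, 0, noise_sd)), ks)
}
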