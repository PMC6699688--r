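ms_from_anova <- function(anova) {
  if (inherits(anova, "lt_anova") || is.data.frame(anova)) {
    need <- c("Line Effect", "Tester Effect", "Line x Tester Eff.", "Error")
    i <- match(need, anova$source)
    if (anyNA(i))
      stop("ANOVA table lacks row(s): ",
           paste(need[is.na(i)], collapse = ", "))
    list(line = anova$MS[i[1]], tester = anova$MS[i[2]],
         lxt = anova$MS[i[3]], error = anova$MS[i[4]])
  } else {
    need <- c("line", "tester", "lxt", "error")
    if (!all(need %in% names(anova)))
      stop("mean squares must be named line, tester, lxt, error")
    as.list(anova)[need]
  }
}

#' Genetic variance components from a line x tester ANOVA
#'
#' Estimates the GCA and SCA variance components from the cross partition
#' mean squares. The default (`form = "paper"`) estimators subtract the
#' error mean square:
#' \deqn{\sigma^2_{gca(line)} = (MS_{line} - MS_{error})/(r t), \quad
#'       \sigma^2_{gca(tester)} = (MS_{tester} - MS_{error})/(r l), \quad
#'       \sigma^2_{sca} = (MS_{lxt} - MS_{error})/r}
#' with the average GCA variance weighted by the number of crosses each
#' parent enters: \eqn{(t \sigma^2_{line} + l \sigma^2_{tester})/(l + t)}.
#' `form = "textbook"` subtracts the interaction mean square from the two
#' GCA mean squares instead. Under the F = 1 parent convention the additive
#' variance is \eqn{\sigma^2_A = 2 \sigma^2_{gca(avg)}} and the dominance
#' variance is \eqn{\sigma^2_D = \sigma^2_{sca}}. Negative estimates are
#' reported as computed unless `clamp_negative = TRUE`.
#'
#' @param anova An [lt_anova()] table, or a named list/vector with elements
#'   `line`, `tester`, `lxt`, `error` (mean squares).
#' @param design A [trial_design()] (only `l`, `t`, `r` are used).
#' @param form `"paper"` (default) or `"textbook"`.
#' @param clamp_negative Truncate negative component estimates at zero.
#' @return An object of class `"variance_components"`: list with
#'   `s2_gca_line`, `s2_gca_tester`, `s2_gca_avg`, `s2_sca`, `s2_A`,
#'   `s2_D`, `ratio_AD`, `env_var` (`MS_error / r`), `ms` and `design`.
#' @examples
#' d <- trial_design(paste0("L", 1:20), paste0("T", 1:6), 3)
#' estimate_variance_components(
#'   c(line = 1054.16, tester = 33.96, lxt = 85.61, error = 4.94), d)
#' @export
estimate_variance_components <- function(anova, design,
                                         form = c("paper", "textbook"),
                                         clamp_negative = FALSE) {
  form <- match.arg(form)
  ms <- ms_from_anova(anova)
  l <- design$l; t <- design$t; r <- design$r
  sub <- if (form == "paper") ms$error else ms$lxt
  s2_line <- (ms$line - sub) / (r * t)
  s2_tester <- (ms$tester - sub) / (r * l)
  s2_sca <- (ms$lxt - ms$error) / r
  if (clamp_negative) {
    s2_line <- max(0, s2_line); s2_tester <- max(0, s2_tester)
    s2_sca <- max(0, s2_sca)
  }
  s2_avg <- (t * s2_line + l * s2_tester) / (l + t)
  s2_A <- 2 * s2_avg
  s2_D <- s2_sca
  structure(list(
    s2_gca_line = s2_line, s2_gca_tester = s2_tester, s2_gca_avg = s2_avg,
    s2_sca = s2_sca, s2_A = s2_A, s2_D = s2_D,
    ratio_AD = if (s2_D != 0) s2_A / s2_D else NA_real_,
    env_var = ms$error / r, ms = ms, design = design, form = form),
    class = "variance_components")
}

#' Average degree of dominance
#'
#' `sqrt(s2_D / s2_A)`; values above 1 indicate overdominance-scale
#' non-additivity, values below 1 partial dominance. Returns `NA` with a
#' warning when the additive variance estimate is not positive.
#'
#' @param vc A `"variance_components"` object.
#' @return Nonnegative scalar, or `NA`.
#' @export
degree_of_dominance <- function(vc) {
  if (!is.finite(vc$s2_A) || vc$s2_A <= 0) {
    warning("additive variance estimate is not positive; degree of dominance undefined")
    return(NA_real_)
  }
  if (vc$s2_D < 0) {
    warning("negative dominance variance estimate; degree of dominance undefined")
    return(NA_real_)
  }
  sqrt(vc$s2_D / vc$s2_A)
}

#' Narrow-sense heritability and genetic advance
#'
#' Heritability (percent) is `100 s2_A / V_P` with phenotypic variance
#' `V_P = s2_A + s2_D + MS_error / r`. Genetic advance under truncation
#' selection is `h2 * sqrt(V_P) * K` with `h2` the heritability fraction
#' and `K` the standardized selection differential (2.06 at 5% selection
#' intensity). `ga_heritability = "broad"` uses
#' `(s2_A + s2_D) / V_P` in the advance formula instead. Heritability is
#' classed high (> 30%), medium (10-30%) or low (< 10%).
#'
#' @param vc A `"variance_components"` object.
#' @param selection_k Selection differential constant (default 2.06).
#' @param ga_heritability `"narrow"` (default) or `"broad"`.
#' @return List with `h2_narrow_pct`, `genetic_advance`, `V_P`, `class`.
#' @export
heritability_and_ga <- function(vc, selection_k = 2.06,
                                ga_heritability = c("narrow", "broad")) {
  ga_heritability <- match.arg(ga_heritability)
  vp <- vc$s2_A + vc$s2_D + vc$env_var
  if (!is.finite(vp) || vp <= 0) stop("non-positive phenotypic variance")
  h2 <- 100 * vc$s2_A / vp
  h2_ga <- if (ga_heritability == "narrow") h2 / 100
           else (vc$s2_A + vc$s2_D) / vp
  ga <- h2_ga * sqrt(vp) * selection_k
  cls <- if (h2 > 30) "high" else if (h2 >= 10) "medium" else "low"
  list(h2_narrow_pct = h2, genetic_advance = ga, V_P = vp, class = cls)
}

#' Predictability ratio
#'
#' `2 s2_gca_avg / (2 s2_gca_avg + s2_sca)`; near 1 indicates additive,
#' GCA-predictable genetic control, near 0 non-additive control.
#'
#' @param vc A `"variance_components"` object.
#' @return Scalar ratio.
#' @export
predictability_ratio <- function(vc) {
  den <- 2 * vc$s2_gca_avg + vc$s2_sca
  if (!is.finite(den) || den == 0) stop("zero denominator")
  2 * vc$s2_gca_avg / den
}

#' @export
print.variance_components <- function(x, digits = 2, ...) {
  hg <- tryCatch(heritability_and_ga(x), error = function(e) NULL)
  cat("Genetic variance components (", x$form, " form)\n", sep = "")
  v <- c("s2_gca(line)" = x$s2_gca_line, "s2_gca(tester)" = x$s2_gca_tester,
         "s2_gca(avg)" = x$s2_gca_avg, "s2_sca" = x$s2_sca,
         "s2_A" = x$s2_A, "s2_D" = x$s2_D, "s2_A/D" = x$ratio_AD,
         "degree of dominance" = suppressWarnings(degree_of_dominance(x)),
         "predictability ratio" = tryCatch(predictability_ratio(x),
                                           error = function(e) NA))
  if (!is.null(hg))
    v <- c(v, "h2 narrow (%)" = hg$h2_narrow_pct,
           "genetic advance (5%)" = hg$genetic_advance)
  print(round(v, digits))
  invisible(x)
}
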