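#' Mid-parent and better-parent heterosis
#'
#' For each cross, mid-parent heterosis is
#' `MPH% = 100 (F1 - MP) / MP` with `MP = (P1 + P2) / 2`, and
#' better-parent heterosis is `BPH% = 100 (F1 - BP) / BP` where `BP` is the
#' per se mean of the parent further in the desirable direction (the larger
#' parent for `direction = "+"` traits, the smaller for `"-"` traits such
#' as earliness). The sign convention of the percentages is unchanged by
#' the direction; direction only selects the better parent and drives
#' ranking. Crosses with a zero mid- or better-parent mean are flagged and
#' get `NA` percentages.
#'
#' `heterosis()` is generic: the default method takes explicit means, and
#' a method for fitted [lt_analysis()] objects extracts the cross and
#' parent means of a trait from the fit.
#'
#' @param x For the default method, a data.frame of cross means with
#'   columns `line`, `tester`, `mean` (an [entry_means()] subset works).
#' @param parent_means Named numeric vector of parental per se means,
#'   indexed by parent identifier.
#' @param direction `"+"` or `"-"`: desirable direction of the trait.
#' @param ... Passed between methods.
#' @return An object of class `"heterosis_table"`: data.frame with columns
#'   `cross`, `line`, `tester`, `F1`, `MP`, `BP`, `MPH`, `BPH`, and
#'   attribute `direction`.
#' @examples
#' cm <- data.frame(line = "L1", tester = "T1", mean = 15)
#' heterosis(cm, c(L1 = 10, T1 = 14), direction = "+")
#' @export
heterosis <- function(x, ...) UseMethod("heterosis")

#' @rdname heterosis
#' @export
heterosis.default <- function(x, parent_means, direction = "+", ...) {
  stopifnot(direction %in% c("+", "-"))
  if (is.matrix(x))
    x <- data.frame(line = rownames(x)[row(x)],
                    tester = colnames(x)[col(x)], mean = as.vector(x),
                    stringsAsFactors = FALSE)
  if (!all(c("line", "tester", "mean") %in% names(x)))
    stop("cross means need columns line, tester, mean")
  miss <- setdiff(unique(c(x$line, x$tester)), names(parent_means))
  if (length(miss))
    stop("no parental mean for: ", paste(miss, collapse = ", "))
  p1 <- parent_means[x$line]
  p2 <- parent_means[x$tester]
  mp <- (p1 + p2) / 2
  bp <- if (direction == "+") pmax(p1, p2) else pmin(p1, p2)
  bad <- mp == 0 | bp == 0
  if (any(bad))
    warning(sum(bad), " cross(es) with zero mid- or better-parent mean; no heterosis value emitted")
  out <- data.frame(
    cross = paste(x$line, x$tester, sep = "x"),
    line = x$line, tester = x$tester, F1 = x$mean,
    MP = unname(mp), BP = unname(bp),
    MPH = ifelse(bad, NA, 100 * (x$mean - mp) / mp),
    BPH = ifelse(bad, NA, 100 * (x$mean - bp) / bp),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("heterosis_table", "data.frame"),
            direction = direction)
}

#' Significance of heterosis estimates
#'
#' Student-t type statistics on entry means over `r` replicates:
#' `(F1 - MP) / sqrt(3 MSe / (2 r))` for mid-parent and
#' `(F1 - BP) / sqrt(2 MSe / r)` for better-parent heterosis, referred to
#' the error degrees of freedom of the trial ANOVA, two-sided, with star
#' codes at the 5, 1 and 0.1 percent levels.
#'
#' @param het A `"heterosis_table"` (or vectors via `F1`, `MP`, `BP`).
#' @param mse Error mean square from the ANOVA (positive).
#' @param r Number of replications (at least 2).
#' @param df_error Error degrees of freedom.
#' @return `het` with added columns `t_MPH`, `t_BPH`, `p_MPH`, `p_BPH`,
#'   `sig_MPH`, `sig_BPH`.
#' @export
heterosis_significance <- function(het, mse, r, df_error) {
  if (!is.finite(mse) || mse <= 0) stop("mse must be positive")
  if (r < 2) stop("r must be at least 2")
  se_mp <- sqrt(3 * mse / (2 * r))
  se_bp <- sqrt(2 * mse / r)
  het$t_MPH <- (het$F1 - het$MP) / se_mp
  het$t_BPH <- (het$F1 - het$BP) / se_bp
  het$p_MPH <- 2 * stats::pt(abs(het$t_MPH), df_error, lower.tail = FALSE)
  het$p_BPH <- 2 * stats::pt(abs(het$t_BPH), df_error, lower.tail = FALSE)
  het$sig_MPH <- sig_codes(het$p_MPH, c(0.05, 0.01, 0.001))
  het$sig_BPH <- sig_codes(het$p_BPH, c(0.05, 0.01, 0.001))
  het
}

#' Top heterotic crosses
#'
#' Ranks the significant crosses by mid-parent heterosis in the desirable
#' direction (most negative first for `"-"` traits) and returns the top
#' `k`. Ties are broken by better-parent heterosis in the same direction,
#' then by cross label, so the ordering is deterministic.
#'
#' @param het A `"heterosis_table"` after [heterosis_significance()].
#' @param k Number of crosses to return (at most the number of crosses).
#' @param direction Desirable direction; defaults to the table's own.
#' @return The top-`k` rows of `het`, ranked; possibly fewer (or none) if
#'   fewer crosses are significant.
#' @export
rank_heterotic <- function(het, k = 10,
                           direction = attr(het, "direction")) {
  if (is.null(direction)) direction <- "+"
  if (k > nrow(het)) stop("k exceeds the number of crosses")
  if (is.null(het$sig_MPH))
    stop("run heterosis_significance() before ranking")
  keep <- het$sig_MPH != "" & !is.na(het$MPH)
  if (direction == "+") keep <- keep & het$MPH > 0
  else keep <- keep & het$MPH < 0
  sub <- het[keep, , drop = FALSE]
  if (nrow(sub) == 0L) return(sub)
  s <- if (direction == "+") -1 else 1
  ord <- order(s * sub$MPH, s * sub$BPH, sub$cross)
  utils::head(sub[ord, , drop = FALSE], k)
}
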