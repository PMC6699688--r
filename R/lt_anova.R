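#' Significance codes from a p-value
#'
#' Star codes at the 5, 1, 0.1 and 0.01 percent levels:
#' `""` (p >= 0.05), `*`, `**`, `***`, `****`.
#' @param p Vector of p-values.
#' @param levels Thresholds, from loosest to tightest.
#' @return Character vector of codes.
#' @export
sig_codes <- function(p, levels = c(0.05, 0.01, 0.001, 0.0001)) {
  out <- character(length(p))
  for (i in seq_along(levels))
    out[!is.na(p) & p < levels[i]] <- strrep("*", i)
  out[is.na(p)] <- ""
  out
}

#' Upper-tail F test with significance code
#'
#' @param f Variance ratio (MS / MS_error).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return List with `p` (upper-tail probability) and `sig` code.
#' @export
f_significance <- function(f, df1, df2) {
  if (any(!is.finite(f))) stop("non-finite F statistic")
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(p = p, sig = sig_codes(p))
}

# SS of a set of entry totals around their own group mean, on a per-plot
# basis: sum(T^2)/r - (sum T)^2 / (n r)
group_ss <- function(totals, r) {
  sum(totals^2) / r - sum(totals)^2 / (length(totals) * r)
}

#' Balanced line x tester analysis of variance
#'
#' Randomized-complete-block ANOVA of the `l + t` parents and `l * t`
#' crosses over `r` replications, with the classical partition of the
#' treatment sum of squares: parents (itself split into lines, testers and
#' the 1-df lines-vs-testers contrast), the 1-df parents-vs-crosses
#' contrast, and crosses (split into line effect, tester effect and the
#' line x tester interaction). Error SS is obtained by subtraction with
#' `(l + t + lt - 1)(r - 1)` degrees of freedom; every mean square is
#' tested against the error mean square with an upper-tail F test. Check
#' entries, if present, are excluded. The data must be complete and
#' balanced.
#'
#' @param records Plot-record data.frame (or an `"lt_trial"`).
#' @param design A [trial_design()]; taken from the trial if omitted.
#' @param trait Trait column name.
#' @return An object of class `"lt_anova"`: a data.frame with columns
#'   `source`, `df`, `SS`, `MS`, `F`, `p`, `sig` in the standard row order
#'   (Replicates, Treatments, Parents, Parents (Line), Parents (Testers),
#'   Parents (L vs T), Parents vs Crosses, Crosses, Line Effect,
#'   Tester Effect, Line x Tester Eff., Error, Total), with attributes
#'   `error_ms`, `error_df`, `design`, `trait`.
#' @examples
#' sim <- simulate_trial(l = 3, t = 2, r = 2, seed = 1)
#' lt_anova(sim$records, sim$design, "y")
#' @export
lt_anova <- function(records, design = NULL, trait = "y") {
  if (inherits(records, "lt_trial")) {
    if (is.null(design)) design <- records$design
    records <- records$records
  }
  if (is.null(design)) stop("a trial design is required")
  l <- design$l; t <- design$t; r <- design$r
  if (r < 2L) stop("at least 2 replications are required for an error term")
  rec <- records[records$role != "check", , drop = FALSE]
  y <- rec[[trait]]
  if (is.null(y)) stop("trait '", trait, "' absent from records")
  if (anyNA(y)) stop("missing plot values: the balanced analysis requires complete data")

  id <- ifelse(rec$role == "cross", paste(rec$line, rec$tester, sep = "x"),
               rec$entry)
  entries <- c(design$lines, design$testers,
               as.vector(outer(design$lines, design$testers, paste,
                               sep = "x")))
  tab <- table(factor(id, levels = entries), factor(rec$rep))
  if (nrow(rec) != length(entries) * r || any(tab != 1L))
    stop("unbalanced data: every parent and cross must appear exactly once per replicate")

  n_ent <- length(entries)
  N <- n_ent * r
  cf <- sum(y)^2 / N
  ss_total <- sum(y^2) - cf
  rep_tot <- tapply(y, rec$rep, sum)
  ss_rep <- sum(rep_tot^2) / n_ent - cf
  ent_tot <- tapply(y, factor(id, levels = entries), sum)
  ss_trt <- sum(ent_tot^2) / r - cf
  ss_err <- ss_total - ss_rep - ss_trt

  par_tot <- ent_tot[c(design$lines, design$testers)]
  line_tot <- ent_tot[design$lines]
  tst_tot <- ent_tot[design$testers]
  cross_tot <- matrix(ent_tot[-seq_len(l + t)], l, t,
                      dimnames = list(design$lines, design$testers))

  ss_par <- group_ss(par_tot, r)
  ss_cross <- group_ss(as.vector(cross_tot), r)
  ss_pvc <- ss_trt - ss_par - ss_cross
  ss_line_p <- group_ss(line_tot, r)
  ss_tst_p <- group_ss(tst_tot, r)
  ss_lvt <- ss_par - ss_line_p - ss_tst_p
  ss_line_c <- group_ss(rowSums(cross_tot), r * t)
  ss_tst_c <- group_ss(colSums(cross_tot), r * l)
  ss_lxt <- ss_cross - ss_line_c - ss_tst_c

  src <- c("Replicates", "Treatments", "Parents", "Parents (Line)",
           "Parents (Testers)", "Parents (L vs T)", "Parents vs Crosses",
           "Crosses", "Line Effect", "Tester Effect", "Line x Tester Eff.",
           "Error", "Total")
  df <- c(r - 1L, n_ent - 1L, l + t - 1L, l - 1L, t - 1L, 1L, 1L,
          l * t - 1L, l - 1L, t - 1L, (l - 1L) * (t - 1L),
          (n_ent - 1L) * (r - 1L), N - 1L)
  ss <- c(ss_rep, ss_trt, ss_par, ss_line_p, ss_tst_p, ss_lvt, ss_pvc,
          ss_cross, ss_line_c, ss_tst_c, ss_lxt, ss_err, ss_total)
  ms <- ss / df
  ms_err <- ms[12]
  fval <- ms / ms_err
  fval[c(12, 13)] <- NA
  if (!is.finite(ms_err) || ms_err <= 0) fval[] <- NA
  p <- ifelse(is.na(fval), NA,
              stats::pf(fval, df, df[12], lower.tail = FALSE))
  out <- data.frame(source = src, df = df, SS = ss, MS = ms, F = fval,
                    p = p, sig = sig_codes(p), stringsAsFactors = FALSE)
  structure(out, class = c("lt_anova", "data.frame"),
            error_ms = ms_err, error_df = df[12], design = design,
            trait = trait)
}

#' @export
print.lt_anova <- function(x, digits = 2, ...) {
  cat("Line x tester ANOVA", if (!is.null(attr(x, "trait")))
    paste0(" for trait ", attr(x, "trait")), "\n", sep = "")
  df <- as.data.frame(x)
  df$SS <- round(df$SS, digits); df$MS <- round(df$MS, digits)
  df$F <- round(df$F, digits); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as TSV
#'
#' @param anova An `"lt_anova"` table (or a list of them, one per trait).
#' @param path Output path.
#' @export
write_anova <- function(anova, path) {
  if (inherits(anova, "lt_anova")) anova <- list(anova)
  wide <- NULL
  for (a in anova) {
    d <- as.data.frame(a)[, c("source", "df", "MS", "sig")]
    tr <- attr(a, "trait")
    names(d)[3:4] <- c(paste0("MS_", tr), paste0("sig_", tr))
    wide <- if (is.null(wide)) d else cbind(wide, d[3:4])
  }
  utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
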