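cross_mean_matrix <- function(means, design) {
  if (is.matrix(means)) {
    m <- means
    if (is.null(rownames(m))) rownames(m) <- design$lines
    if (is.null(colnames(m))) colnames(m) <- design$testers
  } else {
    cm <- means[means$role == "cross", , drop = FALSE]
    m <- matrix(NA_real_, design$l, design$t,
                dimnames = list(design$lines, design$testers))
    m[cbind(match(cm$line, design$lines),
            match(cm$tester, design$testers))] <- cm$mean
  }
  if (anyNA(m))
    stop("missing cell(s) in the line x tester grid of cross means")
  m[design$lines, design$testers, drop = FALSE]
}

#' General and specific combining ability effects
#'
#' From the complete `l x t` grid of cross means, with grand mean `mu`:
#' the GCA of line i is its mean over testers minus `mu`, the GCA of tester
#' j is its mean over lines minus `mu`, and the SCA of cross (i, j) is the
#' cell mean minus both GCAs and `mu`. GCA vectors sum to zero and every
#' row and column of the SCA matrix sums to zero; the cell means are
#' reconstructed exactly as `mu + g_i + g_j + s_ij`.
#'
#' @param means Either an `l x t` numeric matrix of cross means (rows =
#'   lines, columns = testers) or an [entry_means()] data.frame containing
#'   the crosses.
#' @param design A [trial_design()].
#' @param trait Optional trait label carried in the result.
#' @return An object of class `"combining_ability"`: list with
#'   `grand_mean`, `gca_lines`, `gca_testers` (named vectors), `sca`
#'   (matrix), `trait`.
#' @examples
#' d <- trial_design(c("L1", "L2"), c("T1", "T2"), 2)
#' m <- matrix(c(10, 16, 14, 20), 2, 2)
#' estimate_gca_sca(m, d)
#' @export
estimate_gca_sca <- function(means, design, trait = NULL) {
  m <- cross_mean_matrix(means, design)
  mu <- mean(m)
  g_l <- rowMeans(m) - mu
  g_t <- colMeans(m) - mu
  sca <- sweep(sweep(m, 1, g_l + mu), 2, g_t)
  structure(list(grand_mean = mu, gca_lines = g_l, gca_testers = g_t,
                 sca = sca, trait = trait),
            class = "combining_ability")
}

#' @export
print.combining_ability <- function(x, digits = 3, ...) {
  cat("Combining ability", if (!is.null(x$trait)) paste0(" (", x$trait, ")"),
      ": grand mean ", round(x$grand_mean, digits), "\n", sep = "")
  cat("GCA lines:\n"); print(round(x$gca_lines, digits))
  cat("GCA testers:\n"); print(round(x$gca_testers, digits))
  cat("SCA matrix (", nrow(x$sca), " x ", ncol(x$sca), ")\n", sep = "")
  invisible(x)
}

#' Standard errors and critical differences for combining ability
#'
#' With error mean square `mse` from the trial ANOVA, the standard errors
#' of a single effect are `sqrt(mse / (r t))` for a line GCA,
#' `sqrt(mse / (r l))` for a tester GCA and `sqrt(mse / r)` for an SCA.
#' The critical difference at level `alpha` is the two-sided Student-t
#' quantile on the error degrees of freedom times the standard error.
#' `type = "difference"` instead uses the SE of a difference between two
#' effects (`sqrt(2)` times larger).
#'
#' @param mse Error mean square (positive).
#' @param design A [trial_design()].
#' @param alpha Significance level (default 0.05).
#' @param df_error Error degrees of freedom; default
#'   `(l + t + lt - 1) (r - 1)`.
#' @param type `"single"` (default) or `"difference"`.
#' @return List with `se_gca_line`, `se_gca_tester`, `se_sca`,
#'   `cd_gca_line`, `cd_gca_tester`, `cd_sca`, `t_crit`, `df_error`.
#' @export
critical_differences <- function(mse, design, alpha = 0.05,
                                 df_error = NULL,
                                 type = c("single", "difference")) {
  type <- match.arg(type)
  if (!is.finite(mse) || mse <= 0) stop("mse must be positive")
  l <- design$l; t <- design$t; r <- design$r
  if (is.null(df_error)) df_error <- (l + t + l * t - 1L) * (r - 1L)
  k <- if (type == "difference") sqrt(2) else 1
  se <- c(gca_line = sqrt(mse / (r * t)), gca_tester = sqrt(mse / (r * l)),
          sca = sqrt(mse / r)) * k
  tc <- stats::qt(1 - alpha / 2, df_error)
  list(se_gca_line = unname(se[1]), se_gca_tester = unname(se[2]),
       se_sca = unname(se[3]), cd_gca_line = unname(tc * se[1]),
       cd_gca_tester = unname(tc * se[2]), cd_sca = unname(tc * se[3]),
       t_crit = tc, df_error = df_error)
}

#' Significance of GCA and SCA effects
#'
#' Two-sided Student-t test of each effect against zero using the
#' single-effect standard errors from [critical_differences()].
#'
#' @param ca A `"combining_ability"` object.
#' @param mse Error mean square.
#' @param design A [trial_design()].
#' @param df_error Error degrees of freedom (default as in
#'   [critical_differences()]).
#' @return `ca` with added elements `t_lines`, `t_testers`, `t_sca`
#'   (statistics), `p_lines`, `p_testers`, `p_sca`, `sig_lines`,
#'   `sig_testers`, `sig_sca` and the `se`/`cd` list.
#' @export
gca_sca_significance <- function(ca, mse, design, df_error = NULL) {
  cd <- critical_differences(mse, design, df_error = df_error)
  if (cd$se_sca <= 0) stop("zero standard error")
  tstat <- function(e, se) e / se
  pval <- function(t) 2 * stats::pt(abs(t), cd$df_error, lower.tail = FALSE)
  ca$t_lines <- tstat(ca$gca_lines, cd$se_gca_line)
  ca$t_testers <- tstat(ca$gca_testers, cd$se_gca_tester)
  ca$t_sca <- tstat(ca$sca, cd$se_sca)
  ca$p_lines <- pval(ca$t_lines)
  ca$p_testers <- pval(ca$t_testers)
  ca$p_sca <- pval(ca$t_sca)
  ca$sig_lines <- sig_codes(ca$p_lines)
  ca$sig_testers <- sig_codes(ca$p_testers)
  ca$sig_sca <- matrix(sig_codes(ca$p_sca), nrow(ca$sca),
                       dimnames = dimnames(ca$sca))
  ca$se_cd <- cd
  ca
}

#' Write combining-ability tables as TSV
#'
#' GCA table in the published layout (lines block, testers block, CD
#' footer) plus the SCA matrix (line rows x tester columns).
#'
#' @param ca A `"combining_ability"` object, ideally after
#'   [gca_sca_significance()].
#' @param gca_path,sca_path Output paths (either may be NULL to skip).
#' @export
write_combining_ability <- function(ca, gca_path = NULL, sca_path = NULL) {
  if (!is.null(gca_path)) {
    rows <- data.frame(
      entry = c(names(ca$gca_lines), "Testers", names(ca$gca_testers)),
      gca = c(ca$gca_lines, NA, ca$gca_testers),
      sig = c(if (is.null(ca$sig_lines)) rep("", length(ca$gca_lines))
              else ca$sig_lines, "",
              if (is.null(ca$sig_testers)) rep("", length(ca$gca_testers))
              else ca$sig_testers),
      stringsAsFactors = FALSE)
    if (!is.null(ca$se_cd)) {
      rows <- rbind(rows,
        data.frame(entry = c("CD 95% GCA(Line)", "CD 95% GCA(Tester)"),
                   gca = c(ca$se_cd$cd_gca_line, ca$se_cd$cd_gca_tester),
                   sig = "", stringsAsFactors = FALSE))
    }
    utils::write.table(rows, gca_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(sca_path))
    utils::write.table(cbind(line = rownames(ca$sca), round(ca$sca, 6)),
                       sca_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(ca)
}
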