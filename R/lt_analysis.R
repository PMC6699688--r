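#' Fit the full line x tester analysis
#'
#' One call runs, for every trait, the balanced line x tester ANOVA
#' ([lt_anova()]), GCA/SCA estimation with standard errors, critical
#' differences and significance ([estimate_gca_sca()],
#' [gca_sca_significance()]), and the genetic variance components with
#' their derived parameters ([estimate_variance_components()],
#' [degree_of_dominance()], [heritability_and_ga()],
#' [predictability_ratio()]). Entry means (parents and crosses) are stored
#' so heterosis can be computed from the fit.
#'
#' @param data An `"lt_trial"` from [read_phenotypes()] /
#'   [simulate_trial()], or a plot-record data.frame.
#' @param design A [trial_design()]; required when `data` is a bare
#'   data.frame.
#' @param traits Trait columns to analyse (default: the trial's traits,
#'   or all columns after `block`).
#' @param alpha Significance level for critical differences.
#' @param selection_k Selection differential constant for genetic advance.
#' @param vc_form Variance-component estimator form, see
#'   [estimate_variance_components()].
#' @return An object of class `"lt_analysis"`: list with `design`,
#'   `traits`, and per-trait lists `anova`, `effects`
#'   (`"combining_ability"` with significance), `vc`
#'   (`"variance_components"`), `genetic` (heritability etc.), `means`
#'   ([entry_means()] tables) plus the `records`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`, and
#'   [heterosis()].
#' @examples
#' sim <- simulate_trial(l = 5, t = 3, r = 2, seed = 7)
#' fit <- lt_analysis(sim)
#' summary(fit)
#' coef(fit, "gca_line", trait = "y")
#' @export
lt_analysis <- function(data, design = NULL, traits = NULL, alpha = 0.05,
                        selection_k = 2.06,
                        vc_form = c("paper", "textbook")) {
  vc_form <- match.arg(vc_form)
  if (inherits(data, "lt_trial") ||
      (is.list(data) && !is.data.frame(data) &&
       all(c("design", "records") %in% names(data)))) {
    if (is.null(design)) design <- data$design
    if (is.null(traits)) traits <- data$traits
    records <- data$records
  } else records <- data
  if (is.null(design)) stop("a trial design is required")
  if (is.null(traits)) {
    i <- match("block", names(records))
    traits <- names(records)[seq.int(i + 1L, ncol(records))]
  }
  fit <- list(design = design, traits = traits, records = records,
              alpha = alpha, anova = list(), effects = list(),
              vc = list(), genetic = list(), means = list())
  for (tr in traits) {
    a <- lt_anova(records, design, tr)
    em <- entry_means(records, tr)
    ca <- estimate_gca_sca(em, design, trait = tr)
    ca <- gca_sca_significance(ca, attr(a, "error_ms"), design,
                               attr(a, "error_df"))
    vc <- estimate_variance_components(a, design, form = vc_form)
    gen <- c(heritability_and_ga(vc, selection_k = selection_k),
             list(degree_of_dominance =
                    suppressWarnings(degree_of_dominance(vc)),
                  predictability_ratio =
                    tryCatch(predictability_ratio(vc),
                             error = function(e) NA_real_)))
    fit$anova[[tr]] <- a
    fit$means[[tr]] <- em
    fit$effects[[tr]] <- ca
    fit$vc[[tr]] <- vc
    fit$genetic[[tr]] <- gen
  }
  class(fit) <- "lt_analysis"
  fit
}

#' @export
print.lt_analysis <- function(x, ...) {
  cat("Line x tester analysis: ", x$design$l, " lines x ", x$design$t,
      " testers, ", x$design$r, " reps; ", length(x$traits),
      " trait(s)\n", sep = "")
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  cat("use summary() for variance components, coef() for GCA/SCA effects\n")
  invisible(x)
}

#' @export
summary.lt_analysis <- function(object, ...) {
  rows <- lapply(object$traits, function(tr) {
    a <- object$anova[[tr]]; vc <- object$vc[[tr]]
    g <- object$genetic[[tr]]
    i <- match(c("Line Effect", "Tester Effect", "Line x Tester Eff."),
               a$source)
    data.frame(trait = tr,
               MS_line = a$MS[i[1]], MS_tester = a$MS[i[2]],
               MS_lxt = a$MS[i[3]], MS_error = attr(a, "error_ms"),
               s2_gca_line = vc$s2_gca_line,
               s2_gca_tester = vc$s2_gca_tester,
               s2_gca_avg = vc$s2_gca_avg, s2_sca = vc$s2_sca,
               s2_A = vc$s2_A, s2_D = vc$s2_D,
               dod = g$degree_of_dominance,
               h2_ns_pct = g$h2_narrow_pct, GA = g$genetic_advance,
               pred_ratio = g$predictability_ratio,
               h2_class = g$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.lt_analysis", "data.frame")
  out
}

#' @export
print.summary.lt_analysis <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract combining-ability effects from a fit
#'
#' @param object An `"lt_analysis"` fit.
#' @param type `"gca_line"`, `"gca_tester"` or `"sca"`.
#' @param trait Trait name (default the first).
#' @param ... Unused.
#' @return Named vector (GCA) or matrix (SCA) of effects.
#' @export
coef.lt_analysis <- function(object,
                             type = c("gca_line", "gca_tester", "sca"),
                             trait = object$traits[1], ...) {
  type <- match.arg(type)
  ca <- object$effects[[trait]]
  if (is.null(ca)) stop("unknown trait: ", trait)
  switch(type, gca_line = ca$gca_lines, gca_tester = ca$gca_testers,
         sca = ca$sca)
}

#' Predicted cross means from a fit
#'
#' Cell means reconstructed as `mu + g_i + g_j + s_ij`; with
#' `sca = FALSE`, the GCA-only prediction `mu + g_i + g_j` (the value a
#' breeder would forecast from combining ability alone).
#'
#' @param object An `"lt_analysis"` fit.
#' @param trait Trait name (default the first).
#' @param sca Include the SCA term (default TRUE).
#' @param ... Unused.
#' @return l x t matrix of predicted cross means.
#' @export
predict.lt_analysis <- function(object, trait = object$traits[1],
                                sca = TRUE, ...) {
  ca <- object$effects[[trait]]
  if (is.null(ca)) stop("unknown trait: ", trait)
  m <- outer(ca$gca_lines, ca$gca_testers, "+") + ca$grand_mean
  if (sca) m <- m + ca$sca
  m
}

#' Plot-level residuals of a fit
#'
#' Observation minus replicate effect minus entry mean, i.e. the residual
#' of the randomized-complete-block model that the ANOVA decomposes;
#' their sum of squares equals the ANOVA error SS.
#'
#' @param object An `"lt_analysis"` fit.
#' @param trait Trait name (default the first).
#' @param ... Unused.
#' @return Numeric vector, one residual per non-check plot record.
#' @export
residuals.lt_analysis <- function(object, trait = object$traits[1], ...) {
  rec <- object$records[object$records$role != "check", , drop = FALSE]
  y <- rec[[trait]]
  id <- ifelse(rec$role == "cross",
               paste(rec$line, rec$tester, sep = "x"), rec$entry)
  ent_mean <- stats::ave(y, id)
  rep_dev <- stats::ave(y, rec$rep) - mean(y)
  y - ent_mean - rep_dev
}

#' Barplot of GCA effects
#'
#' @param x An `"lt_analysis"` fit.
#' @param trait Trait name (default the first).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.lt_analysis <- function(x, trait = x$traits[1], ...) {
  ca <- x$effects[[trait]]
  eff <- c(ca$gca_lines, ca$gca_testers)
  graphics::barplot(eff, las = 2,
                    main = paste("GCA effects:", trait),
                    ylab = "GCA effect", ...)
  graphics::abline(h = 0)
  cd <- ca$se_cd
  if (!is.null(cd))
    graphics::abline(h = c(-1, 1) * cd$cd_gca_line, lty = 2)
  invisible(x)
}

#' Simulate new trials from a fitted analysis
#'
#' Parametric re-simulation: draws `nsim` balanced trials from
#' [simulate_trial()] with the variance components and grand mean
#' estimated for one trait (negative component estimates are truncated
#' at zero for generation).
#'
#' @param object An `"lt_analysis"` fit.
#' @param nsim Number of trials.
#' @param seed Integer seed.
#' @param trait Trait whose estimates parameterize the generator.
#' @param ... Unused.
#' @return List of `nsim` [simulate_trial()] results.
#' @export
simulate.lt_analysis <- function(object, nsim = 1, seed = 1,
                                 trait = object$traits[1], ...) {
  vc <- object$vc[[trait]]
  ca <- object$effects[[trait]]
  d <- object$design
  lapply(seq_len(nsim), function(s)
    simulate_trial(l = d$l, t = d$t, r = d$r, mu = ca$grand_mean,
                   var_gca_line = max(0, vc$s2_gca_line),
                   var_gca_tester = max(0, vc$s2_gca_tester),
                   var_sca = max(0, vc$s2_sca),
                   var_error = vc$ms$error, trait = trait,
                   seed = seed + s - 1L))
}

#' @rdname heterosis
#' @param trait Trait name (method for fitted analyses).
#' @param significance Attach [heterosis_significance()] columns using the
#'   fit's error mean square.
#' @export
heterosis.lt_analysis <- function(x, trait = x$traits[1],
                                  direction = "+", significance = TRUE,
                                  ...) {
  em <- x$means[[trait]]
  if (is.null(em)) stop("unknown trait: ", trait)
  cm <- em[em$role == "cross", , drop = FALSE]
  pm <- em[em$role %in% c("line_parent", "tester_parent"), , drop = FALSE]
  parent_means <- stats::setNames(pm$mean, pm$entry)
  het <- heterosis.default(cm, parent_means, direction = direction)
  if (significance) {
    a <- x$anova[[trait]]
    het <- heterosis_significance(het, attr(a, "error_ms"), x$design$r,
                                  attr(a, "error_df"))
  }
  het
}
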