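#' Phenotypic (Euclidean) distance between entries
#'
#' Euclidean distance between entries over a set of traits. By default each
#' trait is centred and scaled to unit variance across the entries first,
#' so traits measured in grams and centimetres contribute comparably;
#' zero-variance traits are dropped with a warning. Unstandardized raw
#' distances are available with `standardize = FALSE`.
#'
#' @param means Entries x traits numeric matrix or data.frame (rownames =
#'   entry ids), e.g. assembled from [entry_means()] of the parents.
#' @param traits Trait columns to use (default all columns).
#' @param standardize Z-score traits before the distance (default TRUE).
#' @return Symmetric distance matrix with dimnames = entry ids and
#'   attribute `kind = "euclidean"`.
#' @export
phenotypic_distance <- function(means, traits = colnames(means),
                                standardize = TRUE) {
  m <- if (is.null(traits)) as.matrix(means)
       else as.matrix(means[, traits, drop = FALSE])
  storage.mode(m) <- "double"
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance trait(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "))
      m <- m[, sds > 0, drop = FALSE]
    }
    m <- scale(m)
  }
  d <- as.matrix(stats::dist(m))
  attr(d, "kind") <- "euclidean"
  d
}

#' Parental distance per cross
#'
#' Looks up, for each cross, the distance between its two parents in a
#' distance matrix. Access is by identifier, not position.
#'
#' @param d Square distance matrix with parent ids as dimnames.
#' @param crosses Data.frame with columns `line` and `tester`.
#' @return Named numeric vector, one value per cross, named
#'   `"<line>x<tester>"`, in the order of `crosses`.
#' @export
cross_distance_lookup <- function(d, crosses) {
  miss <- setdiff(unique(c(crosses$line, crosses$tester)), rownames(d))
  if (length(miss))
    stop("parent id(s) absent from the distance matrix: ",
         paste(miss, collapse = ", "))
  v <- d[cbind(crosses$line, crosses$tester)]
  names(v) <- paste(crosses$line, crosses$tester, sep = "x")
  v
}

#' Pearson product-moment correlation with t test
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with finite values.
#' @param label Optional pair label carried in the result.
#' @return An object of class `"correlation_result"`: list with `label`,
#'   `n`, `r`, `t`, `p` (two-sided, Student t on `n - 2` df) and `sig`
#'   code at the 5 and 1 percent levels.
#' @export
pearson_correlation <- function(x, y, label = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  structure(list(label = label, n = n, r = r, t = t, p = p,
                 sig = sig_codes(p, c(0.05, 0.01))),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat(if (!is.null(x$label)) paste0(x$label, ": "),
      "r = ", round(x$r, digits), x$sig, " (n = ", x$n,
      ", t = ", round(x$t, digits), ", p = ", signif(x$p, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Correlation grid of distances, combining ability and heterosis
#'
#' For one trait, the standard 8-row association grid: genetic distance
#' (GD) and phenotypic distance (PD) each against mid-parent heterosis,
#' better-parent heterosis and SCA, plus SCA against MPH and BPH. All
#' vectors are aligned on cross identifiers (`"<line>x<tester>"`), not on
#' position; crosses lacking a heterosis value are dropped pairwise.
#'
#' @param gd,pd Named per-cross parental distance vectors from
#'   [cross_distance_lookup()] (either may be NULL to skip its rows).
#' @param het A `"heterosis_table"` for the trait.
#' @param sca Named per-cross SCA vector (e.g.
#'   `ca$sca[cbind(line, tester)]` named `"<line>x<tester>"`), or a
#'   `"combining_ability"` object.
#' @param trait Trait label for the row names.
#' @return Data.frame with columns `pair`, `trait`, `n`, `r`, `t`, `p`,
#'   `sig`.
#' @export
association_matrix <- function(gd = NULL, pd = NULL, het, sca,
                               trait = "") {
  if (inherits(sca, "combining_ability")) {
    s <- sca$sca
    sca <- stats::setNames(as.vector(s),
                           paste(rownames(s)[row(s)],
                                 colnames(s)[col(s)], sep = "x"))
  }
  ids <- het$cross
  align <- function(v) {
    if (is.null(names(v))) stop("cross vectors must be named by cross id")
    miss <- setdiff(ids, names(v))
    if (length(miss))
      stop("cross id(s) missing: ", paste(utils::head(miss, 3),
                                          collapse = ", "))
    v[ids]
  }
  sca <- align(sca)
  pairs <- list()
  add <- function(name, x, y) {
    cr <- pearson_correlation(x, y, label = name)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      pair = name, trait = trait, n = cr$n, r = cr$r, t = cr$t, p = cr$p,
      sig = cr$sig, stringsAsFactors = FALSE)
  }
  if (!is.null(gd)) {
    gd <- align(gd)
    add("GD-MPH", gd, het$MPH); add("GD-BPH", gd, het$BPH)
    add("GD-SCA", gd, sca)
  }
  if (!is.null(pd)) {
    pd <- align(pd)
    add("PD-MPH", pd, het$MPH); add("PD-BPH", pd, het$BPH)
    add("PD-SCA", pd, sca)
  }
  add("SCA-MPH", sca, het$MPH); add("SCA-BPH", sca, het$BPH)
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Variance shares of trait principal components
#'
#' Eigenvalue shares of the trait correlation matrix (traits standardized
#' by default), i.e. the fraction of total phenotypic variation captured
#' by each principal component, in descending order.
#'
#' @param means Entries x traits numeric matrix or data.frame.
#' @param traits Trait columns to use (default all).
#' @param n_components How many leading shares to return (default all).
#' @param standardize Use the correlation rather than covariance matrix.
#' @return Numeric vector of shares (non-increasing; all components sum
#'   to 1).
#' @export
pca_variance_shares <- function(means, traits = colnames(means),
                                n_components = NULL, standardize = TRUE) {
  m <- if (is.null(traits)) as.matrix(means)
       else as.matrix(means[, traits, drop = FALSE])
  if (nrow(m) < 2L) stop("need at least 2 entries")
  sds <- apply(m, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    warning("dropping zero-variance trait(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, scale. = standardize)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_components))
    shares <- shares[seq_len(min(n_components, length(shares)))]
  shares
}
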