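#' Allele frequencies at a locus
#'
#' Counts alleles over the `2 n` allele slots of the typed (non-missing)
#' individuals at one locus of a codominant panel.
#'
#' @param gm A `"genotype_matrix"` from [read_genotypes()] or
#'   [simulate_markers()].
#' @param locus Locus identifier or column index.
#' @return Named numeric vector of frequencies (sums to 1), with attribute
#'   `n_typed`.
#' @export
allele_frequencies <- function(gm, locus) {
  j <- if (is.character(locus)) match(locus, gm$loci) else locus
  if (is.na(j)) stop("unknown locus: ", locus)
  a <- c(gm$a1[, j], gm$a2[, j])
  a <- a[!is.na(a)]
  if (length(a) == 0L) stop("locus entirely missing: ", gm$loci[j])
  tab <- table(a)
  structure(as.numeric(tab) / length(a), names = names(tab),
            n_typed = length(a) / 2)
}

pic_botstein <- function(p) {
  s2 <- sum(p^2)
  # 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2 ; the double sum equals
  # ((sum p^2)^2 - sum p^4) via the square-of-sums identity
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-locus diversity statistics
#'
#' For each locus: number of typed individuals, distinct allele count `N`,
#' observed heterozygosity `Ho` (heterozygote fraction among typed
#' individuals), expected heterozygosity `He` and polymorphism information
#' content `PIC`. `He` is `1 - sum(p^2)` by default
#' (`he_form = "unbiased"` applies the `2n/(2n - 1)` small-sample factor).
#' `PIC` defaults to Botstein's form
#' `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`, which is at most `He`;
#' `pic_form = "simple"` gives the plain `1 - sum(p^2)`.
#'
#' @param gm A `"genotype_matrix"`.
#' @param loci Loci to evaluate (default all).
#' @param pic_form `"botstein"` (default) or `"simple"`.
#' @param he_form `"plain"` (default) or `"unbiased"`.
#' @return A data.frame with columns `locus`, `n_typed`, `N`, `Ho`, `He`,
#'   `PIC`, one row per locus.
#' @export
locus_stats <- function(gm, loci = gm$loci,
                        pic_form = c("botstein", "simple"),
                        he_form = c("plain", "unbiased")) {
  pic_form <- match.arg(pic_form)
  he_form <- match.arg(he_form)
  rows <- lapply(loci, function(lc) {
    j <- if (is.character(lc)) match(lc, gm$loci) else lc
    p <- allele_frequencies(gm, j)
    n <- attr(p, "n_typed")
    typed <- !is.na(gm$a1[, j])
    ho <- mean(gm$a1[typed, j] != gm$a2[typed, j])
    he <- 1 - sum(p^2)
    if (he_form == "unbiased") he <- he * 2 * n / (2 * n - 1)
    pic <- if (pic_form == "botstein") pic_botstein(p) else 1 - sum(p^2)
    data.frame(locus = gm$loci[j], n_typed = n, N = length(p), Ho = ho,
               He = he, PIC = pic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Panel-level summary of locus diversity
#'
#' Totals and ranges over a set of per-locus statistics, plus marker
#' informativeness classes: highly informative (PIC >= 0.5), reasonably
#' informative (0.25 <= PIC < 0.5) and slightly informative (PIC < 0.25).
#'
#' @param stats A data.frame with columns `N`, `Ho`, `He`, `PIC` and
#'   (optionally) `locus` — from [locus_stats()] or a
#'   [read_fixture_table()] locus table.
#' @return A list with `n_loci`, `total_alleles`, `mean_N`, ranges and
#'   argmin/argmax loci for `Ho`, `He`, `PIC`, and `informativeness`
#'   class counts.
#' @export
summarize_panel <- function(stats) {
  if (nrow(stats) == 0L) stop("empty locus table")
  lab <- if (!is.null(stats$locus)) stats$locus else seq_len(nrow(stats))
  rng <- function(v) list(mean = mean(v), min = min(v), max = max(v),
                          which_min = lab[which.min(v)],
                          which_max = lab[which.max(v)])
  list(n_loci = nrow(stats),
       total_alleles = sum(stats$N),
       mean_N = mean(stats$N),
       min_N = min(stats$N), max_N = max(stats$N),
       Ho = rng(stats$Ho), He = rng(stats$He), PIC = rng(stats$PIC),
       informativeness = c(
         high = sum(stats$PIC >= 0.5),
         reasonable = sum(stats$PIC >= 0.25 & stats$PIC < 0.5),
         slight = sum(stats$PIC < 0.25)))
}

# multiset intersection size of two diploid calls = max over the two
# possible pairings of allele-by-allele matches
shared_alleles <- function(x1, x2, y1, y2) {
  pmax((x1 == y1) + (x2 == y2), (x1 == y2) + (x2 == y1))
}

#' Simple-matching dissimilarity between codominant genotypes
#'
#' Per locus, the similarity of two individuals is the number of shared
#' alleles (counting multiplicity) divided by 2, i.e. 0, 0.5 or 1; the
#' distance of a pair is 1 minus the mean similarity over loci typed in
#' both individuals (pairwise deletion of missing calls).
#'
#' @param gm A `"genotype_matrix"`.
#' @param loci Optional subset/resampling of locus indices (used by the
#'   bootstrap).
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames = individual ids, attribute `kind =
#'   "simple_matching"`.
#' @export
simple_matching_distance <- function(gm, loci = NULL) {
  a1 <- gm$a1; a2 <- gm$a2
  if (!is.null(loci)) { a1 <- a1[, loci, drop = FALSE]
                        a2 <- a2[, loci, drop = FALSE] }
  n <- length(gm$ids)
  d <- matrix(0, n, n, dimnames = list(gm$ids, gm$ids))
  for (i in seq_len(n - 1L)) for (k in seq.int(i + 1L, n)) {
    ok <- !is.na(a1[i, ]) & !is.na(a1[k, ])
    if (!any(ok))
      stop("no co-typed loci for pair ", gm$ids[i], ", ", gm$ids[k])
    s <- shared_alleles(a1[i, ok], a2[i, ok], a1[k, ok], a2[k, ok]) / 2
    d[i, k] <- d[k, i] <- 1 - mean(s)
  }
  attr(d, "kind") <- "simple_matching"
  d
}

#' UPGMA tree with optional locus bootstrap
#'
#' Builds the rooted UPGMA (average-linkage) tree of a distance matrix.
#' When a genotype matrix and `n_boot > 0` are supplied, loci (columns)
#' are resampled with replacement, the simple-matching distance and UPGMA
#' tree are recomputed per replicate, and each internal node is annotated
#' with the fraction of replicate trees containing the same leaf
#' bipartition. Deterministic for a given `seed`.
#'
#' @param d Symmetric distance matrix (as from
#'   [simple_matching_distance()]) or a [stats::dist] object.
#' @param genotypes A `"genotype_matrix"`, required for bootstrapping.
#' @param n_boot Number of bootstrap replicates (0 = none).
#' @param seed Integer seed for the resampling.
#' @return An [ape::as.phylo()] tree; with bootstrapping, node labels hold
#'   support values in `[0, 1]`. Export with [ape::write.tree()].
#' @export
upgma_tree <- function(d, genotypes = NULL, n_boot = 0, seed = 1) {
  dd <- stats::as.dist(d)
  if (attr(dd, "Size") < 2L) stop("need at least 2 leaves")
  tree <- ape::as.phylo(stats::hclust(dd, method = "average"))
  if (n_boot > 0) {
    if (is.null(genotypes))
      stop("bootstrapping requires the genotype matrix")
    set.seed(seed)
    nl <- length(genotypes$loci)
    reps <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nl, nl, replace = TRUE)
      db <- stats::as.dist(simple_matching_distance(genotypes, idx))
      ape::as.phylo(stats::hclust(db, method = "average"))
    })
    cnt <- ape::prop.clades(tree, reps, rooted = TRUE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- cnt / n_boot
  }
  tree
}

#' Neighbour-joining tree
#'
#' Unrooted NJ companion to [upgma_tree()], via [ape::nj()].
#'
#' @inheritParams upgma_tree
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  ape::nj(stats::as.dist(d))
}

#' Evanno delta-K summary of structure log-likelihoods
#'
#' Given replicate model log-likelihoods `L(K)` for consecutive numbers of
#' clusters `K`, computes the first difference `L'(K) = mean L(K) - mean
#' L(K-1)`, the absolute second difference `|L''(K)| = |L'(K+1) - L'(K)|`,
#' and `deltaK = |L''(K)| / sd(L(K))`, defined for interior `K` only. The
#' `K` maximising deltaK is the supported number of clusters.
#'
#' @param loglik A named list (names = K values) of numeric run vectors,
#'   or a runs x K matrix with K values as column names.
#' @return An object of class `"evanno"`: data.frame with columns `K`,
#'   `n_runs`, `mean_L`, `sd_L`, `L1` (first difference), `abs_L2`,
#'   `deltaK`; attribute `best_k`.
#' @examples
#' ll <- list(`1` = c(-100, -101), `2` = c(-80, -81), `3` = c(-75, -74),
#'            `4` = c(-74, -73))
#' evanno_delta_k(ll)
#' @export
evanno_delta_k <- function(loglik) {
  if (is.matrix(loglik))
    loglik <- stats::setNames(
      lapply(seq_len(ncol(loglik)), function(j) loglik[, j]),
      colnames(loglik))
  ks <- as.integer(names(loglik))
  if (anyNA(ks)) ks <- seq_along(loglik)
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  if (any(lengths(loglik) < 2L)) stop("need at least 2 runs per K")
  mu <- vapply(loglik, mean, 0)
  sdv <- vapply(loglik, stats::sd, 0)
  n <- length(ks)
  l1 <- c(NA, diff(mu))                     # L'(K), defined for K >= 2
  l2 <- c(NA, abs(diff(l1[-1])), NA)        # |L''(K)|, interior K only
  interior <- seq(2L, n - 1L)
  if (any(sdv[interior] == 0))
    stop("zero standard deviation of L(K) at an interior K")
  dk <- rep(NA_real_, n)
  dk[interior] <- l2[interior] / sdv[interior]
  out <- data.frame(K = ks, n_runs = lengths(loglik), mean_L = mu,
                    sd_L = sdv, L1 = l1, abs_L2 = l2, deltaK = dk)
  rownames(out) <- NULL
  structure(out, class = c("evanno", "data.frame"),
            best_k = ks[which.max(dk)])
}

#' @export
print.evanno <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  cat("best K (max deltaK):", attr(x, "best_k"), "\n")
  invisible(x)
}

#' Write a distance matrix as TSV
#'
#' @param d Square distance matrix.
#' @param path Output path.
#' @param format `"square"` or `"lower"` (PHYLIP-style lower triangle).
#' @export
write_distance <- function(d, path, format = c("square", "lower")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.table(cbind(id = rownames(d), round(d, 6)), path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i],
                         sprintf("%.6f", d[i, seq_len(i - 1)])),
                       collapse = "\t"), con)
  }
  invisible(path)
}
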