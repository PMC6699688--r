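extdata <- function(name) {
  system.file("extdata", name, package = "linetester", mustWork = TRUE)
}

# tiny hand-built balanced 2x2x2 trial; values chosen arbitrary but fixed
toy_records <- function() {
  design <- trial_design(c("A", "B"), c("X", "Y"), 2)
  grid <- expand.grid(rep = 1:2, entry = c("A", "B", "X", "Y",
                                           "AxX", "AxY", "BxX", "BxY"),
                      stringsAsFactors = FALSE)
  role <- ifelse(grid$entry %in% c("A", "B"), "line_parent",
          ifelse(grid$entry %in% c("X", "Y"), "tester_parent", "cross"))
  line <- ifelse(role == "line_parent", grid$entry,
          ifelse(role == "cross", substr(grid$entry, 1, 1), ""))
  tester <- ifelse(role == "tester_parent", grid$entry,
            ifelse(role == "cross", substr(grid$entry, 3, 3), ""))
  rec <- data.frame(entry = grid$entry, role = role, line = line,
                    tester = tester, rep = grid$rep, block = 1L,
                    y = c(10.2, 11.1, 8.9, 9.4, 12.0, 12.8, 11.5, 10.9,
                          14.3, 15.0, 13.2, 12.6, 15.8, 16.4, 13.9, 14.7),
                    stringsAsFactors = FALSE)
  list(design = design, records = rec)
}

# build a genotype_matrix directly from a list of per-locus call matrices:
# calls[[locus]] is a 2-column character matrix (NA row = missing call)
make_gm <- function(calls, ids = NULL) {
  n <- nrow(calls[[1]])
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(n))
  loci <- if (is.null(names(calls))) sprintf("M%02d", seq_along(calls))
          else names(calls)
  a1 <- sapply(calls, function(m) m[, 1])
  a2 <- sapply(calls, function(m) m[, 2])
  a1 <- matrix(a1, n, dimnames = list(ids, loci))
  a2 <- matrix(a2, n, dimnames = list(ids, loci))
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

# independent sums-of-squares oracle: every SS from group totals and the
# correction factor, written without reference to the package internals
oracle_ss <- function(rec, design) {
  r <- design$r
  y <- rec$y
  id <- ifelse(rec$role == "cross", paste0(rec$line, "x", rec$tester),
               rec$entry)
  cf <- sum(y)^2 / length(y)
  tot <- tapply(y, id, sum)
  gss <- function(ids2, div) sum(tapply(y[id %in% ids2], id[id %in% ids2],
                                        sum)^2) / div -
    sum(y[id %in% ids2])^2 / (length(ids2) * div)
  lines <- design$lines; testers <- design$testers
  crosses <- as.vector(outer(lines, testers, paste, sep = "x"))
  parents <- c(lines, testers)
  ss_total <- sum(y^2) - cf
  ss_rep <- sum(tapply(y, rec$rep, sum)^2) / length(tot) - cf
  ss_trt <- sum(tot^2) / r - cf
  # parent-vs-cross contrast from the two group totals
  gp <- sum(y[id %in% parents]); gc <- sum(y[id %in% crosses])
  ss_pvc <- gp^2 / (length(parents) * r) + gc^2 / (length(crosses) * r) - cf
  gl <- sum(y[id %in% lines]); gt <- sum(y[id %in% testers])
  ss_lvt <- gl^2 / (length(lines) * r) + gt^2 / (length(testers) * r) -
    gp^2 / (length(parents) * r)
  # line/tester main effects among crosses from margin totals
  ct <- matrix(tot[crosses], length(lines), length(testers))
  gcr <- sum(ct)
  ss_line_c <- sum(rowSums(ct)^2) / (length(testers) * r) -
    gcr^2 / (length(crosses) * r)
  ss_tst_c <- sum(colSums(ct)^2) / (length(lines) * r) -
    gcr^2 / (length(crosses) * r)
  list(total = ss_total, rep = ss_rep, treatments = ss_trt,
       parents = gss(parents, r), crosses = gss(crosses, r),
       parents_vs_crosses = ss_pvc,
       parents_line = gss(lines, r), parents_tester = gss(testers, r),
       l_vs_t = ss_lvt, line_eff = ss_line_c, tester_eff = ss_tst_c,
       lxt = gss(crosses, r) - ss_line_c - ss_tst_c,
       error = ss_total - ss_rep - ss_trt)
}
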