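test_that("allele frequencies count over the 2n allele slots", {
  gm <- make_gm(list(M1 = rbind(c("A", "A"), c("A", "B"))))
  p <- allele_frequencies(gm, "M1")
  expect_equal(unname(p["A"]), 0.75)
  expect_equal(unname(p["B"]), 0.25)
  expect_equal(sum(p), 1)
  expect_equal(attr(p, "n_typed"), 2)

  mono <- make_gm(list(M1 = rbind(c("A", "A"), c("A", "A"))))
  expect_equal(as.vector(allele_frequencies(mono, "M1")), 1)

  gone <- make_gm(list(M1 = rbind(c(NA, NA), c(NA, NA))))
  expect_error(allele_frequencies(gone, "M1"), "entirely missing")
  expect_error(allele_frequencies(gm, "Mx"), "unknown locus")
})

test_that("biallelic p = q = 1/2 gives the closed-form statistics", {
  # 2 het + 1 AA + 1 BB: p(A) = p(B) = 0.5
  gm <- make_gm(list(M1 = rbind(c("A", "B"), c("B", "A"), c("A", "A"),
                                c("B", "B"))))
  plain <- locus_stats(gm, pic_form = "simple")
  expect_equal(plain$He, 0.5)
  expect_equal(plain$PIC, 0.5)
  expect_equal(plain$Ho, 0.5)
  bot <- locus_stats(gm, pic_form = "botstein")
  expect_equal(bot$PIC, 0.375)
  unb <- locus_stats(gm, he_form = "unbiased")
  expect_equal(unb$He, 0.5 * 8 / 7)
})

test_that("Botstein PIC equals the brute-force double sum", {
  set.seed(42)
  for (rep in 1:5) {
    k <- 6
    counts <- as.vector(rmultinom(1, 40, rgamma(k, 1)))
    counts[counts == 0] <- 1
    # build individuals so that allele counts match exactly
    alleles <- rep(paste0("a", seq_len(k)), counts)
    alleles <- sample(alleles)
    n <- floor(length(alleles) / 2) * 2
    m <- matrix(alleles[seq_len(n)], ncol = 2)
    gm <- make_gm(list(M1 = m))
    p <- allele_frequencies(gm, "M1")
    oracle <- 1 - sum(p^2)
    for (i in seq_along(p)) for (j in seq_along(p)) if (j > i)
      oracle <- oracle - 2 * p[i]^2 * p[j]^2
    expect_equal(locus_stats(gm)$PIC, unname(oracle), tolerance = 1e-12)
  }
})

test_that("homozygous panels have zero observed heterozygosity", {
  sim <- simulate_markers(n_individuals = 10, n_loci = 6,
                          dh_flags = rep(TRUE, 10), missing_rate = 0,
                          seed = 3)
  st <- locus_stats(sim$genotypes)
  expect_true(all(st$Ho == 0))
})

test_that("PIC (Botstein) never exceeds plain He, equality iff monomorphic", {
  sim <- simulate_markers(n_individuals = 30, n_loci = 40, n_subpops = 2,
                          dh_flags = rep(FALSE, 30), missing_rate = 0.05,
                          seed = 11)
  st <- locus_stats(sim$genotypes)
  expect_true(all(st$PIC <= st$He + 1e-12))
  poly <- st$N > 1
  expect_true(all(st$PIC[poly] < st$He[poly]))
  expect_true(all(st$He[!poly] == 0 & st$PIC[!poly] == 0 &
                    st$Ho[!poly] == 0))
})

test_that("panel summary aggregates and is locus-order invariant", {
  ls <- read_fixture_table(extdata("table6_locus_stats.csv"),
                           "locus_stats")
  s <- summarize_panel(ls)
  expect_equal(s$total_alleles, sum(ls$N))
  expect_equal(s$PIC$which_min, "cnu107")
  s2 <- summarize_panel(ls[sample(nrow(ls)), ])
  expect_equal(s2$mean_N, s$mean_N)
  expect_equal(s2$PIC$mean, s$PIC$mean)
  one <- summarize_panel(ls[1, ])
  expect_equal(one$total_alleles, ls$N[1])
  expect_equal(one$He$mean, ls$He[1])
  expect_equal(sum(s$informativeness), 87)
  expect_error(summarize_panel(ls[0, ]), "empty")
})

test_that("simple matching distance enumerates shared-allele cases", {
  gm <- make_gm(list(M1 = rbind(c("A", "B"), c("A", "B"), c("C", "D"),
                                c("A", "C"))),
                ids = c("i1", "i2", "i3", "i4"))
  d <- simple_matching_distance(gm)
  expect_equal(unname(d["i1", "i2"]), 0)   # identical
  expect_equal(unname(d["i1", "i3"]), 1)   # disjoint
  expect_equal(unname(d["i1", "i4"]), 0.5) # one shared allele
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  # order of alleles within a call is irrelevant
  gm2 <- make_gm(list(M1 = rbind(c("B", "A"), c("A", "B"))))
  expect_equal(unname(simple_matching_distance(gm2)[1, 2]), 0)
})

test_that("simple matching is a metric on complete profiles", {
  sim <- simulate_markers(n_individuals = 12, n_loci = 20, n_subpops = 3,
                          dh_flags = rep(FALSE, 12), missing_rate = 0,
                          seed = 7)
  d <- simple_matching_distance(sim$genotypes)
  expect_true(all(d >= 0 & d <= 1))
  set.seed(1)
  for (rep in 1:30) {
    ijk <- sample(12, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("UPGMA reproduces the hand-computed 3-leaf tree", {
  d <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  coph <- as.matrix(ape::cophenetic.phylo(tr))
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.8)
  expect_equal(coph["B", "C"], 0.8)
  # an ultrametric input is a fixed point of UPGMA
  sim <- simulate_markers(n_individuals = 8, n_loci = 30,
                          dh_flags = rep(FALSE, 8), missing_rate = 0,
                          seed = 2)
  d0 <- simple_matching_distance(sim$genotypes)
  coph0 <- as.matrix(ape::cophenetic.phylo(upgma_tree(d0)))
  tr2 <- upgma_tree(coph0[rownames(d0), rownames(d0)])
  coph2 <- as.matrix(ape::cophenetic.phylo(tr2))
  expect_equal(coph2[rownames(d0), rownames(d0)],
               coph0[rownames(d0), rownames(d0)], tolerance = 1e-10)
  expect_error(upgma_tree(matrix(0, 1, 1)), "2 leaves")
})

test_that("bootstrap over duplicated loci gives full support", {
  base <- rbind(c("A", "A"), c("A", "A"), c("B", "B"), c("B", "B"),
                c("C", "C"), c("D", "D"))
  gm <- make_gm(rep(list(base), 10))
  d <- simple_matching_distance(gm)
  tr <- upgma_tree(d, genotypes = gm, n_boot = 30, seed = 99)
  expect_true(all(tr$node.label == 1))
  tr_a <- upgma_tree(d, genotypes = gm, n_boot = 10, seed = 5)
  tr_b <- upgma_tree(d, genotypes = gm, n_boot = 10, seed = 5)
  expect_identical(ape::write.tree(tr_a), ape::write.tree(tr_b))
  expect_error(upgma_tree(d, n_boot = 5), "genotype")
})

test_that("NJ returns an unrooted tree on the same leaves", {
  sim <- simulate_markers(n_individuals = 6, n_loci = 25,
                          dh_flags = rep(FALSE, 6), missing_rate = 0,
                          seed = 4)
  d <- simple_matching_distance(sim$genotypes)
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, sim$genotypes$ids)
  expect_false(ape::is.rooted(tr))
})

test_that("Evanno delta-K matches hand arithmetic on a 4-point profile", {
  a <- 1 / sqrt(2) # two runs at mean +/- a have sd exactly 1
  mk <- function(m) c(m - a, m + a)
  ll <- list(`1` = mk(-100), `2` = mk(-80), `3` = mk(-75), `4` = mk(-74))
  ev <- evanno_delta_k(ll)
  expect_equal(ev$deltaK[ev$K == 2], 15)
  expect_equal(ev$deltaK[ev$K == 3], 4)
  expect_true(is.na(ev$deltaK[ev$K == 1]) && is.na(ev$deltaK[ev$K == 4]))
  expect_equal(attr(ev, "best_k"), 2)

  lin <- list(`1` = mk(-90), `2` = mk(-80), `3` = mk(-70),
              `4` = mk(-60))
  expect_true(all(evanno_delta_k(lin)$deltaK[2:3] == 0))

  flat <- list(`1` = c(-5, -5), `2` = c(-4, -4), `3` = c(-3, -3))
  expect_error(evanno_delta_k(flat), "zero standard deviation")
  expect_error(evanno_delta_k(ll[1:2]), "3 consecutive")
  expect_error(evanno_delta_k(list(`1` = mk(1), `3` = mk(2),
                                   `5` = mk(3))), "consecutive")
})
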