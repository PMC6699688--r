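test_that("standardized Euclidean distance matches hand z-scores", {
  m <- rbind(e1 = c(t1 = 0, t2 = 5), e2 = c(t1 = 2, t2 = 9))
  d <- phenotypic_distance(m)
  # two entries: z-scores are +/- 1/sqrt(2) per trait, delta = sqrt(2)
  z <- apply(m, 2, function(v) (v - mean(v)) / sd(v))
  expect_equal(unname(d["e1", "e2"]), sqrt(sum((z[1, ] - z[2, ])^2)))
  expect_equal(unname(d["e1", "e2"]), 2)
  expect_equal(unname(diag(d)), c(0, 0))
  # identical entries are at distance zero
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 0, 5))
  expect_equal(unname(phenotypic_distance(m2)["a", "b"]), 0)
})

test_that("standardized distance is invariant to per-trait affine maps", {
  set.seed(14)
  m <- matrix(rnorm(26 * 5, 50, 8), 26, 5,
              dimnames = list(sprintf("P%02d", 1:26), paste0("t", 1:5)))
  d1 <- phenotypic_distance(m)
  m2 <- sweep(sweep(m, 2, c(2, 100, 0.5, 7, 3), "*"), 2,
              c(-5, 10, 0, 2, 1), "+")
  expect_equal(phenotypic_distance(m2), d1, tolerance = 1e-10)
})

test_that("mean pairwise distance scales as sqrt(2p) for random traits", {
  set.seed(99)
  m <- matrix(rnorm(26 * 16), 26, 16,
              dimnames = list(sprintf("P%02d", 1:26), NULL))
  d <- phenotypic_distance(m)
  mean_pd <- mean(d[upper.tri(d)])
  expect_equal(mean_pd, sqrt(2 * 16), tolerance = 0.1)
})

test_that("zero-variance traits are dropped with a warning", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(d <- phenotypic_distance(m), "zero-variance")
  expect_equal(dim(d), c(3, 3))
})

test_that("per-cross distance lookup is label-based", {
  set.seed(3)
  ids <- c(paste0("L", 1:20), paste0("T", 1:6))
  m <- matrix(rnorm(26 * 4), 26, dimnames = list(ids, NULL))
  d <- phenotypic_distance(m)
  crosses <- expand.grid(line = paste0("L", 1:20),
                         tester = paste0("T", 1:6),
                         stringsAsFactors = FALSE)
  v <- cross_distance_lookup(d, crosses)
  expect_length(v, 120)
  expect_equal(unname(v["L3xT2"]), d["L3", "T2"])
  perm <- sample(26)
  v2 <- cross_distance_lookup(d[perm, perm], crosses)
  expect_equal(v2, v)
  expect_equal(unname(cross_distance_lookup(
    d, data.frame(line = "L1", tester = "L1"))), 0)
  expect_error(cross_distance_lookup(d, data.frame(line = "LX",
                                                   tester = "T1")), "LX")
})

test_that("Pearson correlation matches the direct covariance oracle", {
  set.seed(120)
  x <- rnorm(120); y <- rnorm(120)
  cr <- pearson_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$r, r_oracle, tolerance = 1e-12)
  expect_equal(cr$t, r_oracle * sqrt(118 / (1 - r_oracle^2)),
               tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(cr$p, ct$p.value, tolerance = 1e-10)

  lin <- pearson_correlation(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_equal(pearson_correlation(x, -0.5 * x + 3)$r, -1)
  ortho <- pearson_correlation(c(-1, 0, 1, 0), c(0, -1, 0, 1))
  expect_equal(ortho$r, 0)
  expect_error(pearson_correlation(x, rep(1, 120)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("correlation is affine-equivariant in sign", {
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50) + 0.5 * x
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 2, y)$r, r0,
               tolerance = 1e-12)
  expect_equal(pearson_correlation(-3 * x + 2, y)$r, -r0,
               tolerance = 1e-12)
})

test_that("PCA variance shares behave spectrally", {
  set.seed(6)
  base <- rnorm(40)
  two <- cbind(a = base, b = 2 * base + 5)
  expect_equal(pca_variance_shares(two)[1], 1, tolerance = 1e-10)
  m <- matrix(rnorm(5000 * 6), 5000, 6)
  sh <- pca_variance_shares(m)
  expect_true(all(diff(sh) <= 1e-12))
  expect_equal(sum(sh), 1)
  expect_true(all(abs(sh - 1 / 6) < 0.05))
  expect_error(pca_variance_shares(m[1, , drop = FALSE]), "2 entries")
})

test_that("the association grid aligns by cross id and reports 8 rows", {
  sim <- simulate_trial(l = 6, t = 4, r = 3, inbreeding_effect = 4,
                        seed = 17)
  fit <- lt_analysis(sim)
  het <- heterosis(fit, direction = "+")
  ca <- fit$effects$y
  set.seed(1)
  gd <- setNames(runif(24, 0.4, 1), het$cross)
  pd <- setNames(runif(24, 2, 8), het$cross)
  am <- association_matrix(gd, pd, het, ca, trait = "y")
  expect_equal(nrow(am), 8)
  expect_setequal(am$pair, c("GD-MPH", "GD-BPH", "GD-SCA", "PD-MPH",
                             "PD-BPH", "PD-SCA", "SCA-MPH", "SCA-BPH"))
  expect_true(all(abs(am$r) <= 1))
  # shuffling the named vectors must not change anything (id alignment)
  am2 <- association_matrix(gd[sample(24)], pd[sample(24)], het, ca,
                            trait = "y")
  expect_equal(am2$r, am$r, tolerance = 1e-12)
  expect_error(association_matrix(gd[-1], pd, het, ca), "missing")
  expect_error(association_matrix(unname(gd), pd, het, ca), "named")
})
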