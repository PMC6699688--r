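test_that("phenotype files round-trip and the design is inferred", {
  sim <- simulate_trial(l = 20, t = 6, r = 3, n_checks = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(sim$records, path)
  trial <- read_phenotypes(path)
  expect_equal(trial$design$l, 20)
  expect_equal(trial$design$t, 6)
  expect_equal(trial$design$r, 3)
  expect_length(trial$design$checks, 4)
  expect_equal(nrow(trial$records), 450)
  expect_equal(trial$records$y, sim$records$y, tolerance = 1e-12)
  expect_equal(trial$records$entry, sim$records$entry)
  bal <- check_balance(trial$records, trial$design)
  expect_true(bal$balanced)
  expect_equal(bal$expected, 450)
})

test_that("a crosses-only file still yields a minimal balanced design", {
  rec <- expand.grid(line = c("A", "B"), tester = c("X", "Y"), rep = 1:2,
                     stringsAsFactors = FALSE)
  rec <- data.frame(entry = paste0(rec$line, "x", rec$tester),
                    role = "cross", line = rec$line, tester = rec$tester,
                    rep = rec$rep, block = 1L, y = rnorm(8))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  trial <- read_phenotypes(path)
  expect_equal(trial$design$l, 2)
  expect_equal(trial$design$t, 2)
  expect_equal(trial$design$r, 2)
  expect_equal(nrow(trial$records), 8)
})

test_that("malformed phenotype files are rejected with a pointer", {
  toy <- toy_records()
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- toy$records
  bad$role[3] <- "mystery"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_phenotypes(path), "mystery")

  bad <- toy$records
  bad$tester[bad$entry == "AxX"] <- "Z"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_phenotypes(path), "Z")

  bad <- toy$records
  bad$rep[2] <- 1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_phenotypes(path), "duplicate")

  bad <- toy$records
  bad$y <- as.character(bad$y)
  bad$y[5] <- "oops"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_phenotypes(path), "row 5")
})

test_that("entry means average over replicates and ignore record order", {
  rec <- data.frame(entry = c("E1", "E1", "E1", "E2"),
                    role = "cross", line = "L", tester = "T",
                    rep = c(1, 2, 3, 1), block = 1,
                    y = c(10, 12, 14, 7))
  em <- entry_means(rec, "y")
  expect_equal(em$mean[em$entry == "E1"], 12)
  expect_equal(em$n[em$entry == "E1"], 3)
  expect_equal(em$mean[em$entry == "E2"], 7)
  em2 <- entry_means(rec[sample(4), ], "y")
  expect_equal(em2[order(em2$entry), c("mean", "n")],
               em[order(em$entry), c("mean", "n")])
  expect_error(entry_means(rec, "z"), "absent")
})

test_that("a fully degenerate trial has every entry mean at mu", {
  sim <- simulate_trial(l = 3, t = 2, r = 3, mu = 50, var_gca_line = 0,
                        var_gca_tester = 0, var_sca = 0, var_rep = 0,
                        var_error = 0, seed = 1)
  em <- entry_means(sim$records, "y")
  expect_true(all(em$mean == 50))
})

test_that("genotype files round-trip in both dialects", {
  sim <- simulate_markers(n_individuals = 8, n_loci = 5, n_subpops = 2,
                          missing_rate = 0.1, dh_flags = rep(FALSE, 8),
                          seed = 5)
  gm <- sim$genotypes
  for (dialect in c("two_column", "slash_pair")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_genotypes(gm, path, dialect = dialect)
    back <- read_genotypes(path, dialect = dialect)
    expect_equal(back$ids, gm$ids)
    expect_equal(back$loci, gm$loci)
    expect_equal(back$a1, gm$a1)
    expect_equal(back$a2, gm$a2)
  }
})

test_that("genotype parsing handles homozygotes, missing and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,M1,M2", "I1,180/180,NA", "I2,180/176,150/150"), path)
  gm <- read_genotypes(path, dialect = "slash_pair")
  expect_equal(unname(gm$a1["I1", "M1"]), "180")
  expect_equal(unname(gm$a2["I1", "M1"]), "180")
  expect_true(is.na(gm$a1["I1", "M2"]))
  expect_equal(unname(gm$a1["I2", "M1"]), "180")

  writeLines(c("id,M1.1,M1.2", "I1,180,NA"), path)
  expect_error(read_genotypes(path, dialect = "two_column"),
               "half-missing")
})

test_that("fixture tables read with schema validation", {
  ls <- read_fixture_table(extdata("table6_locus_stats.csv"),
                           "locus_stats")
  expect_equal(nrow(ls), 87)
  expect_true(all(c("locus", "Ho", "He", "N", "PIC") %in% names(ls)))

  ms <- read_fixture_table(extdata("table2_mean_squares.csv"),
                           "mean_squares")
  expect_equal(ms$CM[ms$source == "Line Effect"], 1054.16)

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("locus,Ho", path)
  expect_error(read_fixture_table(path, "locus_stats"), "empty|required")
  writeLines(c("locus,Ho", "a,0.1"), path)
  expect_error(read_fixture_table(path, "locus_stats"), "required")
})
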