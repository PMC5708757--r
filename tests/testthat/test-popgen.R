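test_that("squared band distance counts mismatching unmasked columns", {
  panel <- toy_panel(list(a = c("II", "II"), b = c("JJ", "JJ"),
                          c = c("II", "NN")))
  d <- band_sq_distance(band_matrix(panel))
  expect_equal(unname(d["a", "a"]), 0)
  expect_equal(unname(d["a", "b"]), 4)  # all four band columns differ
  expect_equal(unname(d["a", "c"]), 0)  # masked marker excluded pairwise
  expect_equal(unname(d["b", "c"]), 2)
  expect_true(isSymmetric(unclass(d)))
})

test_that("fully masked pairs are rejected by name", {
  panel <- toy_panel(list(a = c("II", "NN"), b = c("NN", "JJ"),
                          c = c("II", "JJ")))
  expect_error(band_sq_distance(band_matrix(panel)), "share no observed",
               class = "indelindex_computation_error")
})

test_that("grouped AMOVA sums of squares equal the brute-force double loop", {
  withr::with_seed(21, {
    for (k in 1:8) {
      n <- sample(5:8, 1)
      panel <- random_panel(n, 12, p_null = 0, seed = 100 + k)
      d2 <- unclass(band_sq_distance(band_matrix(panel)))
      pops <- sample(rep(c("x", "y"), length.out = n))
      while (min(table(pops)) < 2) pops <- sample(rep(c("x", "y"), length.out = n))
      brute <- brute_amova_ss(d2, pops)
      fit <- amova(d2, pops, n_perm = 0)
      s <- tidy(fit)
      expect_equal(s$ss[s$source == "total"], unname(brute["total"]),
                   tolerance = 1e-9)
      expect_equal(s$ss[s$source == "within populations"], unname(brute["within"]),
                   tolerance = 1e-9)
      expect_equal(s$ss[s$source == "among populations"], unname(brute["among"]),
                   tolerance = 1e-9)
      # bookkeeping invariants
      expect_equal(s$ss[3], s$ss[1] + s$ss[2])
      expect_equal(s$df[3], nrow(d2) - 1)
      expect_equal(sum(s$pct[1:2]), 100)
    }
  })
})

test_that("fixed allelic differences give Phi-PT of one", {
  rows <- c(lapply(1:4, function(i) rep("II", 6)),
            lapply(1:4, function(i) rep("JJ", 6)))
  names(rows) <- c(paste0("i", 1:4), paste0("j", 1:4))
  panel <- toy_panel(rows, toy_markers(6))
  fit <- amova(band_sq_distance(band_matrix(panel)),
               rep(c("p1", "p2"), each = 4), n_perm = 999, seed = 1)
  expect_equal(fit$phi_pt, 1)
  # only 2 of the C(8,4) = 70 label splits reproduce phi = 1, so the
  # add-one permutation P concentrates near 2/70
  expect_lt(fit$p_perm, 0.06)
})

test_that("Phi-PT is invariant to population relabeling and sample order", {
  panel <- random_panel(12, 10, seed = 9)
  d <- band_sq_distance(band_matrix(panel))
  pops <- rep(c("a", "b", "c"), each = 4)
  f1 <- amova(d, pops, n_perm = 0)
  f2 <- amova(d, c(a = "z", b = "y", c = "x")[pops], n_perm = 0)
  expect_equal(f1$phi_pt, f2$phi_pt)
  ord <- sample(1:12)
  f3 <- amova(unclass(d)[ord, ord], pops[ord], n_perm = 0)
  expect_equal(f1$phi_pt, f3$phi_pt)
})

test_that("permutation P is reproducible under a seed and absent when disabled", {
  panel <- random_panel(14, 12, seed = 4)
  d <- band_sq_distance(band_matrix(panel))
  pops <- rep(c("a", "b"), each = 7)
  f1 <- amova(d, pops, n_perm = 199, seed = 7)
  f2 <- amova(d, pops, n_perm = 199, seed = 7)
  expect_identical(f1$p_perm, f2$p_perm)
  f0 <- amova(d, pops, n_perm = 0)
  expect_true(is.na(f0$p_perm))
  expect_error(amova(d, c(rep("a", 13), "b"), n_perm = 0),
               "singleton", class = "indelindex_validation_error")
})

test_that("diversity indices match closed forms", {
  panel <- toy_panel(list(a = c("II", "II", "II"), b = c("II", "JJ", "IJ"),
                          c = c("II", "JJ", "IJ"), d = c("II", "JJ", "IJ")),
                     toy_markers(3))
  div <- diversity_stats(panel, rep("p", 4))
  m1 <- div[div$marker_id == "T1", ]
  expect_equal(m1$na, 1)
  expect_equal(m1$ne, 1)
  expect_equal(m1$shannon_i, 0)
  expect_equal(m1$he, 0)
  m2 <- div[div$marker_id == "T2", ]  # p = (0.25, 0.75)
  expect_equal(m2$he, 1 - 0.25^2 - 0.75^2)
  m3 <- div[div$marker_id == "T3", ]  # p = (0.625, 0.375)
  expect_equal(m3$ne, 1 / (0.625^2 + 0.375^2))
  expect_equal(m3$uhe, 8 / 7 * m3$he)
  expect_true(all(div$ne <= div$na + 1e-12))
  expect_true(all(div$uhe >= div$he))
})

test_that("the unbiased correction applies the 2n/(2n-1) factor", {
  rows <- lapply(1:10, function(i) if (i <= 5) "II" else "JJ")
  names(rows) <- paste0("s", 1:10)
  panel <- toy_panel(rows, toy_markers(1))
  div <- diversity_stats(panel, rep("p", 10))
  expect_equal(div$he, 0.5)
  expect_equal(div$uhe, 20 / 19 * 0.5)
  smry <- diversity_summary(div)
  expect_equal(smry$mean[smry$index == "he"], 0.5)
  expect_equal(smry$n_loci, rep(1, 5))
})

test_that("populations without scored samples at a locus are skipped with warning", {
  panel <- toy_panel(list(a = c("II", "NN"), b = c("II", "NN"),
                          c = c("JJ", "JJ"), d = c("JJ", "IJ")))
  expect_warning(div <- diversity_stats(panel, rep(c("p1", "p2"), each = 2)),
                 "no scored samples")
  expect_equal(nrow(div), 3)
  expect_error(diversity_stats(panel, rep("p", 3)),
               class = "indelindex_validation_error")
})
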