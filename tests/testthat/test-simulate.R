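test_that("simulation is deterministic under a seed", {
  cfg <- sim_config(n_loci = 12, populations = sim_populations(
    c("a", "b"), c(6, 6), c(2, 18), c(18, 2)))
  s1 <- simulate_panel(cfg, seed = 99)
  s2 <- simulate_panel(cfg, seed = 99)
  expect_identical(s1$panel$calls, s2$panel$calls)
  expect_identical(s1$truth$loci, s2$truth$loci)
  s3 <- simulate_panel(cfg, seed = 100)
  expect_false(identical(s1$panel$calls, s3$panel$calls))
})

test_that("the study-scale preset has the study's panel dimensions", {
  cfg <- paper_scale_preset()
  sim <- simulate_panel(cfg, seed = 1)
  expect_equal(dim(sim$panel), c(192, 42))
  expect_true(all(c("REF_INDICA", "REF_JAPONICA") %in% sim$panel$calls$sample_id))
  # one triallelic locus carries a non-reference band
  expect_equal(sum(lengths(sim$panel$markers$band_sizes) == 3), 1)
  # census dominated by the indica side
  ix <- classify_panel(sim$panel)
  cen <- class_census(ix)
  indica_side <- sum(cen$n[cen$class <= "close to indica"])
  expect_gt(indica_side / sum(cen$n), 0.5)
  expect_equal(as.character(ix$class[ix$sample_id == "REF_INDICA"]),
               "typical indica")
  expect_equal(as.character(ix$class[ix$sample_id == "REF_JAPONICA"]),
               "typical japonica")
})

test_that("recovered index equals realized truth when overlays are off", {
  cfg <- sim_config(n_loci = 30, n_triallelic = 0,
                    populations = sim_populations(c("a", "b"), c(15, 15),
                                                  c(2, 12), c(8, 3)),
                    het_rate = 0, null_rate = 0, x_allele_rate = 0)
  sim <- simulate_panel(cfg, seed = 42)
  ix <- classify_panel(sim$panel)
  expect_equal(ix$f_j, sim$truth$samples$f_j_realized)
  # and the classification census matches the truth-derived census exactly
  expect_identical(class_census(ix)$n,
                   class_census(tibble::tibble(
                     class = classify_index(sim$truth$samples$f_j_realized)))$n)
})

test_that("degenerate Beta parameters drive all samples to the indica extreme", {
  cfg <- sim_config(n_loci = 20, n_triallelic = 0,
                    populations = sim_populations("a", 10, 0.001, 50),
                    het_rate = 0, null_rate = 0)
  sim <- simulate_panel(cfg, seed = 3)
  ix <- classify_panel(sim$panel)
  expect_true(all(ix$class == "typical indica"))
})

test_that("emitted heterozygosity and null rates match the configuration", {
  cfg <- sim_config(n_loci = 42, n_triallelic = 0,
                    populations = sim_populations("a", 100, 2, 8),
                    het_rate = 0.05, null_rate = 0.01)
  sim <- simulate_panel(cfg, seed = 11)
  ps <- panel_summary(sim$panel)
  n_calls <- 100 * 42
  het_hat <- sum(ps$samples$n_het) / n_calls
  null_hat <- sum(ps$samples$n_null) / n_calls
  # binomial 4-sigma envelopes around the configured rates
  expect_lt(abs(het_hat - 0.05), 4 * sqrt(0.05 * 0.95 / n_calls))
  expect_lt(abs(null_hat - 0.01), 4 * sqrt(0.01 * 0.99 / n_calls))
})

test_that("divergent Beta spectra yield strong differentiation across replicates", {
  hits <- 0
  for (k in 1:20) {
    sim <- simulate_panel(sim_config(
      n_loci = 42, populations = sim_populations(c("a", "b"), c(24, 24),
                                                 c(2, 18), c(18, 2))),
      seed = 500 + k)
    fit <- amova(band_sq_distance(band_matrix(sim$panel)),
                 sim$truth$samples$population, n_perm = 0)
    if (fit$phi_pt > 0.5) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of replicates
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(het_rate = 1.5), class = "indelindex_validation_error")
  expect_error(sim_populations("a", 1, 1, 1), class = "indelindex_validation_error")
  expect_error(sim_populations("a", 5, -1, 1), class = "indelindex_validation_error")
  expect_error(sim_config(n_loci = 4, n_triallelic = 9),
               class = "indelindex_validation_error")
})

test_that("simulated panels round-trip through the file formats with truth sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_panel(sim_config(n_loci = 8, populations = sim_populations(
    c("a", "b"), c(4, 4), c(2, 8), c(8, 2))), seed = 6)
  paths <- write_sim_panel(sim, dir, header = "sim")
  mk <- read_marker_metadata(paths[["markers"]])
  panel <- read_genotype_table(paths[["genotypes"]], mk,
                               samples = paths[["samples"]])
  expect_identical(panel$calls, sim$panel$calls)
  expect_equal(panel$samples$population, sim$panel$samples$population)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$samples$f_j_realized, sim$truth$samples$f_j_realized)
})
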