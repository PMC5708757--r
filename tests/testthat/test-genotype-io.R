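mk_fixture <- read_marker_metadata(indel_marker_fixture())

test_that("marker metadata fixture parses with published band structure", {
  expect_equal(nrow(mk_fixture), 42)
  r2m37 <- mk_fixture[mk_fixture$marker_id == "R2M37", ]
  expect_equal(r2m37$band_sizes[[1]], c(211L, 151L))
  expect_equal(r2m37$indel_size, 60L)
  r3m37 <- mk_fixture[mk_fixture$marker_id == "R3M37", ]
  expect_length(r3m37$band_sizes[[1]], 3)
  expect_equal(r3m37$indica_band, 194L)
  expect_equal(r3m37$japonica_band, 282L)
  expect_true(mk_fixture$dominant[mk_fixture$marker_id == "R1M37"])
  expect_true(all(mk_fixture$chromosome %in% 1:12))
})

test_that("marker metadata validation rejects malformed tables", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("marker_id\tchromosome\tband_sizes\tindica_band\tjaponica_band\tindel_size\tdominant",
             tmp)
  expect_error(read_marker_metadata(tmp), "no marker rows",
               class = "indelindex_validation_error")

  mk <- toy_markers(2)
  mk$marker_id <- c("A", "A")
  expect_error(validate_markers(mk), "duplicate",
               class = "indelindex_validation_error")

  mk <- toy_markers(2)
  mk$chromosome[1] <- 13L
  expect_error(validate_markers(mk), "chromosome",
               class = "indelindex_validation_error")

  mk <- toy_markers(1)
  mk$japonica_band[1] <- mk$indica_band[1]
  mk$band_sizes[[1]] <- rep(mk$indica_band[1], 2)
  expect_error(validate_markers(mk), class = "indelindex_validation_error")

  writeLines(c("marker_id\tchromosome\tband_sizes\tindica_band\tjaponica_band\tindel_size\tdominant",
               "A\t1\tfoo,bar\t200\t150\t50\tFALSE"), tmp)
  expect_error(read_marker_metadata(tmp), "unparseable",
               class = "indelindex_validation_error")
})

test_that("band profiles score to the expected codominant calls", {
  r2m37 <- mk_fixture[mk_fixture$marker_id == "R2M37", ]
  r3m37 <- mk_fixture[mk_fixture$marker_id == "R3M37", ]
  expect_equal(score_bands(151, r2m37), "JJ")
  expect_equal(score_bands(211, r2m37), "II")
  expect_equal(score_bands(c(211, 151), r2m37), "IJ")
  expect_equal(score_bands(c(282, 194), r3m37), "IJ")
  expect_equal(score_bands(240, r3m37), "XX")
  expect_equal(score_bands(c(194, 240), r3m37), "IX")
  expect_equal(score_bands(integer(0), r2m37), "NN")
})

test_that("band scoring is order-invariant and respects tolerance", {
  r3m37 <- mk_fixture[mk_fixture$marker_id == "R3M37", ]
  expect_equal(score_bands(c(194, 282), r3m37), score_bands(c(282, 194), r3m37))
  r2m37 <- mk_fixture[mk_fixture$marker_id == "R2M37", ]
  expect_equal(score_bands(153, r2m37, tolerance_bp = 2), "JJ")
  expect_error(score_bands(153, r2m37, tolerance_bp = 0), "matches no catalogued",
               class = "indelindex_computation_error")
  expect_error(score_bands(c(282, 240, 194), r3m37), "manual review",
               class = "indelindex_computation_error")
})

test_that("dominant markers score band absence as the band-lacking reference", {
  r1m37 <- mk_fixture[mk_fixture$marker_id == "R1M37", ]
  expect_equal(score_bands(167, r1m37), "JJ")      # band present in Dongjinbyeo
  expect_equal(score_bands(integer(0), r1m37), "II")  # absence = Swarna-like
})

test_that("genotype tables round-trip through CSV including band-size cells", {
  mk <- toy_markers(2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,T1,T2",
               "s1,II,220/170",
               "s2,ji,NN",
               "s3,,JJ"), tmp)
  panel <- read_genotype_table(tmp, mk)
  expect_equal(unname(as.matrix(panel$calls[-1])),
               rbind(c("II", "IJ"), c("IJ", "NN"), c("NN", "JJ")))

  out <- withr::local_tempdir()
  write_genotype_table(panel, out, header = "round trip")
  back <- read_genotype_table(file.path(out, "genotypes.csv"), mk)
  expect_identical(back$calls, panel$calls)
})

test_that("genotype table validation names the offending cell", {
  mk <- toy_markers(1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,T9", "s1,II"), tmp)
  expect_error(read_genotype_table(tmp, mk), "T9",
               class = "indelindex_validation_error")
  writeLines(c("sample_id,T1", "s1,QQ"), tmp)
  expect_error(read_genotype_table(tmp, mk), "QQ",
               class = "indelindex_validation_error")
  writeLines(c("sample_id,T1", "s1,II", "s1,JJ"), tmp)
  expect_error(read_genotype_table(tmp, mk), "duplicate",
               class = "indelindex_validation_error")
})

test_that("band matrix expansion honours its invariants", {
  panel <- toy_panel(list(s1 = c("II", "II"), s2 = c("IJ", "NN"),
                          s3 = c("JJ", "II")))
  bm <- band_matrix(panel)
  expect_equal(ncol(bm$x), 4)
  expect_equal(bm$bands$role, rep(c("indica", "japonica"), 2))
  # all-II sample: indica bands first -> (1,0,1,0)
  expect_equal(unname(bm$x["s1", ]), c(1L, 0L, 1L, 0L))
  # heterozygote lights both bands of its marker
  expect_equal(unname(bm$x["s2", 1:2]), c(1L, 1L))
  # null call masks the marker's columns
  expect_true(all(is.na(bm$x["s2", 3:4])))
  expect_equal(unname(bm$mask["s2", ]), c(TRUE, TRUE, FALSE, FALSE))
  # no-null no-het panel: exactly one presence per marker per sample
  pnl2 <- toy_panel(list(a = c("II", "JJ"), b = c("JJ", "II")))
  bm2 <- band_matrix(pnl2)
  per_marker <- sapply(split(seq_len(4), bm2$bands$marker_id),
                       function(j) rowSums(bm2$x[, j, drop = FALSE]))
  expect_true(all(per_marker == 1))
})

test_that("triallelic X calls and dominant markers expand correctly", {
  mk <- toy_markers(2, triallelic = TRUE)
  panel <- toy_panel(list(s1 = c("IX", "II"), s2 = c("XX", "JJ")), mk)
  bm <- band_matrix(panel)
  expect_equal(bm$bands$role[bm$bands$marker_id == "T1"],
               c("indica", "japonica", "other"))
  expect_equal(unname(bm$x["s1", 1:3]), c(1L, 0L, 1L))
  expect_equal(unname(bm$x["s2", 1:3]), c(0L, 0L, 1L))

  mkd <- toy_markers(2, dominant_first = TRUE)
  pd <- toy_panel(list(s1 = c("JJ", "II"), s2 = c("II", "II")), mkd)
  bmd <- band_matrix(pd)
  expect_equal(sum(bmd$bands$marker_id == "T1"), 1)  # single presence column
  expect_equal(unname(bmd$x[, 1]), c(1L, 0L))
})

test_that("panel summary counts heterozygous and null profiles", {
  rows <- list(
    dowana = c(rep("IJ", 7), rep("II", 35)),
    plain = rep("II", 42),
    nully = c(rep("NN", 2), rep("JJ", 40)))
  panel <- toy_panel(rows, toy_markers(42))
  ps <- panel_summary(panel)
  expect_equal(ps$samples$n_het, c(7, 0, 0))
  expect_equal(ps$samples$n_null, c(0, 0, 2))
  expect_equal(ps$samples$n_scored, c(42, 42, 40))
  expect_equal(sum(ps$markers$n_null), 2)
  expect_equal(ps$totals$n_het_samples, 1)
  expect_equal(ps$totals$n_null_samples, 1)
})
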