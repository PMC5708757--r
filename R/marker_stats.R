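#' Gene-count allele frequencies at one marker
#'
#' Each homozygote contributes two copies of its allele, each heterozygote
#' one copy of each of its two alleles; null calls are excluded. Alleles are
#' labelled by their role letter: I (indica reference band), J (japonica
#' reference band), X (non-reference band).
#'
#' @param calls character vector of genotype calls at one marker
#' @return tibble with `allele` and `freq` (frequencies sum to 1 over
#'   observed roles I, J, X)
#' @export
marker_allele_freqs <- function(calls) {
  calls <- canonical_call(calls)
  scored <- calls[calls != "NN"]
  if (length(scored) == 0) stop_computation("all calls null at this marker")
  counts <- unname(vapply(allele_order, function(l) sum(allele_count(scored, l)),
                          numeric(1)))
  tibble::tibble(allele = allele_order, freq = counts / (2 * length(scored)))
}

#' Polymorphic information content
#'
#' PIC = 1 - sum(p_i^2) over allele frequencies p_i. For a locus with k
#' alleles the maximum is 1 - 1/k (0.5 for a biallelic InDel).
#'
#' @param p numeric vector of allele frequencies summing to 1
#' @return PIC in \[0, 1\]
#' @export
#' @examples
#' pic(c(0.5, 0.5))  # 0.5
pic <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stop_validation("allele frequencies must sum to 1")
  1 - sum(p^2)
}

#' Band informativeness and resolving power
#'
#' `band_informativeness()` computes I_b = 1 - 2 * |0.5 - p| for a band
#' present in a proportion p of genotypes; `resolving_power()` sums I_b over
#' a marker's bands (R_p).
#'
#' @param p proportion(s) of genotypes containing a band, in \[0, 1\]
#' @return I_b value(s) in \[0, 1\], or their sum for `resolving_power()`
#' @export
band_informativeness <- function(p) {
  if (any(p < 0 | p > 1)) stop_validation("band proportion must be in [0, 1]")
  1 - 2 * abs(0.5 - p)
}

#' @rdname band_informativeness
#' @export
resolving_power <- function(p) sum(band_informativeness(p))

#' Effective multiplex ratio and marker index
#'
#' EMR = NPA x PPA (number of polymorphic amplicons times the proportion of
#' polymorphic amplicons per assay); MI = PIC x EMR.
#'
#' @param npa number of polymorphic amplicons (bands) of the marker
#' @param ppa proportion of polymorphic amplicons
#' @return EMR, respectively MI
#' @export
emr <- function(npa, ppa) {
  if (any(npa < 0)) stop_validation("npa must be >= 0")
  npa * ppa
}

#' @rdname emr
#' @param pic_value PIC of the marker
#' @param emr_value EMR of the marker
#' @export
marker_index <- function(pic_value, emr_value) pic_value * emr_value

#' Per-marker informativeness report
#'
#' Computes, for every marker of a panel: gene-count allele frequencies,
#' PIC, per-band informativeness and resolving power Rp, the number of
#' polymorphic amplicons NPA, EMR and MI, and the marker's rare bands
#' (present in fewer than `rare_threshold` of samples). Band proportions
#' for Rp use the fraction of samples whose genotype contains the band,
#' over samples where the marker amplified.
#'
#' PPA is not derivable from a stated formula when it exceeds 1; when the
#' marker table carries a printed `ppa` column it is used as-is (and printed
#' `pic`/`rp`/`mi` are echoed for comparison). With `recompute_ppa = TRUE`
#' the report instead uses PPA = NPA / (total bands), which does not
#' reproduce published marker-index tables and is labelled by the
#' `ppa_source` column.
#'
#' @param panel an [indel_panel()]
#' @param rare_threshold rarity cutoff passed to [rare_alleles()]
#' @param recompute_ppa logical; see Details
#' @return tibble with one row per marker (list-columns `allele_freq` and
#'   `rare_bands`); printed columns, when available, appear as
#'   `pic_printed` etc. together with `mi_consistent` flags
#' @export
marker_report <- function(panel, rare_threshold = 0.05, recompute_ppa = FALSE) {
  mat <- as.matrix(panel$calls[-1])
  bm <- band_matrix(panel)
  rare <- rare_alleles(bm, rare_threshold)

  rows <- purrr::map_dfr(seq_len(nrow(panel$markers)), function(i) {
    m <- panel$markers[i, ]
    cc <- mat[, m$marker_id]
    freqs <- marker_allele_freqs(cc)
    obs <- freqs$freq[freqs$freq > 0]
    keep <- bm$bands$marker_id == m$marker_id
    p_band <- colMeans(bm$x[, keep, drop = FALSE], na.rm = TRUE)
    npa <- length(m$band_sizes[[1]])
    if (isTRUE(m$dominant)) npa <- 2L  # presence and absence segregate as two alleles
    ppa <- if (!recompute_ppa && "ppa" %in% names(panel$markers)) {
      m$ppa
    } else {
      npa / length(m$band_sizes[[1]])
    }
    pic_v <- pic(freqs$freq)
    emr_v <- emr(npa, ppa)
    tibble::tibble(
      marker_id = m$marker_id,
      n_scored = sum(cc != "NN"),
      n_null = sum(cc == "NN"),
      n_alleles = length(obs),
      allele_freq = list(freqs),
      pic = pic_v,
      rp = resolving_power(p_band),
      npa = npa,
      ppa = ppa,
      ppa_source = if (!recompute_ppa && "ppa" %in% names(panel$markers))
        "table" else "recomputed",
      emr = emr_v,
      mi = marker_index(pic_v, emr_v),
      rare_bands = list(rare$band_id[rare$marker_id == m$marker_id & rare$rare])
    )
  })
  printed <- intersect(c("pic", "rp", "npa", "ppa", "emr", "mi"),
                       names(panel$markers))
  if (length(printed) > 0) {
    pr <- panel$markers[, c("marker_id", printed)]
    names(pr)[-1] <- paste0(printed, "_printed")
    rows <- dplyr::left_join(rows, pr, by = "marker_id")
    if (all(c("pic_printed", "emr_printed", "mi_printed") %in% names(rows))) {
      rows$mi_consistent <-
        abs(rows$pic_printed * rows$emr_printed - rows$mi_printed) <= 0.01 + 1e-9
    }
    if ("pic_printed" %in% names(rows)) {
      rows$pic_discrepant <- abs(rows$pic - rows$pic_printed) > 0.05
    }
  }
  rows
}

#' Column summaries of a marker report
#'
#' Ranges and threshold counts over a set of marker statistics: PIC and Rp
#' ranges, counts of markers with Rp above 1 and with PIC in the
#' "ideal" 0.35-0.50 window, MI range.
#'
#' @param report a tibble of per-marker statistics with columns `pic`, `rp`,
#'   `emr`, `mi` (e.g. from [marker_report()], or a printed marker table)
#' @return one-row tibble of summaries
#' @export
summarise_marker_stats <- function(report) {
  tibble::tibble(
    n_markers = nrow(report),
    pic_min = min(report$pic), pic_max = max(report$pic),
    rp_min = min(report$rp), rp_max = max(report$rp),
    emr_min = min(report$emr), emr_max = max(report$emr),
    mi_min = min(report$mi), mi_max = max(report$mi),
    n_rp_gt_1 = sum(report$rp > 1.0),
    n_pic_ideal = sum(report$pic >= 0.35 & report$pic <= 0.50),
    n_mi_gt_1 = sum(report$mi > 1.0)
  )
}

#' Internal-consistency check of a printed marker statistics table
#'
#' Recomputes MI as PIC x EMR from the printed PIC and EMR columns of a
#' marker metadata table and reports the absolute difference from the
#' printed MI.
#'
#' @param markers marker tibble with printed `pic`, `emr`, `mi` columns
#' @return tibble: `marker_id`, `pic`, `emr`, `mi_printed`, `mi_recomputed`,
#'   `abs_err`
#' @export
marker_stat_consistency <- function(markers) {
  need <- c("pic", "emr", "mi")
  if (!all(need %in% names(markers)))
    stop_validation("marker table lacks printed columns: %s",
                    paste(setdiff(need, names(markers)), collapse = ", "))
  tibble::tibble(
    marker_id = markers$marker_id,
    pic = markers$pic,
    emr = markers$emr,
    mi_printed = markers$mi,
    mi_recomputed = markers$pic * markers$emr,
    abs_err = abs(markers$pic * markers$emr - markers$mi)
  )
}
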