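#' Subspecies classes assigned by the InDel molecular index
#'
#' Seven ordered classes from typical indica to typical japonica.
#' @return character vector of class labels in increasing japonica-allele
#'   frequency order
#' @export
subspecies_levels <- function() {
  c("typical indica", "indica", "close to indica", "intermediate",
    "close to japonica", "japonica", "typical japonica")
}

# Upper bounds of the half-open F_j intervals for the first six classes; the
# last class closes at 1. Published bands are two-decimal roundings
# (e.g. 0.11-0.25 for "indica"); the gaps between printed bands are closed
# at their midpoints so that the map is total on [0, 1].
fj_breaks <- function() c(0.105, 0.255, 0.395, 0.605, 0.745, 0.895)

#' Classify a japonica-specific allele frequency into a subspecies class
#'
#' Maps F_j through contiguous half-open intervals:
#' \[0, 0.105) typical indica, \[0.105, 0.255) indica, \[0.255, 0.395)
#' close to indica, \[0.395, 0.605) intermediate, \[0.605, 0.745) close to
#' japonica, \[0.745, 0.895) japonica, \[0.895, 1\] typical japonica.
#'
#' @param f_j numeric vector of japonica-specific allele frequencies in
#'   \[0, 1\]; NA propagates
#' @return ordered factor with levels [subspecies_levels()]
#' @export
#' @examples
#' classify_index(c(0.05, 0.50, 0.65))
classify_index <- function(f_j) {
  ok <- is.na(f_j) | (f_j >= 0 & f_j <= 1)
  if (!all(ok))
    stop_validation("F_j out of [0, 1]: %s", paste(f_j[!ok], collapse = ", "))
  idx <- findInterval(f_j, fj_breaks()) + 1L
  factor(subspecies_levels()[idx], levels = subspecies_levels(), ordered = TRUE)
}

#' Per-sample indica/japonica allele frequencies
#'
#' Computes the InDel molecular index of one accession from its genotype
#' calls: F_i = (2 n_II + n_IJ + n_IX) / (2 N_eff) and
#' F_j = (2 n_JJ + n_IJ + n_JX) / (2 N_eff), where N_eff is the number of
#' non-null loci. Null loci carry no scorable allele and are excluded from
#' the denominator; X alleles (bands matching neither reference) count in
#' the denominator but in neither numerator, so they dilute F_i and F_j
#' symmetrically.
#'
#' @param calls character vector of genotype call codes for one sample
#' @return one-row tibble: `f_i`, `f_j`, `n_scored`, `n_het`, `n_null`,
#'   `n_x`
#' @export
#' @examples
#' allele_frequencies(c(rep("II", 30), rep("JJ", 10), rep("IJ", 2)))
allele_frequencies <- function(calls) {
  calls <- canonical_call(calls)
  if (anyNA(calls)) stop_validation("invalid genotype code in calls")
  n_null <- sum(calls == "NN")
  n_eff <- length(calls) - n_null
  if (n_eff == 0)
    stop_computation("all loci null: InDel molecular index undefined")
  scored <- calls[calls != "NN"]
  tibble::tibble(
    f_i = sum(allele_count(scored, "I")) / (2 * n_eff),
    f_j = sum(allele_count(scored, "J")) / (2 * n_eff),
    n_scored = n_eff,
    n_het = sum(is_het_call(scored)),
    n_null = n_null,
    n_x = sum(grepl("X", scored, fixed = TRUE))
  )
}

#' Heterozygous-call proportion of a sample
#'
#' @param calls character vector of genotype call codes for one sample
#' @return percentage of scored (non-null) loci with a heterozygous call,
#'   rounded to one decimal
#' @export
#' @examples
#' het_proportion(c(rep("II", 35), rep("IJ", 7)))  # 16.7
het_proportion <- function(calls) {
  calls <- canonical_call(calls)
  n_scored <- sum(calls != "NN")
  if (n_scored == 0) stop_computation("no scored loci: heterozygosity undefined")
  round(100 * sum(is_het_call(calls)) / n_scored, 1)
}

#' Compute the InDel molecular index and subspecies class for a whole panel
#'
#' Applies [allele_frequencies()] and [classify_index()] to every sample.
#' Samples whose loci are all null get NA index values and class (with a
#' warning) rather than aborting the panel.
#'
#' @param panel an [indel_panel()]
#' @return a tibble of class `indel_index` with one row per sample:
#'   `sample_id`, `f_i`, `f_j`, `n_scored`, `n_het`, `n_null`, `n_x`,
#'   `class`
#' @export
classify_panel <- function(panel) {
  mat <- as.matrix(panel$calls[-1])
  rows <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    tryCatch(allele_frequencies(mat[i, ]),
             indelindex_computation_error = function(e) {
               warning(sprintf("sample '%s': %s", panel$calls$sample_id[i],
                               conditionMessage(e)), call. = FALSE)
               tibble::tibble(f_i = NA_real_, f_j = NA_real_,
                              n_scored = 0L, n_het = 0L,
                              n_null = ncol(mat), n_x = 0L)
             })
  })
  out <- dplyr::bind_cols(tibble::tibble(sample_id = panel$calls$sample_id), rows)
  out$class <- classify_index(out$f_j)
  class(out) <- c("indel_index", class(out))
  out
}

#' Census of subspecies classes
#'
#' @param index an `indel_index` tibble from [classify_panel()]
#' @return tibble with `class` and `n`, covering all seven classes
#' @export
class_census <- function(index) {
  tab <- table(factor(index$class, levels = subspecies_levels()))
  tibble::tibble(class = factor(names(tab), levels = subspecies_levels(),
                                ordered = TRUE),
                 n = as.integer(tab))
}

#' Propose the two populations used for molecular variance partitioning
#'
#' Splits classified samples into population 1 (typical indica, indica and
#' close to indica) and population 2 (intermediate through typical
#' japonica), the grouping under which between-group differentiation is
#' tested by [amova()].
#'
#' @param index an `indel_index` tibble from [classify_panel()]
#' @return factor of "population-1"/"population-2" aligned with
#'   `index$sample_id` (NA class gives NA)
#' @export
proposed_populations <- function(index) {
  japonica_side <- c("intermediate", "close to japonica", "japonica",
                     "typical japonica")
  factor(ifelse(is.na(index$class), NA,
                ifelse(index$class %in% japonica_side,
                       "population-2", "population-1")),
         levels = c("population-1", "population-2"))
}
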