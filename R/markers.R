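#' Read an InDel marker metadata table
#'
#' Parses a tab-separated marker description file into a validated marker
#' tibble. The expected columns are `marker_id`, `chromosome` (1-12),
#' `band_sizes` (comma-separated allele sizes in bp, largest first by
#' convention), `indica_band` and `japonica_band` (the allele carried by the
#' indica and japonica reference cultivar; one may be NA for a dominant
#' marker), `indel_size` (bp, NA allowed for dominant markers) and `dominant`
#' (logical; a single scorable presence/absence band). Additional columns
#' (for example published informativeness statistics) are preserved as-is.
#' Lines starting with `#` are treated as comments.
#'
#' The 42-marker panel used throughout the package documentation ships as
#' `system.file("extdata", "markers_table1.tsv", package = "indelindex")`.
#'
#' @param path path to a TSV file with a header row and one row per marker
#' @return a tibble with one row per marker, `band_sizes` as a list-column of
#'   integer vectors, in file order
#' @export
#' @examples
#' mk <- read_marker_metadata(indel_marker_fixture())
#' mk[mk$marker_id == "R2M37", c("marker_id", "indica_band", "japonica_band")]
read_marker_metadata <- function(path) {
  if (!file.exists(path)) stop_validation("marker metadata file not found: %s", path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        na = c("", "NA"), progress = FALSE,
                        col_types = readr::cols(band_sizes = readr::col_character(),
                                                marker_id = readr::col_character()))
  if (nrow(df) == 0) stop_validation("marker metadata file %s contains no marker rows", path)
  required <- c("marker_id", "chromosome", "band_sizes", "indica_band",
                "japonica_band", "indel_size", "dominant")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_validation("marker metadata is missing column(s): %s",
                    paste(missing, collapse = ", "))
  df$marker_id <- as.character(df$marker_id)
  df$band_sizes <- lapply(strsplit(as.character(df$band_sizes), ","), function(b) {
    out <- suppressWarnings(as.integer(trimws(b)))
    if (length(out) == 0 || anyNA(out))
      stop_validation("unparseable band_sizes entry: '%s'", paste(b, collapse = ","))
    out
  })
  df$chromosome <- as.integer(df$chromosome)
  df$indica_band <- as.integer(df$indica_band)
  df$japonica_band <- as.integer(df$japonica_band)
  df$indel_size <- as.integer(df$indel_size)
  df$dominant <- as.logical(df$dominant)
  validate_markers(tibble::as_tibble(df))
}

#' Path to the bundled 42-marker panel definition
#'
#' @return path to the packaged marker metadata fixture
#' @export
indel_marker_fixture <- function() {
  system.file("extdata", "markers_table1.tsv", package = "indelindex",
              mustWork = TRUE)
}

#' Validate a marker tibble
#'
#' Enforces the marker-table invariants: unique marker ids, chromosomes in
#' 1-12, strictly positive unique band sizes per marker, distinct reference
#' bands when both are present, both references catalogued for codominant
#' markers.
#'
#' @param markers a marker tibble as returned by [read_marker_metadata()]
#' @return the validated tibble, invisibly identical to the input
#' @export
validate_markers <- function(markers) {
  if (anyDuplicated(markers$marker_id))
    stop_validation("duplicate marker_id: %s",
                    paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
                          collapse = ", "))
  bad_chr <- is.na(markers$chromosome) | markers$chromosome < 1L | markers$chromosome > 12L
  if (any(bad_chr))
    stop_validation("chromosome outside 1-12 for marker(s): %s",
                    paste(markers$marker_id[bad_chr], collapse = ", "))
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    bands <- m$band_sizes[[1]]
    if (any(bands <= 0) || anyDuplicated(bands))
      stop_validation("marker %s: band sizes must be positive and unique", m$marker_id)
    refs <- c(m$indica_band, m$japonica_band)
    if (!any(is.na(refs)) && refs[1] == refs[2])
      stop_validation("marker %s: indica and japonica reference bands are identical",
                      m$marker_id)
    if (!isTRUE(m$dominant)) {
      if (any(is.na(refs)))
        stop_validation("marker %s: codominant marker needs both reference bands",
                        m$marker_id)
      if (!all(refs %in% bands))
        stop_validation("marker %s: reference band not in catalogued band sizes",
                        m$marker_id)
    } else {
      if (all(is.na(refs)))
        stop_validation("marker %s: dominant marker needs one reference band",
                        m$marker_id)
      if (!all(refs[!is.na(refs)] %in% bands))
        stop_validation("marker %s: reference band not in catalogued band sizes",
                        m$marker_id)
    }
    if (!is.na(m$indel_size) && m$indel_size < 0)
      stop_validation("marker %s: negative indel_size", m$marker_id)
  }
  markers
}

# Non-reference ("other") bands of a marker, in catalogued order.
other_bands <- function(marker_row) {
  bands <- marker_row$band_sizes[[1]]
  refs <- c(marker_row$indica_band, marker_row$japonica_band)
  setdiff(bands, refs[!is.na(refs)])
}
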