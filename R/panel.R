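#' Construct a genotype panel
#'
#' Bundles a wide sample-by-marker table of codominant genotype calls with
#' its marker definitions and optional per-sample metadata. Calls use the
#' two-letter codes `II` (homozygous indica), `JJ` (homozygous japonica),
#' `IJ` (heterozygous), `NN` (null / no amplification) and, for markers with
#' non-reference alleles, `IX`, `JX`, `XX` where `X` is a band matching
#' neither reference cultivar.
#'
#' @param calls a data frame whose first column is `sample_id` and whose
#'   remaining columns are genotype call codes, one column per marker in
#'   `markers$marker_id`
#' @param markers a marker tibble (see [read_marker_metadata()])
#' @param samples optional per-sample metadata: a data frame with a
#'   `sample_id` column and any of `population`, `latitude`, `longitude`,
#'   `altitude_m`
#' @return an `indel_panel` object: a list with elements `calls`, `markers`
#'   and `samples`
#' @export
indel_panel <- function(calls, markers, samples = NULL) {
  markers <- validate_markers(tibble::as_tibble(markers))
  calls <- tibble::as_tibble(calls)
  if (names(calls)[1] != "sample_id")
    stop_validation("first column of the call table must be 'sample_id'")
  calls$sample_id <- as.character(calls$sample_id)
  if (anyDuplicated(calls$sample_id))
    stop_validation("duplicate sample_id: %s",
                    paste(unique(calls$sample_id[duplicated(calls$sample_id)]),
                          collapse = ", "))
  unknown <- setdiff(names(calls)[-1], markers$marker_id)
  if (length(unknown) > 0)
    stop_validation("call columns not in marker metadata: %s",
                    paste(unknown, collapse = ", "))
  absent <- setdiff(markers$marker_id, names(calls)[-1])
  if (length(absent) > 0)
    stop_validation("marker(s) missing from call table: %s",
                    paste(absent, collapse = ", "))
  calls <- calls[, c("sample_id", markers$marker_id)]
  for (m in markers$marker_id) {
    canon <- canonical_call(calls[[m]])
    if (anyNA(canon)) {
      bad <- which(is.na(canon))[1]
      stop_validation("invalid genotype code '%s' at sample '%s', marker '%s'",
                      calls[[m]][bad], calls$sample_id[bad], m)
    }
    has_x <- grepl("X", canon, fixed = TRUE)
    if (any(has_x) && length(other_bands(markers[markers$marker_id == m, ])) == 0)
      stop_validation("X-coded call at marker '%s' which has no non-reference band", m)
    calls[[m]] <- canon
  }
  if (!is.null(samples)) {
    samples <- tibble::as_tibble(samples)
    if (!"sample_id" %in% names(samples))
      stop_validation("sample metadata needs a 'sample_id' column")
    samples$sample_id <- as.character(samples$sample_id)
    extra <- setdiff(calls$sample_id, samples$sample_id)
    if (length(extra) > 0)
      stop_validation("sample metadata missing entries for: %s",
                      paste(utils::head(extra, 5), collapse = ", "))
    samples <- samples[match(calls$sample_id, samples$sample_id), ]
  }
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "indel_panel")
}

#' @export
print.indel_panel <- function(x, ...) {
  cat(sprintf("<indel_panel> %d samples x %d markers\n",
              nrow(x$calls), nrow(x$markers)))
  tot <- table(factor(unlist(x$calls[-1]), levels = call_codes()))
  cat("  calls:", paste(sprintf("%s=%d", names(tot), tot), collapse = " "), "\n")
  if (!is.null(x$samples))
    cat("  sample metadata:", paste(setdiff(names(x$samples), "sample_id"),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.indel_panel <- function(x) c(nrow(x$calls), nrow(x$markers))

#' Score an observed band profile against a marker's reference alleles
#'
#' Matches each observed band (bp) to the marker's catalogued alleles within
#' `tolerance_bp` and returns the codominant call: the indica-reference band
#' maps to allele `I`, the japonica-reference band to `J` and any other
#' catalogued band to `X`. One matched band yields a homozygous call
#' (II/JJ/XX), two distinct matches a heterozygous call (IJ/IX/JX) and an
#' empty profile a null (NN). For a dominant marker the presence of its
#' single band yields the homozygous call of the reference that carries it,
#' and absence yields the homozygous call of the other reference.
#'
#' @param observed_bands_bp integer vector of observed band sizes (bp); may
#'   be empty
#' @param marker a single-row marker tibble
#' @param tolerance_bp nonnegative matching tolerance in bp; the default 0
#'   expects exact catalogued sizes (gel-estimated sizes may use e.g. 2)
#' @return a single genotype call code
#' @export
#' @examples
#' mk <- read_marker_metadata(indel_marker_fixture())
#' score_bands(c(211, 151), mk[mk$marker_id == "R2M37", ])  # "IJ"
score_bands <- function(observed_bands_bp, marker, tolerance_bp = 0L) {
  stopifnot(nrow(marker) == 1)
  if (tolerance_bp < 0) stop_validation("tolerance_bp must be >= 0")
  observed_bands_bp <- as.numeric(observed_bands_bp)
  bands <- marker$band_sizes[[1]]

  if (isTRUE(marker$dominant)) {
    carrier <- if (!is.na(marker$japonica_band)) "J" else "I"
    absent_ref <- if (carrier == "J") "I" else "J"
    if (length(observed_bands_bp) == 0)
      return(paste0(absent_ref, absent_ref))
    matched <- abs(observed_bands_bp - bands[1]) <= tolerance_bp
    if (!all(matched))
      stop_computation("marker %s: band %s matches no catalogued allele (tolerance %d bp)",
                       marker$marker_id, observed_bands_bp[!matched][1], tolerance_bp)
    return(paste0(carrier, carrier))
  }

  if (length(observed_bands_bp) == 0) return("NN")
  letter_of <- function(size) {
    d <- abs(bands - size)
    if (min(d) > tolerance_bp)
      stop_computation("marker %s: band %s matches no catalogued allele (tolerance %d bp)",
                       marker$marker_id, size, tolerance_bp)
    hit <- bands[which.min(d)]
    if (!is.na(marker$indica_band) && hit == marker$indica_band) "I"
    else if (!is.na(marker$japonica_band) && hit == marker$japonica_band) "J"
    else "X"
  }
  letters <- unique(vapply(observed_bands_bp, letter_of, character(1)))
  distinct_hits <- unique(vapply(observed_bands_bp, function(size) {
    bands[which.min(abs(bands - size))]
  }, numeric(1)))
  if (length(distinct_hits) > 2)
    stop_computation("marker %s: %d distinct bands matched; flag sample for manual review",
                     marker$marker_id, length(distinct_hits))
  letters <- letters[order(match(letters, allele_order))]
  if (length(letters) == 1) paste0(letters, letters)
  else paste(letters, collapse = "")
}

#' Read a genotype table
#'
#' Reads a comma-separated sample-by-marker genotype table. Cells may hold
#' call codes (`II`, `JJ`, `IJ`, `NN`, `IX`, `JX`, `XX`; empty cells and
#' `NA` are read as `NN`) or raw band-size strings such as `"211/151"`,
#' which are scored against the marker's reference alleles via
#' [score_bands()].
#'
#' @param path path to a CSV file whose first column is `sample_id` and whose
#'   header names markers defined in `markers`
#' @param markers a marker tibble (see [read_marker_metadata()])
#' @param samples optional sample metadata data frame or path to a TSV file
#'   (columns `sample_id`, `population`, `latitude`, `longitude`,
#'   `altitude_m`)
#' @param tolerance_bp band matching tolerance passed to [score_bands()]
#' @return an [indel_panel()] object
#' @export
read_genotype_table <- function(path, markers, samples = NULL, tolerance_bp = 0L) {
  if (!file.exists(path)) stop_validation("genotype file not found: %s", path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  if (nrow(df) == 0) stop_validation("genotype file %s contains no samples", path)
  names(df)[1] <- "sample_id"
  unknown <- setdiff(names(df)[-1], markers$marker_id)
  if (length(unknown) > 0)
    stop_validation("genotype columns not in marker metadata: %s",
                    paste(unknown, collapse = ", "))
  band_cell <- function(x) grepl("^[0-9]+(\\s*/\\s*[0-9]+)*$", x)
  for (m in names(df)[-1]) {
    mrow <- markers[markers$marker_id == m, ]
    cells <- df[[m]]
    is_band <- !is.na(cells) & band_cell(cells)
    if (any(is_band)) {
      df[[m]][is_band] <- vapply(cells[is_band], function(cell) {
        sizes <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
        score_bands(sizes, mrow, tolerance_bp)
      }, character(1))
    }
  }
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_metadata(samples)
  }
  indel_panel(df, markers, samples)
}

#' Read per-sample metadata
#'
#' @param path TSV file with columns `sample_id` and optionally `population`,
#'   `latitude`, `longitude`, `altitude_m`
#' @return a tibble
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_validation("sample metadata file not found: %s", path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df))
    stop_validation("sample metadata needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}

#' Write a panel back to its file formats
#'
#' Writes `genotypes.csv` (and `samples.tsv` when metadata is present).
#' Reading the files back with [read_genotype_table()] reproduces the calls
#' exactly.
#'
#' @param panel an [indel_panel()]
#' @param dir output directory (created if needed)
#' @param header optional comment lines (without the leading `#`) written at
#'   the top of each file
#' @return invisibly, the paths written
#' @export
write_genotype_table <- function(panel, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.csv"))
  write_with_header(panel$calls, paths[["genotypes"]], header, delim = ",")
  if (!is.null(panel$samples)) {
    paths["samples"] <- file.path(dir, "samples.tsv")
    write_with_header(panel$samples, paths[["samples"]], header, delim = "\t")
  }
  invisible(paths)
}

# Write a delimited file with '#' comment header lines.
write_with_header <- function(df, path, header = NULL, delim = "\t") {
  if (is.null(header)) {
    readr::write_delim(df, path, delim = delim, na = "NA")
  } else {
    writeLines(paste0("# ", header), path)
    readr::write_delim(df, path, delim = delim, na = "NA",
                       append = TRUE, col_names = TRUE)
  }
}

#' Summarise a genotype panel
#'
#' Per-sample and per-marker call composition: homozygous indica/japonica,
#' heterozygous, null and X-coded counts, together with panel totals.
#'
#' @param panel an [indel_panel()]
#' @return a list with tibbles `samples` (one row per sample), `markers`
#'   (one row per marker) and `totals` (one row)
#' @export
panel_summary <- function(panel) {
  mat <- as.matrix(panel$calls[-1])
  n_loci <- ncol(mat)
  per_sample <- tibble::tibble(
    sample_id = panel$calls$sample_id,
    n_ii = rowSums(mat == "II"),
    n_jj = rowSums(mat == "JJ"),
    n_het = rowSums(matrix(is_het_call(mat), nrow = nrow(mat))),
    n_null = rowSums(mat == "NN"),
    n_x = rowSums(matrix(grepl("X", mat, fixed = TRUE), nrow = nrow(mat))),
    n_scored = n_loci - rowSums(mat == "NN")
  )
  per_marker <- tibble::tibble(
    marker_id = colnames(mat),
    n_ii = colSums(mat == "II"),
    n_jj = colSums(mat == "JJ"),
    n_het = colSums(matrix(is_het_call(mat), nrow = nrow(mat))),
    n_null = colSums(mat == "NN"),
    n_x = colSums(matrix(grepl("X", mat, fixed = TRUE), nrow = nrow(mat)))
  )
  totals <- tibble::tibble(
    n_samples = nrow(mat), n_markers = n_loci,
    n_het_samples = sum(per_sample$n_het > 0),
    n_null_samples = sum(per_sample$n_null > 0),
    n_null_markers = sum(per_marker$n_null > 0),
    n_null_calls = sum(per_marker$n_null)
  )
  list(samples = per_sample, markers = per_marker, totals = totals)
}
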