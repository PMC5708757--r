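#' Expand genotype calls into a binary band presence/absence matrix
#'
#' Converts the codominant call grid into the 0/1 band matrix used by all
#' distance-based analyses. Each marker contributes one column per
#' catalogued band, ordered indica reference first, japonica reference
#' second, then any non-reference bands in catalogue order. A homozygous
#' call lights one band of its marker, a heterozygous call two; a null call
#' leaves the marker's columns masked (missing) for that sample so they are
#' excluded pairwise from downstream distances. Dominant markers contribute
#' a single presence/absence column.
#'
#' @param panel an [indel_panel()]
#' @return a `band_matrix` object: a list with `x` (samples x bands integer
#'   0/1 matrix), `mask` (logical matrix, TRUE where observed) and `bands`
#'   (tibble: band_id, marker_id, size_bp, role)
#' @export
band_matrix <- function(panel) {
  markers <- panel$markers
  bands <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    if (isTRUE(m$dominant)) {
      role <- if (!is.na(m$japonica_band)) "japonica" else "indica"
      return(tibble::tibble(marker_id = m$marker_id,
                            size_bp = m$band_sizes[[1]][1], role = role))
    }
    ob <- other_bands(m)
    tibble::tibble(
      marker_id = m$marker_id,
      size_bp = c(m$indica_band, m$japonica_band, ob),
      role = c("indica", "japonica", rep("other", length(ob)))
    )
  })
  bands$band_id <- paste0(bands$marker_id, "_", bands$size_bp)
  bands <- bands[, c("band_id", "marker_id", "size_bp", "role")]

  calls <- as.matrix(panel$calls[-1])
  n <- nrow(calls)
  x <- matrix(0L, n, nrow(bands), dimnames = list(panel$calls$sample_id, bands$band_id))
  mask <- matrix(TRUE, n, nrow(bands), dimnames = dimnames(x))
  role_letter <- c(indica = "I", japonica = "J", other = "X")
  for (j in seq_len(nrow(bands))) {
    m <- bands$marker_id[j]
    cc <- calls[, m]
    if (isTRUE(markers$dominant[markers$marker_id == m])) {
      carrier <- role_letter[[bands$role[j]]]
      x[, j] <- as.integer(grepl(carrier, cc, fixed = TRUE))
    } else {
      x[, j] <- as.integer(grepl(role_letter[[bands$role[j]]], cc, fixed = TRUE))
    }
    mask[, j] <- cc != "NN"
    x[!mask[, j], j] <- NA_integer_
  }
  structure(list(x = x, mask = mask, bands = bands), class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("<band_matrix> %d samples x %d bands (%d masked cells)\n",
              nrow(x$x), ncol(x$x), sum(!x$mask)))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$x)

#' Flag rare bands
#'
#' A band is rare when it is present in strictly fewer than
#' `threshold` x (number of samples) of the panel's samples, counting only
#' samples where the band's marker amplified.
#'
#' @param bm a [band_matrix()]
#' @param threshold rarity cutoff as a proportion of samples (default 0.05)
#' @return tibble with one row per band: `band_id`, `marker_id`, `size_bp`,
#'   `n_present`, `prop`, `rare`
#' @export
rare_alleles <- function(bm, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1)
    stop_validation("threshold must be in (0, 1)")
  n_present <- colSums(bm$x == 1L, na.rm = TRUE)
  n_total <- nrow(bm$x)
  tibble::tibble(
    band_id = bm$bands$band_id,
    marker_id = bm$bands$marker_id,
    size_bp = bm$bands$size_bp,
    n_present = as.integer(n_present),
    prop = n_present / n_total,
    rare = n_present > 0 & n_present < threshold * n_total
  )
}
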