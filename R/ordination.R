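#' Principal component analysis of the band matrix
#'
#' Eigen-decomposition of the sample covariance of the centred (not
#' standardised) binary band columns. Masked cells (null calls) are imputed
#' with the column mean, with a warning, before decomposition.
#'
#' @param bm a [band_matrix()]
#' @param n_axes number of axes to report scores for (default 3, capped at
#'   the available rank)
#' @return an `indel_ordination` object: `scores` tibble (sample_id, axis
#'   columns), `eigenvalues`, `pct_variance` per axis over all axes, and a
#'   `method` tag
#' @export
pca_band <- function(bm, n_axes = 3) {
  x <- bm$x
  if (nrow(x) < 3 || ncol(x) < 2)
    stop_validation("PCA needs at least 3 samples and 2 bands")
  if (anyNA(x)) {
    warning(sprintf("%d masked cells mean-imputed per band column before PCA",
                    sum(is.na(x))), call. = FALSE)
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  pct <- 100 * ev / sum(ev)
  k <- min(n_axes, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  names(scores) <- paste0("axis", seq_len(k))
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(bm$x)), scores)
  structure(list(scores = scores, eigenvalues = ev, pct_variance = pct,
                 method = "pca_covariance"),
            class = "indel_ordination")
}

#' Principal coordinate analysis of collection-site geography
#'
#' Classical metric multidimensional scaling of Euclidean distances between
#' column-standardised (z-scored) latitude, longitude and altitude, used to
#' relate genetic groupings to the ecological regions samples were
#' collected from. Samples with a missing coordinate are dropped with a
#' warning.
#'
#' @param samples data frame with `sample_id`, `latitude`, `longitude` and
#'   `altitude_m`
#' @param n_axes number of axes to report (default 3)
#' @return an `indel_ordination` (eigenvalues are the positive PCoA
#'   eigenvalues; `pct_variance` is relative to their sum)
#' @export
pcoa_geographic <- function(samples, n_axes = 3) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "latitude", "longitude", "altitude_m")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    stop_validation("sample table lacks column(s): %s", paste(miss, collapse = ", "))
  coords <- as.matrix(samples[, c("latitude", "longitude", "altitude_m")])
  complete <- stats::complete.cases(coords)
  if (!all(complete)) {
    warning(sprintf("%d sample(s) with missing coordinates dropped from PCoA",
                    sum(!complete)), call. = FALSE)
  }
  coords <- coords[complete, , drop = FALSE]
  ids <- samples$sample_id[complete]
  if (nrow(coords) < 3)
    stop_validation("PCoA needs at least 3 samples with complete coordinates")
  z <- scale(coords)
  z[, apply(coords, 2, stats::sd) == 0] <- 0  # constant column: no spread
  d <- stats::dist(z)
  k <- min(n_axes, nrow(coords) - 1)
  # cmdscale warns when k exceeds the positive-eigenvalue rank (expected
  # for collinear configurations); the eigenvalues are reported regardless
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pos <- fit$eig[fit$eig > 1e-9]
  pct <- 100 * fit$eig / sum(pos)
  pts <- fit$points
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  scores <- tibble::as_tibble(pts)
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids), scores)
  structure(list(scores = scores, eigenvalues = fit$eig,
                 pct_variance = pct, method = "pcoa_geographic"),
            class = "indel_ordination")
}

#' @export
print.indel_ordination <- function(x, ...) {
  k <- min(3, length(x$pct_variance))
  cat(sprintf("<indel_ordination> %s: %d samples; first axes explain %s\n",
              x$method, nrow(x$scores),
              paste(sprintf("%.2f%%", x$pct_variance[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Tidy methods for ordinations
#'
#' @param x an `indel_ordination`
#' @param ... unused
#' @return `tidy()`: the per-sample score tibble; `glance()`: one row with
#'   the leading axis percentages
#' @method tidy indel_ordination
#' @export
tidy.indel_ordination <- function(x, ...) x$scores

#' @rdname tidy.indel_ordination
#' @method glance indel_ordination
#' @export
glance.indel_ordination <- function(x, ...) {
  k <- min(3, length(x$pct_variance))
  out <- tibble::tibble(n_samples = nrow(x$scores),
                        n_axes = length(x$eigenvalues))
  for (i in seq_len(k)) out[[paste0("pct_axis", i)]] <- x$pct_variance[i]
  out
}
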