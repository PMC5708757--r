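#' Squared Euclidean band distance
#'
#' Pairwise squared Euclidean distance between samples on the binary band
#' matrix: the number of band columns, observed (unmasked) in both samples,
#' where presence differs. This is the binary distance substrate on which
#' molecular variance is partitioned.
#'
#' @param bm a [band_matrix()]
#' @return an `indel_dist` object: a symmetric numeric matrix of squared
#'   distances with zero diagonal and a `metric` attribute
#' @export
band_sq_distance <- function(bm) {
  n <- nrow(bm$x)
  if (n < 2) stop_validation("need at least 2 samples")
  x <- bm$x
  shared <- (!is.na(x)) %*% t(!is.na(x))
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop_computation("samples '%s' and '%s' share no observed band columns",
                     rownames(x)[bad[1]], rownames(x)[bad[2]])
  }
  x0 <- x; x0[is.na(x0)] <- 0L
  obs <- (!is.na(x)) * 1L
  # mismatches over mutually observed columns:
  # sum_c [x_i != x_j] = x_i'(1-x_j) + (1-x_i)'x_j restricted to shared cols
  cross <- x0 %*% t(x0)
  ones_i <- x0 %*% t(obs)  # x_i summed over columns observed in j
  ones_j <- obs %*% t(x0)
  d <- (ones_i - cross) + (ones_j - cross)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(d, metric = "squared_euclidean_band", class = c("indel_dist", "matrix"))
}

#' @export
print.indel_dist <- function(x, ...) {
  cat(sprintf("<indel_dist> %d x %d, metric: %s\n", nrow(x), ncol(x),
              attr(x, "metric")))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

# Sum of squared pairwise distances within a group, divided by group size:
# (1/n_p) * sum_{i<j in p} d2_ij.
ss_group <- function(d2, idx) sum(d2[idx, idx]) / (2 * length(idx))

# Sums of squares for a partition; d2 is the full squared-distance matrix.
amova_ss <- function(d2, pops) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(split(seq_len(n), pops), function(idx)
    ss_group(d2, idx), numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Analysis of molecular variance (two-level, binary distances)
#'
#' Partitions the total squared-distance variation of a panel among and
#' within populations, estimates the among-population variance component Va
#' and Phi-PT = Va / (Va + Vw), and tests Phi-PT by random permutation of
#' sample-to-population assignments (preserving population sizes).
#'
#' Sums of squares follow the standard distance-matrix formulation:
#' SS_total = (1/N) sum over pairs of d2; SS_within sums (1/n_p) of the
#' within-population pair distances; MS = SS/df with df_among = P - 1 and
#' df_within = N - P. Va = max(0, (MS_among - MS_within) / n0) with
#' n0 = (N - sum(n_p^2)/N) / (P - 1); negative estimates are truncated to 0
#' so Phi-PT stays in \[0, 1\]. Significance is assessed by permuting the
#' population labels and ranking the observed among-population sum of
#' squares (a monotone, untruncated surrogate for Phi-PT, which keeps null
#' P-values uniform); the P-value uses the add-one estimator
#' (1 + number of permutations at least as extreme) / (1 + n_perm) and is
#' therefore never exactly 0.
#'
#' @param d an `indel_dist` squared-distance matrix (e.g. from
#'   [band_sq_distance()]), or any symmetric matrix of squared distances
#' @param populations vector of population labels aligned with the rows of
#'   `d`; at least two populations with two samples each
#' @param n_perm number of label permutations (default 10000); 0 skips the
#'   test and leaves the P-value NA
#' @param seed optional integer seed for the permutation stream; the
#'   caller's RNG state is restored afterwards
#' @return an `indel_amova` object; see [tidy()] and [glance()] methods
#' @export
#' @examples
#' pnl <- simulate_panel(sim_config(
#'   populations = sim_populations(c("a", "b"), c(10, 10), c(2, 18), c(18, 2))),
#'   seed = 1)
#' fit <- amova(band_sq_distance(band_matrix(pnl$panel)),
#'              pnl$truth$samples$population, n_perm = 99, seed = 1)
#' glance(fit)
amova <- function(d, populations, n_perm = 10000, seed = NULL) {
  d2 <- unclass(as.matrix(d))
  n <- nrow(d2)
  if (length(populations) != n)
    stop_validation("length of populations (%d) != number of samples (%d)",
                    length(populations), n)
  pops <- factor(populations)
  sizes <- table(pops)
  if (length(sizes) < 2) stop_validation("need at least 2 populations")
  if (any(sizes < 2))
    stop_validation("singleton population(s): %s",
                    paste(names(sizes)[sizes < 2], collapse = ", "))
  if (n_perm < 0) stop_validation("n_perm must be >= 0")
  p <- length(sizes)
  df_among <- p - 1L
  df_within <- n - p
  n0 <- (n - sum(sizes^2) / n) / df_among

  ss <- amova_ss(d2, pops)
  ms_among <- ss[["among"]] / df_among
  ms_within <- ss[["within"]] / df_within
  va <- max(0, (ms_among - ms_within) / n0)
  vw <- ms_within
  phi <- if (va + vw > 0) va / (va + vw) else 0

  # The permutation test ranks the observed partition by SS_among
  # (equivalently by -SS_within, the only term label permutation moves).
  # Ranking the zero-truncated Phi instead would pile permutations onto the
  # Phi = 0 atom and make null P-values conservative rather than uniform.
  p_perm <- NA_real_
  if (n_perm > 0) {
    ssw_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        perm <- pops[sample.int(n)]
        sum(vapply(split(seq_len(n), perm), function(idx)
          ss_group(d2, idx), numeric(1)))
      }, numeric(1))
    })
    p_perm <- (1 + sum(ssw_perm <= ss[["within"]] + 1e-12)) / (1 + n_perm)
  }

  sources <- tibble::tibble(
    source = c("among populations", "within populations", "total"),
    df = c(df_among, df_within, df_among + df_within),
    ss = c(ss[["among"]], ss[["within"]], ss[["total"]]),
    ms = c(ms_among, ms_within, NA_real_),
    variance = c(va, vw, va + vw),
    pct = 100 * c(va, vw, va + vw) / (va + vw)
  )
  structure(list(sources = sources, phi_pt = phi, p_perm = p_perm,
                 n_perm = as.integer(n_perm), seed = seed, n0 = n0,
                 n = n, populations = sizes),
            class = "indel_amova")
}

#' @export
print.indel_amova <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  cat(sprintf("  %d samples in %d populations (%s)\n", x$n, length(x$populations),
              paste(sprintf("%s: %d", names(x$populations), x$populations),
                    collapse = ", ")))
  s <- x$sources
  cat(sprintf("  %-19s %4s %10s %9s %9s %6s\n", "Source", "df", "SS", "MS",
              "Est.Var.", "%"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-19s %4d %10.2f %9s %9.2f %5.0f%%\n", s$source[i], s$df[i],
                s$ss[i], ifelse(is.na(s$ms[i]), "", sprintf("%.2f", s$ms[i])),
                s$variance[i], s$pct[i]))
  cat(sprintf("  Phi-PT = %.3f", x$phi_pt))
  if (!is.na(x$p_perm))
    cat(sprintf(", P = %.4g (%d permutations)", x$p_perm, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Tidy an AMOVA fit
#'
#' @param x an `indel_amova` object
#' @param ... unused
#' @return the variance-partition table as a tibble (source, df, ss, ms,
#'   variance, pct)
#' @method tidy indel_amova
#' @export
tidy.indel_amova <- function(x, ...) x$sources

#' One-row summary of an AMOVA fit
#'
#' @param x an `indel_amova` object
#' @param ... unused
#' @return tibble with `phi_pt`, `p_perm`, `n_perm`, `n_samples`, `n_pops`
#' @method glance indel_amova
#' @export
glance.indel_amova <- function(x, ...) {
  tibble::tibble(phi_pt = x$phi_pt, p_perm = x$p_perm, n_perm = x$n_perm,
                 n_samples = x$n, n_pops = length(x$populations))
}

#' Per-population diversity indices
#'
#' For each population and locus, computes from gene-count allele
#' frequencies: observed allele number Na, effective allele number
#' Ne = 1/sum(p^2), Shannon information I = -sum(p log p), expected
#' heterozygosity He = 1 - sum(p^2) and its small-sample unbiased version
#' uHe = 2n/(2n-1) He (n = samples scored at the locus). Null calls are
#' excluded locus-wise; loci with no scored sample in a population are
#' skipped with a warning.
#'
#' @param panel an [indel_panel()]
#' @param populations vector of population labels aligned with the panel's
#'   samples
#' @return tibble with one row per population x locus: `population`,
#'   `marker_id`, `n`, `na`, `ne`, `shannon_i`, `he`, `uhe`
#' @export
diversity_stats <- function(panel, populations) {
  if (length(populations) != nrow(panel$calls))
    stop_validation("populations must match the panel's samples")
  pops <- factor(populations)
  if (any(table(pops) < 1)) stop_validation("empty population")
  mat <- as.matrix(panel$calls[-1])
  purrr::map_dfr(levels(pops), function(pp) {
    rows <- which(pops == pp)
    purrr::map_dfr(colnames(mat), function(m) {
      cc <- mat[rows, m]
      scored <- cc[cc != "NN"]
      if (length(scored) == 0) {
        warning(sprintf("population '%s', marker '%s': no scored samples; skipped",
                        pp, m), call. = FALSE)
        return(NULL)
      }
      f <- marker_allele_freqs(scored)
      pv <- f$freq[f$freq > 0]
      n <- length(scored)
      he <- 1 - sum(pv^2)
      tibble::tibble(
        population = pp, marker_id = m, n = n,
        na = length(pv),
        ne = 1 / sum(pv^2),
        shannon_i = -sum(pv * log(pv)),
        he = he,
        uhe = if (2 * n - 1 > 0) 2 * n / (2 * n - 1) * he else NA_real_
      )
    })
  })
}

#' Mean and standard error of diversity indices across loci
#'
#' @param div per-locus diversity tibble from [diversity_stats()]
#' @return tibble with one row per population and index: `population`,
#'   `index`, `mean`, `se` (sd across loci / sqrt(number of loci)), `n_loci`
#' @export
diversity_summary <- function(div) {
  long <- tidyr::pivot_longer(div, c("na", "ne", "shannon_i", "he", "uhe"),
                              names_to = "index", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$population, .data$index),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n_loci = dplyr::n(), .groups = "drop")
  out$index <- factor(out$index, levels = c("na", "ne", "shannon_i", "he", "uhe"))
  dplyr::arrange(out, .data$population, .data$index)
}
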