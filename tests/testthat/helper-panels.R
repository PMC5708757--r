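# Shared fixture builders: tiny marker sets and panels constructed in code.

toy_markers <- function(n = 2, triallelic = FALSE, dominant_first = FALSE) {
  ind <- 200L + 10L * seq_len(n)
  jap <- 150L + 10L * seq_len(n)
  mk <- tibble::tibble(
    marker_id = paste0("T", seq_len(n)),
    chromosome = ((seq_len(n) - 1L) %% 12L) + 1L,
    band_sizes = lapply(seq_len(n), function(i) c(ind[i], jap[i])),
    indica_band = ind,
    japonica_band = jap,
    indel_size = ind - jap,
    dominant = FALSE
  )
  if (triallelic) {
    mk$band_sizes[[1]] <- c(mk$band_sizes[[1]], 120L)
  }
  if (dominant_first) {
    mk$band_sizes[[1]] <- mk$japonica_band[1]
    mk$indica_band[1] <- NA_integer_
    mk$dominant[1] <- TRUE
  }
  mk
}

# Build a panel from a character matrix of calls (samples x markers).
toy_panel <- function(call_rows, markers = NULL, samples = NULL) {
  m <- do.call(rbind, call_rows)
  if (is.null(markers)) markers <- toy_markers(ncol(m))
  colnames(m) <- markers$marker_id
  calls <- dplyr::bind_cols(
    tibble::tibble(sample_id = names(call_rows)),
    tibble::as_tibble(m))
  indel_panel(calls, markers, samples)
}

# Random call panel (no structure), useful for property checks.
random_panel <- function(n_samples, n_markers, p_het = 0.1, p_null = 0.05,
                         seed = 1) {
  withr::with_seed(seed, {
    codes <- c("II", "JJ", "IJ", "NN")
    probs <- c((1 - p_het - p_null) / 2, (1 - p_het - p_null) / 2, p_het, p_null)
    rows <- lapply(seq_len(n_samples), function(i)
      sample(codes, n_markers, replace = TRUE, prob = probs))
    names(rows) <- sprintf("S%02d", seq_len(n_samples))
    toy_panel(rows, toy_markers(n_markers))
  })
}

# Brute-force AMOVA sums of squares by explicit double loops.
brute_amova_ss <- function(d2, pops) {
  n <- nrow(d2)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d2[idx[a], idx[b]]
    }
    ss_within <- ss_within + acc / length(idx)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# Exhaustive UPGMA oracle: repeatedly merge the closest pair of clusters,
# recomputing all-pairs average distances from the original matrix.
brute_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      if (avg < best[1] - 1e-12) best <- c(avg, a, b)
    }
    a <- best[2]; b <- best[3]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- best[1]
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}
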