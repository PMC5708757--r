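#' Population specifications for the panel simulator
#'
#' Each population draws its per-locus japonica-allele frequency q from a
#' Beta(alpha, beta) distribution, giving contrasting frequency spectra
#' between populations (e.g. an indica-like population with small mean q
#' and a japonica-leaning one with large mean q).
#'
#' @param label population labels
#' @param n_samples samples per population (>= 2)
#' @param alpha,beta Beta shape parameters per population (> 0)
#' @return tibble with one row per population
#' @export
sim_populations <- function(label, n_samples, alpha, beta) {
  out <- tibble::tibble(label = as.character(label),
                        n_samples = as.integer(n_samples),
                        alpha = as.numeric(alpha), beta = as.numeric(beta))
  if (any(out$n_samples < 2)) stop_validation("population sizes must be >= 2")
  if (any(out$alpha <= 0 | out$beta <= 0))
    stop_validation("Beta parameters must be > 0")
  if (anyDuplicated(out$label)) stop_validation("duplicate population labels")
  out
}

#' Configuration of the synthetic genotype-panel generator
#'
#' Defines a selfing-species genotype panel: mostly homozygous calls with an
#' explicit per-call heterozygosity rate (rather than Hardy-Weinberg
#' proportions, which would overstate heterozygosity for predominantly
#' self-pollinating rice landraces), sparse null alleles, and optional
#' triallelic loci carrying a third, non-reference band.
#'
#' @param n_loci number of InDel loci (default 42)
#' @param n_triallelic number of loci carrying a third band (default 1)
#' @param populations a tibble from [sim_populations()]
#' @param het_rate per-call probability of a heterozygous IJ call
#'   (default 0.03)
#' @param null_rate per-call probability of a null NN call (default 0.005)
#' @param x_allele_rate per-allele probability, at triallelic loci, that an
#'   allele is replaced by the third band (default 0.02)
#' @param include_references add two reference-like extreme samples
#'   (REF_INDICA all II, REF_JAPONICA all JJ, population "reference")
#' @return a `sim_config` list
#' @export
sim_config <- function(n_loci = 42, n_triallelic = 1,
                       populations = sim_populations(
                         c("indica_like", "japonica_leaning"),
                         c(160, 30), c(2, 6), c(8, 4)),
                       het_rate = 0.03, null_rate = 0.005,
                       x_allele_rate = 0.02, include_references = FALSE) {
  rates <- c(het_rate, null_rate, x_allele_rate)
  if (any(rates < 0 | rates > 1)) stop_validation("rates must be in [0, 1]")
  if (n_loci < 1) stop_validation("n_loci must be >= 1")
  if (n_triallelic < 0 || n_triallelic > n_loci)
    stop_validation("n_triallelic must be in [0, n_loci]")
  structure(list(n_loci = as.integer(n_loci),
                 n_triallelic = as.integer(n_triallelic),
                 populations = sim_populations(populations$label,
                                               populations$n_samples,
                                               populations$alpha,
                                               populations$beta),
                 het_rate = het_rate, null_rate = null_rate,
                 x_allele_rate = x_allele_rate,
                 include_references = isTRUE(include_references)),
            class = "sim_config")
}

#' Study-scale simulator preset
#'
#' A 192-sample x 42-locus panel: 160 indica-like landraces (per-locus q ~
#' Beta(2, 8)), 30 japonica-leaning landraces (q ~ Beta(6, 4)), two
#' reference-like extremes, one triallelic locus, and the default
#' heterozygosity/null rates. The class census of such a panel is dominated
#' by the indica side (~85% of samples), with the japonica-leaning minority
#' spread over the intermediate and close-to-japonica classes.
#'
#' @return a `sim_config`
#' @export
paper_scale_preset <- function() {
  sim_config(include_references = TRUE)
}

# Synthetic marker definitions for a simulated panel: biallelic loci
# (indica band listed first), with the first n_triallelic loci carrying a
# third non-reference band.
sim_markers <- function(n_loci, n_triallelic) {
  id <- sprintf("M%02d", seq_len(n_loci))
  chrom <- ((seq_len(n_loci) - 1L) %% 12L) + 1L
  ind <- 200L + 2L * seq_len(n_loci)
  jap <- 150L + 2L * seq_len(n_loci)
  tibble::tibble(
    marker_id = id, chromosome = chrom,
    band_sizes = lapply(seq_len(n_loci), function(i) {
      b <- c(ind[i], jap[i])
      if (i <= n_triallelic) b <- c(b, jap[i] - 30L)
      b
    }),
    indica_band = ind, japonica_band = jap,
    indel_size = ind - jap, dominant = FALSE
  )
}

#' Simulate a genotype panel with known truth
#'
#' Draws, for every population and locus, a japonica-allele frequency q
#' from the population's Beta distribution; then, for every sample and
#' locus, emits IJ with probability `het_rate`, otherwise JJ with
#' probability q and II with probability 1 - q. At triallelic loci each
#' emitted allele is independently replaced by the third band (X) with
#' probability `x_allele_rate`; finally calls become NN with probability
#' `null_rate`. Geographic coordinates are attached per population
#' (distinct regional centres with jitter; the japonica-leaning populations
#' sit at higher altitude), emulating regionally structured collection
#' sites.
#'
#' The truth table records both the parameter level (per-population,
#' per-locus q) and the realisation level: each sample's japonica-allele
#' proportion computed from the emitted calls before the X/null overlays,
#' so that index recovery can be asserted exactly when the overlay rates
#' are zero.
#'
#' @param config a [sim_config()]
#' @param seed integer seed; the generator is deterministic given
#'   (config, seed)
#' @return list with `panel` (an [indel_panel()]) and `truth` (list of
#'   tibbles `samples` and `loci`)
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    markers <- sim_markers(config$n_loci, config$n_triallelic)
    pops <- config$populations
    n_loci <- config$n_loci

    q_loci <- purrr::map_dfr(seq_len(nrow(pops)), function(p) {
      tibble::tibble(population = pops$label[p],
                     marker_id = markers$marker_id,
                     q_japonica = stats::rbeta(n_loci, pops$alpha[p], pops$beta[p]))
    })

    sample_rows <- list()
    call_rows <- list()
    for (p in seq_len(nrow(pops))) {
      qs <- q_loci$q_japonica[q_loci$population == pops$label[p]]
      for (s in seq_len(pops$n_samples[p])) {
        sid <- sprintf("%s_%03d", toupper(substr(pops$label[p], 1, 3)), s)
        het <- stats::runif(n_loci) < config$het_rate
        jj <- stats::runif(n_loci) < qs
        calls <- ifelse(het, "IJ", ifelse(jj, "JJ", "II"))
        f_j_real <- (2 * sum(calls == "JJ") + sum(calls == "IJ")) / (2 * n_loci)
        # X substitution at triallelic loci, per allele
        if (config$n_triallelic > 0 && config$x_allele_rate > 0) {
          for (l in seq_len(config$n_triallelic)) {
            al <- strsplit(calls[l], "")[[1]]
            swap <- stats::runif(2) < config$x_allele_rate
            if (calls[l] != "NN" && any(swap)) {
              al[swap] <- "X"
              al <- al[order(match(al, allele_order))]
              calls[l] <- paste(al, collapse = "")
            }
          }
        }
        nulls <- stats::runif(n_loci) < config$null_rate
        calls[nulls] <- "NN"
        call_rows[[sid]] <- calls
        sample_rows[[sid]] <- tibble::tibble(
          sample_id = sid, population = pops$label[p],
          f_j_realized = f_j_real,
          f_j_expected = mean(qs * (1 - config$het_rate) + config$het_rate / 2))
      }
    }
    if (config$include_references) {
      call_rows[["REF_INDICA"]] <- rep("II", n_loci)
      call_rows[["REF_JAPONICA"]] <- rep("JJ", n_loci)
      sample_rows[["REF_INDICA"]] <- tibble::tibble(
        sample_id = "REF_INDICA", population = "reference",
        f_j_realized = 0, f_j_expected = 0)
      sample_rows[["REF_JAPONICA"]] <- tibble::tibble(
        sample_id = "REF_JAPONICA", population = "reference",
        f_j_realized = 1, f_j_expected = 1)
    }
    truth_samples <- dplyr::bind_rows(sample_rows)

    call_mat <- do.call(rbind, call_rows)
    colnames(call_mat) <- markers$marker_id
    calls <- dplyr::bind_cols(tibble::tibble(sample_id = names(call_rows)),
                              tibble::as_tibble(call_mat))

    # regional collection-site geography: one centre per population,
    # japonica-leaning populations at higher altitude
    centres <- tibble::tibble(
      population = unique(truth_samples$population),
      lat0 = 19 + 1.5 * seq_along(unique(truth_samples$population)),
      lon0 = 80 + 1.0 * seq_along(unique(truth_samples$population)),
      alt0 = ifelse(grepl("japonica", unique(truth_samples$population)), 600, 300))
    geo <- dplyr::left_join(truth_samples["population"], centres, by = "population")
    samples_meta <- tibble::tibble(
      sample_id = truth_samples$sample_id,
      population = truth_samples$population,
      latitude = geo$lat0 + stats::rnorm(nrow(geo), 0, 0.4),
      longitude = geo$lon0 + stats::rnorm(nrow(geo), 0, 0.4),
      altitude_m = pmax(100, geo$alt0 + stats::rnorm(nrow(geo), 0, 50)))

    panel <- indel_panel(calls, markers, samples_meta)
    list(panel = panel,
         truth = list(samples = truth_samples, loci = q_loci))
  })
}

#' Write a simulated panel to the package's file formats
#'
#' Emits `genotypes.csv`, `markers.tsv`, `samples.tsv` and a `truth.json`
#' sidecar into `dir`.
#'
#' @param sim result of [simulate_panel()]
#' @param dir output directory
#' @param header optional comment header lines
#' @return invisibly, the paths written
#' @export
write_sim_panel <- function(sim, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_genotype_table(sim$panel, dir, header = header)
  mk <- sim$panel$markers
  mk$band_sizes <- vapply(mk$band_sizes, paste, character(1), collapse = ",")
  paths["markers"] <- file.path(dir, "markers.tsv")
  write_with_header(mk, paths[["markers"]], header)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}
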