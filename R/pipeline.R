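# End-to-end pipeline stages. Each stage writes plain-text artifacts into an
# output directory, with a comment header recording the package version, the
# seed and a hash of the run configuration so that identical (config, seed)
# runs are byte-identical.

run_header <- function(seed, config) {
  c(sprintf("indelindex %s", as.character(utils::packageVersion("indelindex"))),
    sprintf("seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("config=%s", rlang::hash(config)))
}

load_panel <- function(genotypes, markers, samples = NULL, tolerance_bp = 0L) {
  mk <- if (is.character(markers)) read_marker_metadata(markers) else markers
  read_genotype_table(genotypes, mk, samples = samples, tolerance_bp = tolerance_bp)
}

#' Pipeline stages
#'
#' File-to-file wrappers over the analysis functions, used both
#' programmatically and by the command-line tool in
#' `system.file("cli", "indelindex-tool.R", package = "indelindex")`.
#'
#' * `run_classify()` writes `classification.tsv` (per-sample index and
#'   class) and `census.tsv`.
#' * `run_markerstats()` writes `marker_stats.tsv` and `summary.json`.
#' * `run_amova()` writes `amova.txt` (variance-partition layout) and
#'   `amova.json`; populations default to the proposed split from the
#'   classification when the sample metadata has no `population` column.
#' * `run_cluster()` writes `similarity.csv`, `tree.nwk`, `clusters.tsv`,
#'   `pca_scores.tsv` and, when coordinates are available,
#'   `pcoa_scores.tsv`.
#' * `run_simulate()` writes a simulated panel (`genotypes.csv`,
#'   `markers.tsv`, `samples.tsv`, `truth.json`).
#' * `run_report()` chains simulate-or-load, classify, markerstats, amova
#'   and cluster, skipping stages whose inputs are unavailable, and writes
#'   `report.txt`.
#'
#' @param genotypes path to a genotype CSV
#' @param markers path to a marker metadata TSV, or a marker tibble
#' @param out_dir output directory (created if needed)
#' @param samples optional path to a sample metadata TSV
#' @param seed integer seed recorded in artifact headers and used for any
#'   randomised step
#' @param n_perm permutations for the Phi-PT test
#' @param cut_similarity similarity level for cluster membership
#' @param config a [sim_config()] for `run_simulate()`
#' @return each stage invisibly returns the paths it wrote
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_classify <- function(genotypes, markers, out_dir, samples = NULL, seed = NULL) {
  panel <- load_panel(genotypes, markers, samples)
  idx <- classify_panel(panel)
  hdr <- run_header(seed, list(stage = "classify", genotypes = basename(genotypes)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(classification = file.path(out_dir, "classification.tsv"),
             census = file.path(out_dir, "census.tsv"))
  out <- idx
  out$class <- as.character(out$class)
  write_with_header(out, paths[["classification"]], hdr)
  cen <- class_census(idx)
  cen$class <- as.character(cen$class)
  write_with_header(cen, paths[["census"]], hdr)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_markerstats <- function(genotypes, markers, out_dir, seed = NULL) {
  panel <- load_panel(genotypes, markers)
  rep <- marker_report(panel)
  hdr <- run_header(seed, list(stage = "markerstats", genotypes = basename(genotypes)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stats = file.path(out_dir, "marker_stats.tsv"),
             summary = file.path(out_dir, "summary.json"))
  flat <- rep[, !vapply(rep, is.list, logical(1))]
  write_with_header(flat, paths[["stats"]], hdr)
  jsonlite::write_json(summarise_marker_stats(rep), paths[["summary"]],
                       dataframe = "columns", digits = NA)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_amova <- function(genotypes, markers, out_dir, samples = NULL,
                      n_perm = 10000, seed = NULL) {
  panel <- load_panel(genotypes, markers, samples)
  pops <- panel$samples[["population"]]
  if (is.null(pops)) {
    idx <- classify_panel(panel)
    pops <- proposed_populations(idx)
  }
  fit <- amova(band_sq_distance(band_matrix(panel)), pops,
               n_perm = n_perm, seed = seed)
  hdr <- run_header(seed, list(stage = "amova", n_perm = n_perm))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(txt = file.path(out_dir, "amova.txt"),
             json = file.path(out_dir, "amova.json"))
  con <- file(paths[["txt"]], open = "w")
  writeLines(paste0("# ", hdr), con)
  sink(con); print(fit); sink()
  close(con)
  jsonlite::write_json(list(sources = tidy(fit), summary = glance(fit)),
                       paths[["json"]], dataframe = "columns", digits = NA)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_cluster <- function(genotypes, markers, out_dir, samples = NULL,
                        cut_similarity = 0.30, seed = NULL) {
  panel <- load_panel(genotypes, markers, samples)
  bm <- band_matrix(panel)
  sim <- jaccard_similarity(bm)
  tree <- upgma(jaccard_distance(bm))
  hdr <- run_header(seed, list(stage = "cluster", cut = cut_similarity))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(similarity = file.path(out_dir, "similarity.csv"),
             tree = file.path(out_dir, "tree.nwk"),
             clusters = file.path(out_dir, "clusters.tsv"),
             pca = file.path(out_dir, "pca_scores.tsv"))
  sim_df <- tibble::as_tibble(as.data.frame(sim), rownames = "sample_id")
  write_with_header(sim_df, paths[["similarity"]], hdr, delim = ",")
  write_newick(tree, paths[["tree"]])
  write_with_header(cut_clusters(tree, cut_similarity), paths[["clusters"]], hdr)
  pca <- pca_band(bm)
  write_with_header(tidy(pca), paths[["pca"]], hdr)
  meta <- panel$samples
  if (!is.null(meta) && all(c("latitude", "longitude", "altitude_m") %in% names(meta))) {
    paths["pcoa"] <- file.path(out_dir, "pcoa_scores.tsv")
    write_with_header(tidy(pcoa_geographic(meta)), paths[["pcoa"]], hdr)
  } else {
    message("no complete coordinates in sample metadata; geographic PCoA skipped")
  }
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, config = paper_scale_preset(), seed = NULL) {
  sim <- simulate_panel(config, seed = seed)
  hdr <- run_header(seed, list(stage = "simulate", config = unclass(config)))
  invisible(write_sim_panel(sim, out_dir, header = hdr))
}

#' @rdname pipeline
#' @export
run_report <- function(genotypes, markers, out_dir, samples = NULL,
                       n_perm = 10000, cut_similarity = 0.30, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stages <- list(
    classify = function() run_classify(genotypes, markers, out_dir,
                                       samples = samples, seed = seed),
    markerstats = function() run_markerstats(genotypes, markers, out_dir, seed = seed),
    amova = function() run_amova(genotypes, markers, out_dir, samples = samples,
                                 n_perm = n_perm, seed = seed),
    cluster = function() run_cluster(genotypes, markers, out_dir,
                                     samples = samples,
                                     cut_similarity = cut_similarity, seed = seed))
  status <- character(0)
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      status[nm] <- paste("SKIPPED:", conditionMessage(res))
      message(sprintf("stage '%s' skipped: %s", nm, conditionMessage(res)))
    } else {
      status[nm] <- "ok"
      paths <- c(paths, res)
    }
  }
  report <- file.path(out_dir, "report.txt")
  writeLines(c(paste0("# ", run_header(seed, list(stage = "report", n_perm = n_perm,
                                                  cut = cut_similarity))),
               sprintf("%-12s %s", names(status), status)), report)
  paths["report"] <- report
  invisible(paths)
}
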