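#' Run the full analysis pipeline and write stage outputs
#'
#' Executes occurrence filtering, metaweb construction, module detection,
#' module completeness, timepoint-network topology, SBM nulls, phylogenetic
#' dispersion, environmental optima + Mantel correlogram, diversity, and
#' pollutant-removal correlations, writing each stage's table under
#' `out_dir` together with a run log (config echo, seed, stage timings).
#'
#' @param cd A [count_data] object.
#' @param metadata Sample metadata tibble (see [read_metadata()]).
#' @param tree An [ape::phylo] tree covering the ASVs.
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param nulls Run the SBM null stage (default TRUE; the slowest stage).
#' @param correlogram Run the Mantel correlogram stage (default TRUE).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(cd, metadata, tree, config = run_config(), out_dir,
                         nulls = TRUE, correlogram = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  out <- list()
  out$filtered <- stage("filter", filter_by_occurrence(cd, config$presence_threshold))
  occ <- stage("occurrence", occurrence_matrix(out$filtered, config$presence_threshold))
  out$metaweb <- stage("metaweb",
                       build_metaweb(occ, config$significance, config$inclusive))
  readr::write_tsv(out$metaweb$pairs, file.path(out_dir, "pairs.tsv"), progress = FALSE)
  out$partition <- stage("modules",
                         detect_modules(out$metaweb, config$walk_length, config$seed))
  readr::write_tsv(tibble::as_tibble(out$partition),
                   file.path(out_dir, "partition.tsv"), progress = FALSE)
  write_network(out$metaweb, file.path(out_dir, "metaweb.graphml"),
                file.path(out_dir, "edges.tsv"), out$partition)
  out$completeness <- stage("completeness", module_completeness(out$partition, occ))
  readr::write_tsv(out$completeness, file.path(out_dir, "completeness.tsv"), progress = FALSE)
  out$topology <- stage("timepoints",
                        extract_timepoint_networks(out$metaweb, occ,
                                                   walk_length = config$walk_length,
                                                   seed = config$seed))
  readr::write_tsv(tibble::as_tibble(out$topology) |>
                     dplyr::select(-dplyr::any_of("graphs")),
                   file.path(out_dir, "topology.tsv"), progress = FALSE)
  if (nulls) {
    out$nulls <- stage("nulls",
                       null_distributions(out$metaweb, out$partition, occ,
                                          n_iter = config$n_sbm, seed = config$seed,
                                          observed = out$topology,
                                          walk_length = config$walk_length))
    readr::write_tsv(out$nulls, file.path(out_dir, "nulls.tsv"), progress = FALSE)
  }
  dist <- stage("cophenetic", cophenetic_distances(tree))
  out$dispersion <- stage("dispersion",
                          ses_dispersion(out$filtered, dist,
                                         n_null = config$n_phylo, seed = config$seed))
  readr::write_tsv(tibble::as_tibble(out$dispersion),
                   file.path(out_dir, "dispersion.tsv"), progress = FALSE)
  out$optima <- stage("optima", environmental_optima(out$filtered, metadata))
  readr::write_tsv(out$optima, file.path(out_dir, "optima.tsv"), progress = FALSE)
  if (correlogram) {
    td <- optima_distances(out$optima)
    pd <- dist[rownames(td), rownames(td)]
    out$correlogram <- stage("correlogram",
                             mantel_correlogram(td, pd, config$n_phylo, config$seed))
    readr::write_tsv(out$correlogram, file.path(out_dir, "correlogram.tsv"), progress = FALSE)
  }
  out$alpha <- stage("diversity", alpha_diversity(out$filtered, tree))
  readr::write_tsv(out$alpha, file.path(out_dir, "alpha.tsv"), progress = FALSE)
  bc <- stage("braycurtis", bray_curtis(out$filtered))
  readr::write_tsv(tibble::as_tibble(bc, rownames = "sample_id"),
                   file.path(out_dir, "braycurtis.tsv"), progress = FALSE)
  out$rates <- stage("removal", removal_rates(metadata))
  readr::write_tsv(out$rates, file.path(out_dir, "removal.tsv"), progress = FALSE)
  out$correlations <- stage("correlate",
                            correlate_nodes(out$filtered, out$metaweb$nodes$asv_id,
                                            out$rates, fdr = config$fdr,
                                            seed = config$seed))
  readr::write_tsv(out$correlations, file.path(out_dir, "node_correlations.tsv"),
                   progress = FALSE)
  out$correlated_series <- stage("series",
                                 correlated_abundance_series(out$correlations, out$filtered))
  readr::write_tsv(out$correlated_series, file.path(out_dir, "correlated_series.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(config = unclass(config), seed = config$seed,
                            timings_s = timings,
                            finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(out)
}

spearman_trend <- function(value, timepoint) {
  ok <- stats::complete.cases(value, timepoint)
  if (sum(ok) < 3 || stats::sd(value[ok]) == 0) return(NA_real_)
  stats::cor(value[ok], timepoint[ok], method = "spearman")
}

#' Summarize a pipeline run directory
#'
#' Aggregates the stage tables written by [run_pipeline()] into one
#' machine-readable summary — metaweb sizes, module count and sizes, means
#' +/- sd and temporal Spearman trends of the per-sample metrics, NRI/NTI and
#' diversity — and writes `summary.json` plus a `manifest.txt` of file
#' hashes. Every reported number is recomputed from the stage TSVs.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param require_nulls Error when `nulls.tsv` is absent (default FALSE).
#' @return The summary, invisibly (a nested list).
#' @export
summarize_run <- function(run_dir, require_nulls = FALSE) {
  need <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) {
      stop("missing stage output: ", name, " (stage not run?)", call. = FALSE)
    }
    readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
  }
  edges <- need("edges.tsv")
  partition <- need("partition.tsv")
  topology <- need("topology.tsv")
  dispersion <- need("dispersion.tsv")
  alpha <- need("alpha.tsv")
  if (require_nulls || file.exists(file.path(run_dir, "nulls.tsv"))) {
    nulls <- need("nulls.tsv")
  } else nulls <- NULL
  log_path <- file.path(run_dir, "run_log.json")
  run_log <- if (file.exists(log_path)) jsonlite::read_json(log_path) else NULL
  msd <- function(x) list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  trend_of <- function(df, col) spearman_trend(df[[col]], df$timepoint)
  mod_sizes <- as.list(table(partition$module))
  summary <- list(
    metaweb = list(
      n_nodes = length(unique(c(edges$node_a, edges$node_b))),
      n_cooccurrence_edges = sum(edges$layer == "cooccurrence"),
      n_coexclusion_edges = sum(edges$layer == "coexclusion")),
    modules = list(n_modules = length(mod_sizes), sizes = mod_sizes),
    topology = list(
      modularity = c(msd(topology$modularity),
                     trend = trend_of(topology, "modularity")),
      clustering = c(msd(topology$clustering),
                     trend = trend_of(topology, "clustering")),
      coexclusion_proportion = c(msd(topology$coexclusion_proportion),
                                 trend = trend_of(topology, "coexclusion_proportion"))),
    dispersion = list(nri = c(msd(dispersion$nri), trend = trend_of(dispersion, "nri")),
                      nti = c(msd(dispersion$nti), trend = trend_of(dispersion, "nti"))),
    diversity = lapply(stats::setNames(nm = intersect(c("q0", "q1", "q2", "pd0"),
                                                      names(alpha))),
                       function(cn) c(msd(alpha[[cn]]), trend = trend_of(alpha, cn))),
    config = run_log$config, seed = run_log$seed)
  if (!is.null(nulls)) {
    summary$null_z <- lapply(split(nulls, nulls$metric),
                             function(df) msd(df$z))
  }
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(run_dir), "manifest.txt")
  hashes <- tools::md5sum(file.path(run_dir, files))
  writeLines(sprintf("%s  %s", unname(hashes), files),
             file.path(run_dir, "manifest.txt"))
  invisible(summary)
}
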