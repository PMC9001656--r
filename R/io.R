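#' Read an ASV count table and its sample map
#'
#' The count table is a TSV whose header row holds sample ids and whose first
#' column holds ASV ids; the sample map is a CSV with columns
#' `sample_id,timepoint,replicate`. Both are validated into a [count_data]
#' bundle.
#'
#' @param path Path to the counts TSV.
#' @param sample_map_path Path to the sample map CSV.
#' @return A [count_data] object.
#' @export
read_count_table <- function(path, sample_map_path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(counts) >= 1L) names(counts)[1] <- "asv_id"
  counts$asv_id <- as.character(counts$asv_id)
  if (nrow(counts) == 0L) { # header-only: column types are indeterminate
    counts[, -1] <- lapply(counts[, -1, drop = FALSE], as.integer)
  }
  nonnum <- names(counts)[-1][!vapply(counts[, -1, drop = FALSE], is.numeric, TRUE)]
  if (length(nonnum)) {
    stop("non-numeric count column(s): ", paste(nonnum, collapse = ", "), call. = FALSE)
  }
  samples <- readr::read_csv(sample_map_path, col_types = readr::cols(), progress = FALSE)
  count_data(counts, samples)
}

#' Write a count table and sample map
#'
#' Inverse of [read_count_table()]; round trips preserve values exactly.
#'
#' @param cd A [count_data] object.
#' @param path Output TSV path for the counts.
#' @param sample_map_path Output CSV path for the sample map.
#' @return `cd`, invisibly.
#' @export
write_count_table <- function(cd, path, sample_map_path) {
  readr::write_tsv(cd$counts, path, progress = FALSE)
  readr::write_csv(cd$samples, sample_map_path, progress = FALSE)
  invisible(cd)
}

#' Read sample metadata
#'
#' Expects a CSV keyed by `sample_id` with a `temperature` column (degrees C)
#' and influent/effluent concentrations `bod_in, bod_out, tn_in, tn_out,
#' tp_in, tp_out` (mg/L). Extra columns are kept.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata needs a sample_id column", call. = FALSE)
  }
  meta
}

#' Read a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with the validation the pipeline needs: terminal
#' semicolon required, branch lengths present and non-negative, unique tip
#' labels. Quoted labels are allowed; internal node labels are ignored.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";\\s*$", txt)) {
    stop("Newick string must end with a semicolon", call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("unparseable Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable Newick file", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree is missing branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be present and non-negative", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  tree
}

check_tree_covers <- function(tree, ids) {
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing)) {
    stop("tree tips do not cover ASVs: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a metaweb to GraphML and a TSV edge list
#'
#' The GraphML file carries a `module` node attribute (when a partition is
#' given) and a `layer` edge attribute (`cooccurrence` or `coexclusion`);
#' the TSV edge list has columns `node_a, node_b, layer, p_value`.
#'
#' @param metaweb A [build_metaweb()] result.
#' @param graphml_path Output GraphML path.
#' @param edges_path Output TSV edge-list path (optional).
#' @param partition Optional [detect_modules()] result for node modules.
#' @return The igraph object written, invisibly.
#' @export
write_network <- function(metaweb, graphml_path, edges_path = NULL, partition = NULL) {
  g <- metaweb_graph(metaweb, layer = "both")
  if (!is.null(partition)) {
    mod <- partition$module[match(igraph::V(g)$name, partition$asv_id)]
    igraph::V(g)$module <- as.integer(mod)
  }
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    edges <- metaweb$edges
    out <- tibble::tibble(node_a = edges$asv_a, node_b = edges$asv_b,
                          layer = edges$layer, p_value = edges$p_value)
    readr::write_tsv(out, edges_path, progress = FALSE)
  }
  invisible(g)
}

#' Read a network written by [write_network()]
#'
#' @param graphml_path Path to a GraphML file.
#' @return An undirected igraph with `layer` edge attribute.
#' @export
read_network <- function(graphml_path) {
  igraph::read_graph(graphml_path, format = "graphml")
}

#' Pipeline configuration
#'
#' Central knobs shared across stages, with the defaults the pipeline was
#' designed around.
#'
#' @param significance Tail-probability threshold for classifying a pair as
#'   co-occurring/co-excluding (default 0.95).
#' @param walk_length Walktrap random-walk length (default 4).
#' @param n_sbm Stochastic-block-model null iterations (default 1000).
#' @param n_phylo Taxa-shuffle null iterations for NRI/NTI (default 999).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @param seed Master RNG seed (integer).
#' @param presence_threshold A taxon is "present" in a sample when its count
#'   exceeds this value (default 0).
#' @param inclusive Use `>=` (TRUE, default) vs `>` (FALSE) when comparing
#'   tail probabilities to `significance`.
#' @return A `run_config` list.
#' @export
run_config <- function(significance = 0.95, walk_length = 4L, n_sbm = 1000L,
                       n_phylo = 999L, fdr = 0.05, seed = 1L,
                       presence_threshold = 0, inclusive = TRUE) {
  stopifnot(significance > 0, significance < 1, n_sbm >= 1, n_phylo >= 1,
            fdr > 0, fdr < 1, walk_length >= 1)
  structure(list(significance = significance, walk_length = as.integer(walk_length),
                 n_sbm = as.integer(n_sbm), n_phylo = as.integer(n_phylo),
                 fdr = fdr, seed = as.integer(seed),
                 presence_threshold = presence_threshold,
                 inclusive = isTRUE(inclusive)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys missing from the file fall back to [run_config()] defaults; unknown
#' keys are an error.
#'
#' @param path Path to a YAML key/value file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}
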