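#' Detect metaweb modules with walktrap
#'
#' Runs walktrap (short random walks, agglomerative merging, cut at the
#' maximum-modularity level) on the co-occurrence layer. Vertices are ordered
#' by sorted ASV id before clustering so results are reproducible; isolated
#' nodes get singleton modules.
#'
#' @param metaweb A [build_metaweb()] result.
#' @param walk_length Random-walk length (default 4).
#' @param seed Optional integer seed.
#' @return A `module_partition` tibble with columns `asv_id` and `module`
#'   (contiguous integers, largest module first), carrying the modularity `Q`
#'   of the partition on the co-occurrence layer as attribute `"Q"`.
#' @export
detect_modules <- function(metaweb, walk_length = 4L, seed = NULL) {
  g <- metaweb_graph(metaweb, "cooccurrence")
  partition_graph(g, walk_length = walk_length, seed = seed)
}

#' Walktrap partition of an arbitrary graph
#'
#' The same walktrap procedure [detect_modules()] applies to the metaweb's
#' co-occurrence layer, exposed for standalone graphs (used for
#' per-timepoint partitions and recovery benchmarks).
#'
#' @param g An undirected igraph with named vertices.
#' @param walk_length Random-walk length (default 4).
#' @param seed Optional integer seed.
#' @return A `module_partition` tibble (see [detect_modules()]).
#' @export
partition_graph <- function(g, walk_length = 4L, seed = NULL) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("v%06d", seq_len(igraph::vcount(g)))
  }
  ord <- order(igraph::V(g)$name)
  g <- igraph::permute(g, order(ord))
  run <- function() {
    if (igraph::vcount(g) == 0L) {
      memb <- integer(0)
    } else if (igraph::ecount(g) == 0L) {
      memb <- seq_len(igraph::vcount(g))
    } else {
      memb <- as.integer(igraph::membership(
        igraph::cluster_walktrap(g, steps = walk_length)))
    }
    memb
  }
  memb <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  # relabel contiguously, largest module first, ties by first appearance
  if (length(memb)) {
    sizes <- table(memb)
    new_lab <- rank(-as.vector(sizes), ties.method = "first")
    names(new_lab) <- names(sizes)
    memb <- as.integer(new_lab[as.character(memb)])
  }
  q <- if (igraph::ecount(g) > 0L) igraph::modularity(g, memb) else NA_real_
  out <- tibble::tibble(asv_id = igraph::V(g)$name, module = memb)
  class(out) <- c("module_partition", class(out))
  attr(out, "Q") <- q
  out
}

#' @rdname detect_modules
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_modules = length(unique(x$module)),
                 n_nodes = nrow(x), modularity = attr(x, "Q"))
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c (e_c/m - (d_c/2m)^2) over modules c, with m the edge count,
#' e_c within-module edges and d_c the module degree sum. Returns `NA` for
#' an edgeless graph (undefined, not 0).
#'
#' @param graph An undirected igraph.
#' @param membership Integer module labels, one per vertex, or a
#'   `module_partition` whose `asv_id`s cover the graph's vertices.
#' @return Modularity Q, or `NA_real_` when the graph has no edges.
#' @export
network_modularity <- function(graph, membership) {
  if (inherits(membership, "module_partition") || is.data.frame(membership)) {
    idx <- match(igraph::V(graph)$name, membership$asv_id)
    if (anyNA(idx)) stop("partition is missing graph vertices", call. = FALSE)
    membership <- membership$module[idx]
  }
  if (length(membership) != igraph::vcount(graph)) {
    stop("membership length must equal vertex count", call. = FALSE)
  }
  if (igraph::ecount(graph) == 0L) return(NA_real_)
  igraph::modularity(graph, membership)
}

#' Clustering coefficient (transitivity)
#'
#' Global transitivity (3 x triangles / connected triples) by default;
#' average local clustering behind `type = "average_local"`. Graphs without
#' connected triples return `NA` (undefined).
#'
#' @param graph An undirected igraph.
#' @param type `"global"` (default) or `"average_local"`.
#' @return The clustering coefficient, or `NA_real_` when undefined.
#' @export
clustering_coefficient <- function(graph, type = c("global", "average_local")) {
  type <- match.arg(type)
  val <- if (type == "global") {
    igraph::transitivity(graph, type = "global")
  } else {
    igraph::transitivity(graph, type = "localaverage", isolates = "NaN")
  }
  if (is.nan(val)) NA_real_ else val
}

#' Co-exclusion proportion of a timepoint network
#'
#' Fraction of a sample's induced edges that are co-exclusions:
#' e_excl / (e_excl + e_cooc). `NA` when the sample induces no edges at all.
#' The node-based variant (fraction of present metaweb nodes touched by at
#' least one co-exclusion edge) is available via `basis = "nodes"`.
#'
#' @param n_coexclusion,n_cooccurrence Induced edge counts, or igraphs
#'   (vectors recycle).
#' @param basis `"edges"` (default) or `"nodes"`; `"nodes"` requires graphs.
#' @return Proportion in [0, 1], or `NA_real_`.
#' @export
coexclusion_proportion <- function(n_coexclusion, n_cooccurrence, basis = c("edges", "nodes")) {
  basis <- match.arg(basis)
  if (igraph::is_igraph(n_coexclusion)) {
    g_ex <- n_coexclusion; g_oc <- n_cooccurrence
    if (basis == "nodes") {
      present <- igraph::vcount(g_ex)
      if (present == 0L) return(NA_real_)
      touched <- sum(igraph::degree(g_ex) > 0)
      return(touched / present)
    }
    n_coexclusion <- igraph::ecount(g_ex)
    n_cooccurrence <- igraph::ecount(g_oc)
  } else if (basis == "nodes") {
    stop("basis = \"nodes\" needs igraph inputs", call. = FALSE)
  }
  tot <- n_coexclusion + n_cooccurrence
  ifelse(tot == 0, NA_real_, n_coexclusion / tot)
}

#' Module completeness per sample
#'
#' The fraction of each module's nodes present in each individual sample.
#'
#' @param partition A [detect_modules()] result.
#' @param occ An [occurrence_matrix()] covering the partition's ASVs.
#' @return A tibble: `sample_id`, `timepoint`, `replicate`, `module`,
#'   `n_present`, `module_size`, `completeness`.
#' @export
module_completeness <- function(partition, occ) {
  idx <- match(partition$asv_id, rownames(occ$presence))
  if (anyNA(idx)) stop("occurrence matrix is missing partition ASVs", call. = FALSE)
  pres <- occ$presence[idx, , drop = FALSE]
  mods <- sort(unique(partition$module))
  per_mod <- purrr::map_dfr(mods, function(m) {
    rows <- partition$module == m
    size <- sum(rows)
    n_present <- colSums(pres[rows, , drop = FALSE])
    tibble::tibble(sample_id = colnames(pres), module = m,
                   n_present = as.integer(n_present), module_size = size,
                   completeness = n_present / size)
  })
  dplyr::left_join(per_mod, occ$samples, by = "sample_id") |>
    dplyr::select("sample_id", "timepoint", "replicate", "module",
                  "n_present", "module_size", "completeness") |>
    dplyr::arrange(.data$timepoint, .data$replicate, .data$module)
}

#' Per-sample timepoint networks and their topology
#'
#' For every sample, induces the co-occurrence and co-exclusion subgraphs of
#' the metaweb on the ASVs present in that sample and computes modularity
#' (from a fresh walktrap partition of the induced co-occurrence subgraph,
#' or from the inherited metaweb partition when `partition` is supplied and
#' `fresh_partition = FALSE`), the clustering coefficient, and the
#' co-exclusion proportion. Samples inducing fewer than 2 metaweb nodes get
#' `NA` metrics.
#'
#' @param metaweb A [build_metaweb()] result.
#' @param occ An [occurrence_matrix()] on the same samples.
#' @param partition Optional metaweb partition (needed when
#'   `fresh_partition = FALSE`).
#' @param fresh_partition Recompute walktrap per induced subgraph (default
#'   TRUE).
#' @param walk_length,seed Passed to walktrap.
#' @param clustering_type Passed to [clustering_coefficient()].
#' @param coexclusion_basis Passed to [coexclusion_proportion()].
#' @return A `timepoint_networks` tibble (`sample_id`, `timepoint`,
#'   `replicate`, `n_nodes`, `n_cooccurrence`, `n_coexclusion`, `modularity`,
#'   `clustering`, `coexclusion_proportion`), with the induced igraph pairs
#'   in attribute `"graphs"`.
#' @export
extract_timepoint_networks <- function(metaweb, occ, partition = NULL,
                                       fresh_partition = TRUE,
                                       walk_length = 4L, seed = NULL,
                                       clustering_type = "global",
                                       coexclusion_basis = "edges") {
  if (!fresh_partition && is.null(partition)) {
    stop("inherited scoring needs `partition`", call. = FALSE)
  }
  pres <- occ$presence
  node_ids <- metaweb$nodes$asv_id
  in_occ <- intersect(node_ids, rownames(pres))
  g_oc_full <- metaweb_graph(metaweb, "cooccurrence")
  g_ex_full <- metaweb_graph(metaweb, "coexclusion")
  graphs <- list()
  rows <- purrr::map_dfr(seq_len(ncol(pres)), function(j) {
    sid <- colnames(pres)[j]
    present <- in_occ[pres[in_occ, j]]
    g_oc <- igraph::induced_subgraph(g_oc_full, present)
    g_ex <- igraph::induced_subgraph(g_ex_full, present)
    graphs[[sid]] <<- list(cooccurrence = g_oc, coexclusion = g_ex)
    n_nodes <- length(present)
    if (n_nodes < 2L) {
      mod <- clus <- cprop <- NA_real_
    } else {
      memb <- if (fresh_partition) {
        sub_seed <- if (is.null(seed)) NULL else seed + j
        partition_graph(g_oc, walk_length = walk_length, seed = sub_seed)
      } else {
        partition
      }
      mod <- network_modularity(g_oc, memb)
      clus <- clustering_coefficient(g_oc, clustering_type)
      cprop <- coexclusion_proportion(g_ex, g_oc, coexclusion_basis)
    }
    tibble::tibble(sample_id = sid, n_nodes = n_nodes,
                   n_cooccurrence = as.integer(igraph::ecount(g_oc)),
                   n_coexclusion = as.integer(igraph::ecount(g_ex)),
                   modularity = mod, clustering = clus,
                   coexclusion_proportion = cprop)
  })
  out <- dplyr::left_join(rows, occ$samples, by = "sample_id") |>
    dplyr::select("sample_id", "timepoint", "replicate", dplyr::everything()) |>
    dplyr::arrange(.data$timepoint, .data$replicate)
  class(out) <- c("timepoint_networks", class(out))
  attr(out, "graphs") <- graphs
  out
}

#' Per-sample metaweb module counts
#'
#' How many present metaweb nodes each sample contributes to each module —
#' the block sizes the SBM null draws from.
#'
#' @inheritParams module_completeness
#' @return A tibble `sample_id` x `module` x `n_present`.
#' @export
sample_module_counts <- function(partition, occ) {
  module_completeness(partition, occ) |>
    dplyr::select("sample_id", "timepoint", "replicate", "module", "n_present")
}
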