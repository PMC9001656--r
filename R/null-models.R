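#' Fit a stochastic block model to the metaweb
#'
#' For each layer and each module pair (k, l), the Bernoulli edge probability
#' is the observed edge count between k and l divided by the number of
#' possible pairs (n_k n_l between blocks, n_k(n_k-1)/2 within). A plain
#' (non-degree-corrected) SBM: the minimal model that preserves the block
#' structure while matching expected edge counts exactly.
#'
#' @param metaweb A [build_metaweb()] result.
#' @param partition A [detect_modules()] partition covering the metaweb nodes.
#' @return A `block_model`: list with `modules` (labels), `sizes`, and
#'   symmetric probability matrices `p_cooccurrence`, `p_coexclusion`.
#' @export
fit_sbm <- function(metaweb, partition) {
  idx <- match(metaweb$nodes$asv_id, partition$asv_id)
  if (anyNA(idx)) stop("partition does not cover metaweb nodes", call. = FALSE)
  memb <- partition$module[idx]
  mods <- sort(unique(memb))
  k <- length(mods)
  sizes <- as.integer(table(factor(memb, levels = mods)))
  possible <- outer(sizes, sizes)
  diag(possible) <- sizes * (sizes - 1) / 2
  layer_matrix <- function(layer) {
    edges <- metaweb$edges[metaweb$edges$layer == layer, , drop = FALSE]
    ma <- match(match(edges$asv_a, metaweb$nodes$asv_id), seq_along(memb))
    ka <- memb[match(edges$asv_a, metaweb$nodes$asv_id)]
    kb <- memb[match(edges$asv_b, metaweb$nodes$asv_id)]
    counts <- matrix(0, k, k, dimnames = list(mods, mods))
    for (i in seq_along(ka)) {
      a <- as.character(ka[i]); b <- as.character(kb[i])
      counts[a, b] <- counts[a, b] + 1
      if (a != b) counts[b, a] <- counts[b, a] + 1
    }
    p <- ifelse(possible > 0, counts / possible, 0)
    dimnames(p) <- list(mods, mods)
    p
  }
  structure(list(modules = mods, sizes = stats::setNames(sizes, mods),
                 p_cooccurrence = layer_matrix("cooccurrence"),
                 p_coexclusion = layer_matrix("coexclusion")),
            class = "block_model")
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf("<block_model> %d blocks (sizes %s)\n", length(x$modules),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Expected edge count of a fitted block model
#'
#' @param block_model A [fit_sbm()] result.
#' @param layer Which layer's probability matrix to use.
#' @param sizes Optional block sizes (defaults to the fitted sizes).
#' @return Expected number of edges (moment-matching check: equals the
#'   observed count at the fitted sizes).
#' @export
sbm_expected_edges <- function(block_model, layer = c("cooccurrence", "coexclusion"),
                               sizes = NULL) {
  layer <- match.arg(layer)
  p <- block_model[[paste0("p_", layer)]]
  if (is.null(sizes)) sizes <- block_model$sizes
  possible <- outer(sizes, sizes)
  diag(possible) <- sizes * (sizes - 1) / 2
  sum(p[upper.tri(p, diag = FALSE)] * possible[upper.tri(possible)]) +
    sum(diag(p) * diag(possible))
}

#' Draw one synthetic timepoint network from a block model
#'
#' Generates fresh nodes with the observed per-module counts of a sample and
#' wires each layer independently as a Bernoulli SBM, then computes the three
#' timepoint metrics on the draw.
#'
#' @param block_model A [fit_sbm()] result.
#' @param module_counts Named integer vector: nodes per module in the sample
#'   (names matching `block_model$modules`).
#' @param walk_length,seed Walktrap settings for the null modularity.
#' @param clustering_type,coexclusion_basis As in
#'   [extract_timepoint_networks()].
#' @return A list with `graphs` (the two igraphs) and `metrics` (one-row
#'   tibble: modularity, clustering, coexclusion_proportion).
#' @export
sample_null_timepoint <- function(block_model, module_counts, walk_length = 4L,
                                  seed = NULL, clustering_type = "global",
                                  coexclusion_basis = "edges") {
  run <- function() {
    counts <- module_counts[as.character(block_model$modules)]
    counts[is.na(counts)] <- 0L
    n <- sum(counts)
    keep <- counts > 0
    draw <- function(p) {
      if (n == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
      igraph::sample_sbm(n, pref.matrix = p[keep, keep, drop = FALSE],
                         block.sizes = counts[keep])
    }
    g_oc <- draw(block_model$p_cooccurrence)
    g_ex <- draw(block_model$p_coexclusion)
    igraph::V(g_oc)$name <- sprintf("n%05d", seq_len(igraph::vcount(g_oc)))
    igraph::V(g_ex)$name <- sprintf("n%05d", seq_len(igraph::vcount(g_ex)))
    if (n < 2L) {
      mod <- clus <- cprop <- NA_real_
    } else {
      memb <- partition_graph(g_oc, walk_length = walk_length)
      mod <- network_modularity(g_oc, memb)
      clus <- clustering_coefficient(g_oc, clustering_type)
      cprop <- coexclusion_proportion(g_ex, g_oc, coexclusion_basis)
    }
    list(graphs = list(cooccurrence = g_oc, coexclusion = g_ex),
         metrics = tibble::tibble(modularity = mod, clustering = clus,
                                  coexclusion_proportion = cprop))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' SBM null distributions for timepoint-network metrics
#'
#' For every sample, draws `n_iter` synthetic timepoint networks from the
#' fitted block model (matching the sample's per-module node counts) and
#' standardizes the observed metrics: z = (obs - null mean) / null sd.
#' Undefined draws (e.g. edgeless graphs) are excluded from the null mean/sd;
#' undefined observed metrics, or null sd of 0, propagate as `NA` z.
#'
#' @param metaweb,partition,occ Upstream artifacts.
#' @param n_iter Null iterations per sample (default 1000; must be >= 2).
#' @param seed Integer seed; same seed gives identical tables.
#' @param observed Optional precomputed [extract_timepoint_networks()] table
#'   (recomputed if missing).
#' @param walk_length,clustering_type,coexclusion_basis Metric settings,
#'   shared by observed and null networks.
#' @return A `null_distributions` tibble: `sample_id`, `timepoint`,
#'   `replicate`, `metric`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `n_iter`, `n_defined`.
#' @export
null_distributions <- function(metaweb, partition, occ, n_iter = 1000L, seed = 1L,
                               observed = NULL, walk_length = 4L,
                               clustering_type = "global",
                               coexclusion_basis = "edges") {
  if (n_iter < 2L) stop("n_iter must be at least 2 (sd undefined otherwise)", call. = FALSE)
  if (is.null(observed)) {
    observed <- extract_timepoint_networks(metaweb, occ, walk_length = walk_length,
                                           seed = seed,
                                           clustering_type = clustering_type,
                                           coexclusion_basis = coexclusion_basis)
  }
  bm <- fit_sbm(metaweb, partition)
  counts_tbl <- sample_module_counts(partition, occ)
  metrics <- c("modularity", "clustering", "coexclusion_proportion")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(observed)), function(i) {
      sid <- observed$sample_id[i]
      mc <- counts_tbl[counts_tbl$sample_id == sid, ]
      module_counts <- stats::setNames(mc$n_present, mc$module)
      null_mat <- matrix(NA_real_, n_iter, 3, dimnames = list(NULL, metrics))
      for (it in seq_len(n_iter)) {
        null_mat[it, ] <- unlist(sample_null_timepoint(
          bm, module_counts, walk_length = walk_length,
          clustering_type = clustering_type,
          coexclusion_basis = coexclusion_basis)$metrics)
      }
      purrr::map_dfr(metrics, function(m) {
        vals <- null_mat[, m]
        vals <- vals[!is.na(vals)]
        mu <- if (length(vals)) mean(vals) else NA_real_
        sdv <- if (length(vals) >= 2) stats::sd(vals) else NA_real_
        obs <- observed[[m]][i]
        z <- if (is.na(obs) || is.na(sdv) || sdv == 0) NA_real_ else (obs - mu) / sdv
        tibble::tibble(sample_id = sid, timepoint = observed$timepoint[i],
                       replicate = observed$replicate[i], metric = m,
                       observed = obs, null_mean = mu, null_sd = sdv, z = z,
                       n_iter = n_iter, n_defined = length(vals))
      })
    })
  })
}
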