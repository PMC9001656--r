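#' Presence/absence matrix with timepoint occupancy
#'
#' Converts counts to presence per individual sample (each replicate is a
#' sample) and tallies, per ASV, the number of timepoints where it is present
#' in at least one replicate.
#'
#' @param cd A [count_data] object.
#' @param threshold Presence means count strictly greater than this (default 0).
#' @return An `occurrence_matrix`: list with `presence` (logical ASV x sample
#'   matrix), `samples` (the sample map tibble), `occupancy` (tibble with
#'   `asv_id`, `n_samples_present`, `n_timepoints_present`) and `n_timepoints`.
#' @export
occurrence_matrix <- function(cd, threshold = 0) {
  m <- as.matrix(cd)
  pres <- m > threshold
  tps <- cd$samples$timepoint[match(colnames(pres), cd$samples$sample_id)]
  utp <- sort(unique(tps))
  # ASV x timepoint: present in >=1 replicate of the timepoint
  tp_pres <- vapply(utp, function(t) {
    cols <- which(tps == t)
    if (length(cols) == 1L) pres[, cols] else rowSums(pres[, cols, drop = FALSE]) > 0
  }, logical(nrow(pres)))
  if (is.null(dim(tp_pres))) tp_pres <- matrix(tp_pres, nrow = nrow(pres))
  occupancy <- tibble::tibble(
    asv_id = rownames(pres),
    n_samples_present = unname(rowSums(pres)),
    n_timepoints_present = unname(rowSums(tp_pres))
  )
  structure(list(presence = pres, samples = cd$samples, occupancy = occupancy,
                 n_timepoints = length(utp), threshold = threshold),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix> %d ASVs x %d samples, %d timepoints\n",
              nrow(x$presence), ncol(x$presence), x$n_timepoints))
  invisible(x)
}

#' Occurrence filter: drop one-timepoint and every-timepoint ASVs
#'
#' Retains only ASVs present in more than one timepoint but not in every
#' timepoint (occupancy counted at the timepoint level: present in at least
#' one replicate). The sample set is unchanged.
#'
#' @param cd A [count_data] object with at least 2 timepoints.
#' @param threshold Presence threshold, see [occurrence_matrix()].
#' @return A filtered [count_data] object (possibly with zero ASVs, with a
#'   warning).
#' @export
filter_by_occurrence <- function(cd, threshold = 0) {
  occ <- occurrence_matrix(cd, threshold)
  if (occ$n_timepoints < 2L) stop("need at least 2 timepoints", call. = FALSE)
  t_occ <- occ$occupancy$n_timepoints_present
  keep <- t_occ > 1L & t_occ < occ$n_timepoints
  if (!any(keep)) warning("occurrence filter removed every ASV")
  count_data(cd$counts[keep, , drop = FALSE], cd$samples)
}

#' Exact hypergeometric tail probabilities for a pair of presence vectors
#'
#' Under random, independent placement of two taxa occupying `n_a` and `n_b`
#' of `n_samples` samples, the number of shared samples J is hypergeometric:
#' P(J = j) = C(n_a, j) C(N - n_a, n_b - j) / C(N, n_b). The co-occurrence
#' probability `p_lt` is P(J < j_obs) (a random pair shares fewer samples than
#' observed) and the co-exclusion probability `p_gt` is P(J > j_obs). All
#' arguments are vectorized.
#'
#' @param n_a,n_b Sample occupancies of the two taxa.
#' @param j_obs Observed number of shared samples.
#' @param n_samples Total number of samples N.
#' @return A tibble with columns `p_lt`, `p_gt`, `p_eq`.
#' @export
pair_tail_probabilities <- function(n_a, n_b, j_obs, n_samples) {
  n <- vctrs_size_common(n_a, n_b, j_obs, n_samples)
  n_a <- rep_len(n_a, n); n_b <- rep_len(n_b, n)
  j_obs <- rep_len(j_obs, n); N <- rep_len(n_samples, n)
  if (any(n_a < 0 | n_a > N | n_b < 0 | n_b > N)) {
    stop("occupancies must lie in [0, n_samples]", call. = FALSE)
  }
  lo <- pmax(0, n_a + n_b - N)
  hi <- pmin(n_a, n_b)
  if (any(j_obs < lo | j_obs > hi)) {
    stop("j_obs outside the feasible range [max(0, n_a+n_b-N), min(n_a, n_b)]",
         call. = FALSE)
  }
  p_lt <- stats::phyper(j_obs - 1, n_a, N - n_a, n_b)
  p_gt <- stats::phyper(j_obs, n_a, N - n_a, n_b, lower.tail = FALSE)
  tibble::tibble(p_lt = p_lt, p_gt = p_gt, p_eq = pmax(0, 1 - p_lt - p_gt))
}

vctrs_size_common <- function(...) max(lengths(list(...)))

#' Test all ASV pairs for co-occurrence / co-exclusion
#'
#' @param occ An [occurrence_matrix()].
#' @param significance Tail-probability threshold (default 0.95).
#' @param inclusive Compare tails with `>=` (default) rather than `>`.
#' @return A tibble, one row per unordered pair, with occupancies, observed
#'   joint count, tail probabilities and a `classification` in
#'   {cooccurrence, coexclusion, none}. Pairs whose feasible support is a
#'   single point are classified `none`.
#' @export
pair_associations <- function(occ, significance = 0.95, inclusive = TRUE) {
  pres <- occ$presence
  n_asv <- nrow(pres)
  if (n_asv < 2L) {
    return(tibble::tibble(asv_a = character(), asv_b = character(),
                          n_a = integer(), n_b = integer(), j_obs = integer(),
                          p_lt = double(), p_gt = double(),
                          classification = character()))
  }
  N <- ncol(pres)
  occ_n <- rowSums(pres)
  joint <- tcrossprod(pres * 1L)
  idx <- which(upper.tri(joint), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  tails <- pair_tail_probabilities(occ_n[a], occ_n[b], joint[idx], N)
  cmp <- if (inclusive) `>=` else `>`
  degenerate <- pmax(0, occ_n[a] + occ_n[b] - N) == pmin(occ_n[a], occ_n[b])
  classification <- rep("none", length(a))
  classification[!degenerate & cmp(tails$p_lt, significance)] <- "cooccurrence"
  classification[!degenerate & cmp(tails$p_gt, significance)] <- "coexclusion"
  tibble::tibble(asv_a = rownames(pres)[a], asv_b = rownames(pres)[b],
                 n_a = occ_n[a], n_b = occ_n[b], j_obs = joint[idx],
                 p_lt = tails$p_lt, p_gt = tails$p_gt,
                 classification = classification)
}

#' Build the co-occurrence/co-exclusion metaweb
#'
#' Classifies every unordered pair of filtered ASVs with the exact
#' hypergeometric model and keeps, as metaweb nodes, the ASVs carrying at
#' least one significant edge in either layer.
#'
#' @inheritParams pair_associations
#' @return A `metaweb` object: list with `nodes` (tibble of `asv_id`),
#'   `edges` (tibble: `asv_a`, `asv_b`, `layer`, `probability`, `p_value`),
#'   `pairs` (all tested pairs), `n_samples` and `significance`.
#' @export
build_metaweb <- function(occ, significance = 0.95, inclusive = TRUE) {
  pairs <- pair_associations(occ, significance, inclusive)
  sig <- pairs[pairs$classification != "none", , drop = FALSE]
  prob <- ifelse(sig$classification == "cooccurrence", sig$p_lt, sig$p_gt)
  edges <- tibble::tibble(asv_a = sig$asv_a, asv_b = sig$asv_b,
                          layer = sig$classification,
                          probability = prob, p_value = 1 - prob)
  nodes <- tibble::tibble(asv_id = sort(unique(c(edges$asv_a, edges$asv_b))))
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 n_samples = ncol(occ$presence), significance = significance),
            class = "metaweb")
}

#' @export
print.metaweb <- function(x, ...) {
  cat(sprintf("<metaweb> %d nodes; %d co-occurrence / %d co-exclusion edges (N = %d samples)\n",
              nrow(x$nodes), sum(x$edges$layer == "cooccurrence"),
              sum(x$edges$layer == "coexclusion"), x$n_samples))
  invisible(x)
}

#' @rdname build_metaweb
#' @param x A `metaweb` object.
#' @param ... Unused.
#' @method tidy metaweb
#' @export
tidy.metaweb <- function(x, ...) x$edges

#' @rdname build_metaweb
#' @method glance metaweb
#' @export
glance.metaweb <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes),
                 n_cooccurrence = sum(x$edges$layer == "cooccurrence"),
                 n_coexclusion = sum(x$edges$layer == "coexclusion"),
                 n_samples = x$n_samples, significance = x$significance)
}

#' Extract an igraph layer from a metaweb
#'
#' @param metaweb A `metaweb` object.
#' @param layer `"cooccurrence"`, `"coexclusion"` or `"both"`.
#' @param nodes Optional node subset (character ids) to induce on.
#' @return An undirected igraph whose vertices are ASV ids, with a `layer`
#'   edge attribute.
#' @export
metaweb_graph <- function(metaweb, layer = c("cooccurrence", "coexclusion", "both"),
                          nodes = NULL) {
  layer <- match.arg(layer)
  edges <- metaweb$edges
  if (layer != "both") edges <- edges[edges$layer == layer, , drop = FALSE]
  verts <- metaweb$nodes$asv_id
  if (!is.null(nodes)) {
    verts <- intersect(verts, nodes)
    edges <- edges[edges$asv_a %in% verts & edges$asv_b %in% verts, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$asv_a, to = edges$asv_b,
               layer = edges$layer, p_value = edges$p_value),
    directed = FALSE,
    vertices = data.frame(name = verts))
  g
}
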