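# Small builders shared across test files.

# count_data from a plain matrix; samples default to 1 replicate per timepoint
toy_count_data <- function(mat, timepoints = NULL, replicates = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("asv%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  if (is.null(timepoints)) timepoints <- seq_len(ncol(mat))
  if (is.null(replicates)) replicates <- rep(1L, ncol(mat))
  count_data(
    tibble::as_tibble(cbind(tibble::tibble(asv_id = rownames(mat)),
                            tibble::as_tibble(mat))),
    tibble::tibble(sample_id = colnames(mat), timepoint = timepoints,
                   replicate = replicates))
}

# occurrence_matrix straight from a logical presence matrix
toy_occurrence <- function(pres, timepoints = NULL) {
  storage.mode(pres) <- "integer"
  toy_count_data(pres, timepoints = timepoints) |> occurrence_matrix()
}

# metaweb object built directly from edge lists (bypasses the pair model)
toy_metaweb <- function(cooc = NULL, coex = NULL, nodes = NULL, n_samples = 10L) {
  mk <- function(e, layer) {
    if (is.null(e)) return(tibble::tibble(asv_a = character(), asv_b = character(),
                                          layer = character(), probability = double(),
                                          p_value = double()))
    tibble::tibble(asv_a = e[, 1], asv_b = e[, 2], layer = layer,
                   probability = 0.99, p_value = 0.01)
  }
  edges <- rbind(mk(cooc, "cooccurrence"), mk(coex, "coexclusion"))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$asv_a, edges$asv_b)))
  structure(list(nodes = tibble::tibble(asv_id = nodes), edges = edges,
                 pairs = edges, n_samples = n_samples, significance = 0.95),
            class = "metaweb")
}

# edge matrix helper: clique on a set of node names
clique_edges <- function(ids) {
  t(utils::combn(ids, 2))
}

# independent Newman-Girvan modularity, summing over the definition directly
oracle_modularity <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(memb)) {
    in_c <- which(memb == c)
    e_c <- sum(el[, 1] %in% in_c & el[, 2] %in% in_c)
    d_c <- sum(deg[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# brute-force global transitivity: closed triples / connected triples,
# enumerating every path i-j-k (i < k) centred on j
oracle_transitivity <- function(g) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(adj)
  triples <- 0; closed <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < k && j != i && j != k && adj[i, j] && adj[j, k]) {
      triples <- triples + 1
      if (adj[i, k]) closed <- closed + 1
    }
  }
  if (triples == 0) return(NA_real_)
  closed / triples
}
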