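#' Hill number of order q
#'
#' The effective number of equally abundant taxa:
#' ^qD = (sum p_i^q)^(1/(1-q)) for q != 1, and the entropy limit
#' ^1D = exp(-sum p_i log p_i). q = 0 is richness, q = 2 the inverse Simpson
#' index.
#'
#' @param abundances Non-negative numeric vector (any scale; normalized
#'   internally).
#' @param q Diversity order, q >= 0.
#' @return The Hill number, or `NA_real_` for an all-zero vector.
#' @export
hill_number <- function(abundances, q) {
  stopifnot(q >= 0)
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(abundances)
  if (tot == 0) return(NA_real_)
  p <- abundances[abundances > 0] / tot
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Phylogenetic Hill number (branch-segment formulation)
#'
#' The effective number of equally distinct lineages, computed over branch
#' segments: each branch b of length L_b carries the summed relative
#' abundance a_b of its descendant tips, and the abundance-weighted mean
#' depth is Tbar = sum_b L_b a_b. Then
#' ^qpD = ( sum_b (L_b / Tbar) a_b^q )^(1/(1-q)) for q != 1 (entropy limit at
#' q = 1). At q = 0 this is Faith's PD of the present taxa divided by Tbar.
#' A single present taxon returns 1 by convention.
#'
#' @param abundances Named non-negative vector; names must be tree tips.
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param q Diversity order (default 0).
#' @return The phylogenetic Hill number, or `NA_real_` for an all-zero
#'   vector.
#' @export
phylo_hill_number <- function(abundances, tree, q = 0) {
  stopifnot(q >= 0)
  tot <- sum(abundances)
  if (tot == 0) return(NA_real_)
  if (is.null(names(abundances))) stop("abundances must be named by tip label", call. = FALSE)
  check_tree_covers(tree, names(abundances)[abundances > 0])
  if (sum(abundances > 0) == 1L) return(1)
  seg <- branch_segments(tree)
  p <- abundances / tot
  a_b <- vapply(seg$tips, function(tp) sum(p[intersect(tp, names(p))]), 0)
  keep <- a_b > 0
  L <- seg$length[keep]; a_b <- a_b[keep]
  tbar <- sum(L * a_b)
  if (q == 1) {
    exp(-sum(L / tbar * a_b * log(a_b)))
  } else {
    sum((L / tbar) * a_b^q)^(1 / (1 - q))
  }
}

# Branch lengths and descendant-tip sets for every edge of the tree.
branch_segments <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  tips_below <- vector("list", n_tip + tree$Nnode)
  fill <- function(node) {
    if (node <= n_tip) {
      tips_below[[node]] <<- tree$tip.label[node]
    } else {
      acc <- character(0)
      for (ch in kids[[node]]) {
        fill(ch)
        acc <- c(acc, tips_below[[ch]])
      }
      tips_below[[node]] <<- acc
    }
  }
  fill(n_tip + 1L)
  list(length = tree$edge.length,
       tips = lapply(tree$edge[, 2], function(nd) tips_below[[nd]]))
}

#' Alpha-diversity table
#'
#' Per-sample taxonomic Hill numbers ^0D, ^1D, ^2D and (when a tree is given)
#' the phylogenetic Hill number ^0pD.
#'
#' @param cd A [count_data] object.
#' @param tree Optional [ape::phylo] tree covering the ASVs.
#' @return A tibble: `sample_id`, `timepoint`, `replicate`, `q0`, `q1`, `q2`,
#'   and `pd0` when a tree is supplied.
#' @export
alpha_diversity <- function(cd, tree = NULL) {
  m <- as.matrix(cd)
  out <- tibble::tibble(
    sample_id = colnames(m),
    q0 = apply(m, 2, hill_number, q = 0),
    q1 = apply(m, 2, hill_number, q = 1),
    q2 = apply(m, 2, hill_number, q = 2))
  if (!is.null(tree)) {
    check_tree_covers(tree, rownames(m)[rowSums(m) > 0])
    out$pd0 <- apply(m, 2, function(col) {
      names(col) <- rownames(m)
      phylo_hill_number(col, tree, q = 0)
    })
  }
  dplyr::left_join(out, cd$samples, by = "sample_id") |>
    dplyr::select("sample_id", "timepoint", "replicate", dplyr::everything())
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(s, t) = 1 - 2 sum_i min(a_is, a_it) / (sum_i a_is + sum_i a_it),
#' computed on raw counts. Pairs of all-zero samples are undefined (NA).
#'
#' @param cd A [count_data] object with at least 2 samples.
#' @return A symmetric sample x sample matrix with zero diagonal.
#' @export
bray_curtis <- function(cd) {
  m <- as.matrix(cd)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  zero <- colSums(m) == 0
  bc <- suppressWarnings(as.matrix(vegan::vegdist(t(m), method = "bray")))
  if (any(zero)) {
    bc[zero, !zero] <- 1 # empty vs non-empty: fully dissimilar
    bc[!zero, zero] <- 1
    bc[zero, zero] <- NA_real_
  }
  diag(bc) <- 0
  bc
}
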