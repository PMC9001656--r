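#' Patristic (cophenetic) distance matrix
#'
#' Sum of branch lengths along the tip-to-tip path, for every tip pair.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  stats::cophenetic(tree)
}

#' Abundance-weighted environmental optima
#'
#' For each ASV and each selected environmental variable, the abundance-
#' weighted mean of the variable over samples:
#' optimum(i, v) = sum_s a_is E_sv / sum_s a_is.
#'
#' @param cd A [count_data] object.
#' @param metadata Sample metadata tibble with `sample_id` and the variables.
#' @param variables Character vector of metadata columns (default
#'   temperature and influent BOD/TN/TP).
#' @return A tibble `asv_id` x `variable` x `optimum` (NA for all-zero ASVs).
#' @export
environmental_optima <- function(cd, metadata,
                                 variables = c("temperature", "bod_in", "tn_in", "tp_in")) {
  missing_v <- setdiff(variables, names(metadata))
  if (length(missing_v)) {
    stop("metadata lacks variable(s): ", paste(missing_v, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(cd)
  meta <- metadata[match(colnames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata is missing samples", call. = FALSE)
  tot <- rowSums(m)
  purrr::map_dfr(variables, function(v) {
    env <- meta[[v]]
    opt <- as.vector(m %*% env) / tot
    opt[tot == 0] <- NA_real_
    tibble::tibble(asv_id = rownames(m), variable = v, optimum = opt)
  })
}

#' Euclidean trait distances between ASV optima
#'
#' Optima are z-scored per variable before computing Euclidean distances, so
#' variables on different scales contribute comparably.
#'
#' @param optima An [environmental_optima()] tibble.
#' @return A symmetric distance matrix over ASVs with defined optima.
#' @export
optima_distances <- function(optima) {
  wide <- tidyr::pivot_wider(optima, names_from = "variable", values_from = "optimum")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  m <- scale(as.matrix(wide[, -1, drop = FALSE]))
  m[is.nan(m)] <- 0 # constant variable: no contribution
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(wide$asv_id, wide$asv_id)
  d
}

#' Mantel correlogram of phylogenetic signal
#'
#' Tests whether trait (environmental-optimum) distances track phylogenetic
#' distances within distance classes: phylogenetic distances are binned
#' (Sturges rule), and per class a Mantel statistic between the trait
#' distances and class membership is evaluated against tip-label
#' permutations, with progressive Bonferroni correction across classes.
#'
#' @param trait_dist,phylo_dist Matched symmetric distance matrices (shared
#'   tip ids; `trait_dist` rows are matched to `phylo_dist` by name when
#'   dimnames are present).
#' @param n_permutations Permutations per class (must be >= 1).
#' @param seed Optional integer seed.
#' @return A tibble: `class_index` (class midpoint distance), `n_dist`
#'   (pairs in class), `mantel_r`, `p_value`, `p_corrected`, `significant`
#'   (at 0.05 after correction); classes without testable pairs carry NA.
#' @export
mantel_correlogram <- function(trait_dist, phylo_dist, n_permutations = 999L,
                               seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  trait_dist <- as.matrix(trait_dist); phylo_dist <- as.matrix(phylo_dist)
  if (!is.null(dimnames(trait_dist)[[1]]) && !is.null(dimnames(phylo_dist)[[1]])) {
    shared <- intersect(rownames(trait_dist), rownames(phylo_dist))
    if (length(shared) < 3L) stop("fewer than 3 shared tips", call. = FALSE)
    trait_dist <- trait_dist[shared, shared]
    phylo_dist <- phylo_dist[shared, shared]
  }
  run <- function() {
    vegan::mantel.correlog(stats::as.dist(trait_dist),
                           D.geo = stats::as.dist(phylo_dist),
                           nperm = n_permutations, mult = "bonferroni",
                           progressive = TRUE)
  }
  mc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  res <- as.data.frame(mc$mantel.res)
  tibble::tibble(class_index = res[[1]], n_dist = res[[2]], mantel_r = res[[3]],
                 p_value = res[[4]], p_corrected = res[[5]],
                 significant = !is.na(res[[5]]) & res[[5]] <= 0.05)
}

#' Mean pairwise distance of a community
#'
#' MPD = sum_{i != j} f_i f_j d_ij / sum_{i != j} f_i f_j with f the relative
#' abundances (abundance-weighted, the default) or equal weights over present
#' taxa (`weighted = FALSE`).
#'
#' @param abundances Named numeric vector of (relative) abundances; names
#'   must appear in `dist`.
#' @param dist Symmetric distance matrix.
#' @param weighted Abundance-weight the average (default TRUE).
#' @return MPD, or `NA_real_` with fewer than 2 present taxa.
#' @export
mpd <- function(abundances, dist, weighted = TRUE) {
  x <- community_weights(abundances, dist, weighted)
  if (is.null(x)) return(NA_real_)
  f <- x$f; d <- x$d
  num <- drop(f %*% d %*% f)
  den <- 1 - sum(f^2)
  num / den
}

#' Mean nearest taxon distance of a community
#'
#' MNTD = sum_i f_i min_{j != i} d_ij / sum_i f_i over present taxa.
#'
#' @inheritParams mpd
#' @return MNTD, or `NA_real_` with fewer than 2 present taxa.
#' @export
mntd <- function(abundances, dist, weighted = TRUE) {
  x <- community_weights(abundances, dist, weighted)
  if (is.null(x)) return(NA_real_)
  d <- x$d
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  sum(x$f * nearest)
}

community_weights <- function(abundances, dist, weighted) {
  dist <- as.matrix(dist)
  present <- which(abundances > 0)
  if (length(present) < 2L) return(NULL)
  ids <- names(abundances)[present]
  if (is.null(ids)) {
    d <- dist[present, present]
  } else {
    miss <- setdiff(ids, rownames(dist))
    if (length(miss)) stop("distance matrix missing taxa: ",
                           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    d <- dist[ids, ids]
  }
  f <- abundances[present]
  if (!weighted) f <- rep(1, length(f))
  list(f = f / sum(f), d = d)
}

#' Standardized effect sizes of MPD/MNTD (NRI, NTI)
#'
#' Per sample, compares observed abundance-weighted MPD and MNTD with a
#' taxa-labels null: the tip labels of the distance matrix are shuffled over
#' the full analyzed taxon pool, and MPD/MNTD are recomputed for every
#' sample under each shuffle. SES = (observed - null mean) / null sd;
#' NRI = -SES(MPD), NTI = -SES(MNTD). Positive NRI/NTI indicate
#' phylogenetic clustering (habitat filtering), negative overdispersion.
#'
#' @param cd A [count_data] object (or an ASV x sample numeric matrix).
#' @param dist Distance matrix covering every ASV with positive abundance.
#' @param n_null Number of label shuffles (default 999; ignored for the
#'   exhaustive null).
#' @param seed Integer seed.
#' @param weighted Abundance-weight MPD/MNTD (default TRUE).
#' @param method `"sampling"` (default) draws `n_null` random label
#'   permutations; `"exhaustive"` enumerates every permutation of the pool
#'   (pools of at most 8 taxa), giving the exact null moments.
#' @return A `dispersion_result` tibble, one row per sample: observed MPD and
#'   MNTD, their null means/sds, `ses_mpd`, `ses_mntd`, `nri`, `nti`,
#'   `n_taxa`. Null sd of 0 (or undefined observed) gives NA.
#' @export
ses_dispersion <- function(cd, dist, n_null = 999L, seed = 1L, weighted = TRUE,
                           method = c("sampling", "exhaustive")) {
  method <- match.arg(method)
  if (n_null < 1L) stop("n_null must be >= 1", call. = FALSE)
  m <- if (inherits(cd, "count_data")) as.matrix(cd) else as.matrix(cd)
  dist <- as.matrix(dist)
  pool <- rownames(m) # full analyzed taxon pool, present or not
  miss <- setdiff(pool, rownames(dist))
  if (length(miss)) stop("distance matrix missing taxa: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  d <- dist[pool, pool]
  sub <- m[pool, , drop = FALSE]
  tot <- colSums(sub)
  tot[tot == 0] <- 1
  f_mat <- t(sweep(sub, 2, tot, "/")) # samples x taxa
  if (!weighted) {
    f_mat <- t(apply(f_mat, 1, function(r) { p <- r > 0; p / max(1, sum(p)) }))
  }
  obs <- mpd_mntd_all(f_mat, d)
  n_pool <- length(pool)
  if (method == "exhaustive") {
    if (n_pool > 8L) stop("exhaustive null is limited to pools of <= 8 taxa", call. = FALSE)
    perms <- all_permutations(n_pool)
    n_null <- nrow(perms)
  }
  null_mpd <- matrix(NA_real_, n_null, nrow(f_mat))
  null_mntd <- matrix(NA_real_, n_null, nrow(f_mat))
  withr::with_seed(seed, {
    for (b in seq_len(n_null)) {
      perm <- if (method == "exhaustive") perms[b, ] else sample.int(n_pool)
      nm <- mpd_mntd_all(f_mat, d[perm, perm, drop = FALSE])
      null_mpd[b, ] <- nm$mpd
      null_mntd[b, ] <- nm$mntd
    }
  })
  ses <- function(o, nulls) {
    mu <- colMeans(nulls)
    sdv <- apply(nulls, 2, stats::sd)
    z <- (o - mu) / sdv
    z[is.na(o) | is.na(sdv) | sdv == 0] <- NA_real_
    list(mean = mu, sd = sdv, z = z)
  }
  s_mpd <- ses(obs$mpd, null_mpd)
  s_mntd <- ses(obs$mntd, null_mntd)
  out <- tibble::tibble(
    sample_id = rownames(f_mat),
    n_taxa = rowSums(f_mat > 0),
    mpd_obs = obs$mpd, mpd_null_mean = s_mpd$mean, mpd_null_sd = s_mpd$sd,
    ses_mpd = s_mpd$z, nri = -s_mpd$z,
    mntd_obs = obs$mntd, mntd_null_mean = s_mntd$mean, mntd_null_sd = s_mntd$sd,
    ses_mntd = s_mntd$z, nti = -s_mntd$z)
  if (inherits(cd, "count_data")) {
    out <- dplyr::left_join(out, cd$samples, by = "sample_id") |>
      dplyr::select("sample_id", "timepoint", "replicate", dplyr::everything())
  }
  class(out) <- c("dispersion_result", class(out))
  attr(out, "n_null") <- n_null
  out
}

# Weighted MPD and MNTD for all rows of a samples x taxa proportion matrix.
mpd_mntd_all <- function(f_mat, d) {
  pres_n <- rowSums(f_mat > 0)
  ok <- pres_n >= 2
  mpd_v <- rep(NA_real_, nrow(f_mat))
  den <- 1 - rowSums(f_mat^2)
  mpd_v[ok] <- (rowSums((f_mat %*% d) * f_mat) / den)[ok]
  mntd_v <- rep(NA_real_, nrow(f_mat))
  for (i in which(ok)) {
    idx <- which(f_mat[i, ] > 0)
    dd <- d[idx, idx, drop = FALSE]
    diag(dd) <- Inf
    nearest <- apply(dd, 1, min)
    mntd_v[i] <- sum(f_mat[i, idx] * nearest)
  }
  list(mpd = mpd_v, mntd = mntd_v)
}

#' @rdname ses_dispersion
#' @param x A `dispersion_result`.
#' @param ... Unused.
#' @method glance dispersion_result
#' @export
glance.dispersion_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 nri_mean = mean(x$nri, na.rm = TRUE),
                 nri_sd = stats::sd(x$nri, na.rm = TRUE),
                 nti_mean = mean(x$nti, na.rm = TRUE),
                 nti_sd = stats::sd(x$nti, na.rm = TRUE),
                 n_null = attr(x, "n_null"))
}
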