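# independent patristic oracle: d(i, j) = depth_i + depth_j - 2 depth_mrca
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  mrcas <- ape::mrca(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- depths[i] + depths[j] - 2 * depths[mrcas[i, j]]
  }
  d
}

test_that("cophenetic distances equal hand path sums and the mrca oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- cophenetic_distances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(unname(diag(d)), rep(0, 3))
  t50 <- simulate_tree(50, seed = 21)
  d50 <- cophenetic_distances(t50)
  oracle <- oracle_patristic(t50)
  expect_equal(d50[rownames(oracle), colnames(oracle)], oracle, tolerance = 1e-10)
  # ultrametric depth-1 tree: max distance 2 x depth
  expect_equal(max(d50), 2, tolerance = 1e-8)
})

test_that("environmental optima are abundance-weighted means", {
  mat <- matrix(c(3L, 0L, 2L,
                  0L, 5L, 0L,
                  2L, 0L, 2L,
                  0L, 0L, 0L), 4, 3, byrow = TRUE,
                dimnames = list(c("only20", "mix", "equal", "absent"), NULL))
  cd <- toy_count_data(mat)
  meta <- tibble::tibble(sample_id = colnames(as.matrix(cd)),
                         temperature = c(20, 10, 20))
  opt <- environmental_optima(cd, meta, "temperature")
  get <- function(id) unname(opt$optimum[opt$asv_id == id])
  expect_equal(get("only20"), 20)
  expect_equal(get("mix"), 10)
  expect_equal(get("equal"), 20)
  expect_true(is.na(get("absent")))
  expect_error(environmental_optima(cd, meta, "ph"), "lacks variable")
})

test_that("recovered optima rank-correlate with planted optima", {
  sim <- simulate_scenario(scenario_spec("seasonal"), seed = 41)
  opt <- environmental_optima(sim$counts, sim$metadata, "temperature")
  merged <- dplyr::inner_join(opt, sim$truth, by = "asv_id") |>
    dplyr::filter(role == "core")
  expect_gte(cor(merged$optimum.x, merged$optimum.y, method = "spearman",
                 use = "complete.obs"), 0.7)
})

test_that("Mantel correlogram finds self-signal and rejects bad inputs", {
  tree <- simulate_tree(40, seed = 31)
  pd <- cophenetic_distances(tree)
  mc <- mantel_correlogram(pd, pd, n_permutations = 199, seed = 1)
  expect_gt(mc$mantel_r[1], 0)
  expect_true(mc$significant[1])
  expect_error(mantel_correlogram(pd, pd, n_permutations = 0), ">= 1")
})

test_that("Mantel correlogram detects phylogenetic signal in simulated optima", {
  sim <- simulate_scenario(scenario_spec("seasonal"), seed = 43)
  opt <- environmental_optima(sim$counts, sim$metadata)
  td <- optima_distances(opt)
  pd <- cophenetic_distances(sim$tree)
  mc <- mantel_correlogram(td, pd, n_permutations = 199, seed = 2)
  expect_gt(mc$mantel_r[1], 0) # positive correlation at short distances
  expect_true(mc$significant[1])
})

test_that("MPD and MNTD match their definitions and a brute-force oracle", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  ab <- c(x = 5, y = 1)
  expect_equal(mpd(ab, d2), 3)
  expect_equal(mntd(ab, d2), 3)
  # equal abundances: MPD = mean off-diagonal distance
  tree <- simulate_tree(6, seed = 51)
  d <- cophenetic_distances(tree)
  eq <- setNames(rep(2, 6), rownames(d))
  expect_equal(mpd(eq, d), mean(d[upper.tri(d)]))
  expect_equal(mpd(eq, d, weighted = FALSE), mean(d[upper.tri(d)]))
  # 5-taxon random abundances vs explicit double loop
  ab5 <- setNames(c(4, 1, 0, 2, 3), rownames(d)[1:5])
  present <- names(ab5)[ab5 > 0]
  f <- ab5[present] / sum(ab5[present])
  num <- 0; den <- 0; mn <- 0
  for (i in present) for (j in present) {
    if (i != j) { num <- num + f[i] * f[j] * d[i, j]; den <- den + f[i] * f[j] }
  }
  for (i in present) {
    mn <- mn + f[i] * min(d[i, setdiff(present, i)])
  }
  expect_equal(mpd(ab5, d), unname(num / den))
  expect_equal(mntd(ab5, d), unname(mn))
  expect_true(is.na(mpd(c(x = 1, y = 0), d2)))
})

test_that("SES matches the exhaustive taxa-label permutation null", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:0.5):1);")
  d <- cophenetic_distances(tree)
  mat <- matrix(c(3L, 1L, 2L, 0L), 4, 1,
                dimnames = list(c("A", "B", "C", "D"), "s1"))
  cd <- toy_count_data(mat)
  got <- ses_dispersion(cd, d, method = "exhaustive")
  # oracle: enumerate all 4! label assignments by hand
  f <- c(3, 1, 2) / 6
  perms <- rbind(1, expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))[-1, ]
  perms <- as.matrix(perms[apply(perms, 1, function(r) length(unique(r)) == 4), ])
  vals <- t(apply(perms, 1, function(pm) {
    dd <- d[pm, pm]
    present <- 1:3 # A, B, C hold the abundance
    sub <- dd[present, present]
    mpd_v <- sum(outer(f, f) * sub) / (1 - sum(f^2))
    diag(sub) <- Inf
    mntd_v <- sum(f * apply(sub, 1, min))
    c(mpd_v, mntd_v)
  }))
  obs <- vals[apply(perms, 1, function(p) all(p == 1:4)), ]
  ses_mpd_oracle <- (obs[1] - mean(vals[, 1])) / sd(vals[, 1])
  ses_mntd_oracle <- (obs[2] - mean(vals[, 2])) / sd(vals[, 2])
  expect_equal(got$ses_mpd, ses_mpd_oracle, tolerance = 1e-10)
  expect_equal(got$ses_mntd, ses_mntd_oracle, tolerance = 1e-10)
  expect_equal(got$nri, -ses_mpd_oracle, tolerance = 1e-10)
  expect_equal(got$nti, -ses_mntd_oracle, tolerance = 1e-10)
  # the sampling null converges towards the exhaustive value
  sampled <- ses_dispersion(cd, d, n_null = 4000, seed = 2)
  expect_equal(sampled$ses_mpd, ses_mpd_oracle, tolerance = 0.1)
})

test_that("observed MPD/MNTD agree with picante", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(12, seed = 61)
  d <- cophenetic_distances(tree)
  mat <- withr::with_seed(62, matrix(rpois(12 * 4, 3), 12, 4,
                                     dimnames = list(tree$tip.label, NULL)))
  cd <- toy_count_data(mat)
  got <- ses_dispersion(cd, d, n_null = 9, seed = 1)
  comm <- t(as.matrix(cd))
  pic_mpd <- picante::mpd(comm, d, abundance.weighted = TRUE)
  pic_mntd <- picante::mntd(comm, d, abundance.weighted = TRUE)
  expect_equal(got$mntd_obs, pic_mntd, tolerance = 1e-10)
  # picante keeps self-pairs in the weighted-mean denominator; our MPD
  # excludes them, so the two differ by exactly 1 - sum(f^2). The factor is
  # permutation-invariant, so SES/NRI are identical under either convention.
  f2 <- colSums(apply(comm, 1, function(r) (r / sum(r))^2))
  expect_equal(unname(got$mpd_obs * (1 - f2)), pic_mpd, tolerance = 1e-10)
})

test_that("star phylogenies give undefined SES (null sd 0)", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  cd <- toy_count_data(matrix(c(1L, 1L, 1L, 0L), 4, 1,
                              dimnames = list(letters[1:4], NULL)))
  got <- ses_dispersion(cd, d, n_null = 49, seed = 1)
  expect_true(is.na(got$nri))
  expect_true(is.na(got$nti))
})

test_that("NRI/NTI are invariant to branch-length rescaling", {
  tree <- simulate_tree(15, seed = 71)
  d <- cophenetic_distances(tree)
  mat <- withr::with_seed(72, matrix(rpois(15 * 3, 2), 15, 3,
                                     dimnames = list(tree$tip.label, NULL)))
  cd <- toy_count_data(mat)
  a <- ses_dispersion(cd, d, n_null = 99, seed = 3)
  b <- ses_dispersion(cd, d * 7.3, n_null = 99, seed = 3)
  expect_equal(a$nri, b$nri, tolerance = 1e-10)
  expect_equal(a$nti, b$nti, tolerance = 1e-10)
})

test_that("clustered clades give positive NTI, spread taxa negative", {
  signs <- vapply(1:5, function(sd) {
    tree <- simulate_tree(40, seed = 80 + sd)
    d <- cophenetic_distances(tree)
    ord <- ape::reorder.phylo(tree, "cladewise")
    tip_order <- tree$tip.label[ord$edge[ord$edge[, 2] <= 40, 2]]
    clustered <- tip_order[1:8] # one clade
    spread <- tip_order[seq(1, 40, by = 5)] # one tip per region
    mat <- matrix(0L, 40, 2, dimnames = list(tree$tip.label, c("clust", "over")))
    mat[clustered, 1] <- 1L
    mat[spread, 2] <- 1L
    got <- ses_dispersion(toy_count_data(mat), d, n_null = 199, seed = sd)
    c(got$nti[got$sample_id == "clust"], got$nti[got$sample_id == "over"])
  }, numeric(2))
  expect_gte(mean(signs[1, ] > 0), 0.8)
  expect_gte(mean(signs[2, ] < 0), 0.8)
})
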