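# independent oracle: exhaustive enumeration of the co-occurrence null.
# For all C(N, n_a) x C(N, n_b) placements of two taxa, tabulate the overlap
# distribution and accumulate the tails.
enumerate_tails <- function(n_a, n_b, j_obs, N) {
  a_sets <- utils::combn(N, n_a, simplify = FALSE)
  b_sets <- utils::combn(N, n_b, simplify = FALSE)
  overlaps <- unlist(lapply(a_sets, function(a)
    vapply(b_sets, function(b) length(intersect(a, b)), 0L)))
  c(p_lt = mean(overlaps < j_obs), p_gt = mean(overlaps > j_obs))
}

test_that("occurrence filter keeps 1 < occupancy < T at the timepoint level", {
  T <- 10L
  pres <- matrix(0L, 5, T, dimnames = list(paste0("a", 1:5), NULL))
  pres[1, 1] <- 1L          # occupancy 1 -> dropped
  pres[2, 1:2] <- 1L        # occupancy 2 -> kept
  pres[3, 1:(T - 1)] <- 1L  # occupancy T-1 -> kept
  pres[4, ] <- 1L           # occupancy T -> dropped
  # row 5: occupancy 0 -> dropped
  cd <- toy_count_data(pres)
  kept <- filter_by_occurrence(cd)
  expect_setequal(kept$counts$asv_id, c("a2", "a3"))
  expect_identical(ncol(as.matrix(kept)), T)
  # occupancy is per timepoint: presence in one replicate of two timepoints counts as 2
  pres2 <- matrix(0L, 2, 6)
  pres2[1, c(1, 4)] <- 1L # replicate 1 of timepoints 1 and 2
  pres2[2, ] <- 1L
  cd2 <- toy_count_data(pres2, timepoints = rep(1:2, each = 3), replicates = rep(1:3, 2))
  occ2 <- occurrence_matrix(cd2)
  expect_identical(occ2$occupancy$n_timepoints_present, c(2, 2))
  expect_warning(filter_by_occurrence(cd2), "removed every ASV")
})

test_that("hypergeometric tails match exhaustive enumeration", {
  N <- 10L; n_a <- 5L; n_b <- 4L
  for (j in 0:4) {
    oracle <- enumerate_tails(n_a, n_b, j, N)
    got <- pair_tail_probabilities(n_a, n_b, j, N)
    expect_equal(got$p_lt, unname(oracle["p_lt"]), tolerance = 1e-12)
    expect_equal(got$p_gt, unname(oracle["p_gt"]), tolerance = 1e-12)
    expect_equal(got$p_lt + got$p_gt + got$p_eq, 1, tolerance = 1e-12)
  }
})

test_that("tail probabilities are symmetric and handle degenerate support", {
  got_ab <- pair_tail_probabilities(7, 4, 3, 12)
  got_ba <- pair_tail_probabilities(4, 7, 3, 12)
  expect_equal(got_ab, got_ba)
  # n_a = N forces J = n_b: both tails empty
  forced <- pair_tail_probabilities(10, 4, 4, 10)
  expect_equal(forced$p_lt, 0)
  expect_equal(forced$p_gt, 0)
  # j at the upper support bound
  expect_equal(pair_tail_probabilities(5, 4, 4, 10)$p_gt, 0)
  expect_error(pair_tail_probabilities(5, 4, 5, 10), "feasible range")
  expect_error(pair_tail_probabilities(11, 4, 2, 10), "occupancies")
})

test_that("tails agree with a Monte-Carlo shuffle oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      N <- sample(10:30, 1)
      n_a <- sample.int(N, 1); n_b <- sample.int(N, 1)
      a <- c(rep(TRUE, n_a), rep(FALSE, N - n_a))
      draws <- replicate(20000, sum(a[sample.int(N, n_b)]))
      feasible <- max(0, n_a + n_b - N):min(n_a, n_b)
      j <- feasible[sample.int(length(feasible), 1)]
      got <- pair_tail_probabilities(n_a, n_b, j, N)
      expect_lt(abs(got$p_lt - mean(draws < j)), 0.015)
      expect_lt(abs(got$p_gt - mean(draws > j)), 0.015)
    }
  })
})

test_that("metaweb classifies planted co-occurrence and co-exclusion", {
  N <- 20
  pres <- matrix(FALSE, 4, N, dimnames = list(c("co1", "co2", "ex1", "ex2"), NULL))
  pres[c("co1", "co2"), 1:5] <- TRUE   # identical sets of 5
  pres["ex1", 1:10] <- TRUE            # disjoint 10 vs 10
  pres["ex2", 11:20] <- TRUE
  occ <- toy_occurrence(pres)
  mw <- build_metaweb(occ, significance = 0.95)
  edges <- tidy(mw)
  expect_identical(edges$layer[edges$asv_a == "co1" & edges$asv_b == "co2"],
                   "cooccurrence")
  expect_identical(edges$layer[edges$asv_a == "ex1" & edges$asv_b == "ex2"],
                   "coexclusion")
  # layers disjoint and nodes restricted to ASVs with >= 1 significant edge
  expect_identical(anyDuplicated(edges[, c("asv_a", "asv_b")]), 0L)
  expect_true(all(c(edges$asv_a, edges$asv_b) %in% mw$nodes$asv_id))
})

test_that("pair classification is invariant under ASV relabeling", {
  withr::with_seed(7, {
    pres <- matrix(runif(12 * 30) < 0.4, 12, 30,
                   dimnames = list(sprintf("a%02d", 1:12), NULL))
  })
  occ <- toy_occurrence(pres * 1L)
  mw1 <- build_metaweb(occ)
  relabeled <- pres[rev(seq_len(nrow(pres))), ]
  rownames(relabeled) <- rev(rownames(pres))
  mw2 <- build_metaweb(toy_occurrence(relabeled * 1L))
  key <- function(mw) {
    e <- mw$edges
    sorted <- t(apply(cbind(e$asv_a, e$asv_b), 1, sort))
    df <- data.frame(a = sorted[, 1], b = sorted[, 2], layer = e$layer)
    df[order(df$a, df$b), ]
  }
  expect_equal(key(mw1), key(mw2), ignore_attr = TRUE)
})

test_that("single-point support pairs are classified none", {
  pres <- matrix(FALSE, 2, 8, dimnames = list(c("all", "x"), NULL))
  pres["all", ] <- TRUE # n_a = N: support is a single point
  pres["x", 1:3] <- TRUE
  pairs <- pair_associations(toy_occurrence(pres))
  expect_identical(pairs$classification, "none")
  mw <- build_metaweb(toy_occurrence(pres))
  expect_identical(nrow(mw$nodes), 0L)
})

test_that("fewer than 2 ASVs give an empty metaweb", {
  pres <- matrix(1L, 1, 5, dimnames = list("only", NULL))
  mw <- build_metaweb(toy_occurrence(pres))
  expect_identical(nrow(mw$edges), 0L)
  expect_identical(nrow(mw$nodes), 0L)
})
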