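test_that("walktrap resolves disjoint cliques and trivial graphs", {
  ids1 <- paste0("a", 1:5); ids2 <- paste0("b", 1:5)
  mw <- toy_metaweb(cooc = rbind(clique_edges(ids1), clique_edges(ids2)))
  part <- detect_modules(mw, seed = 1)
  expect_identical(length(unique(part$module)), 2L)
  expect_identical(length(unique(part$module[part$asv_id %in% ids1])), 1L)
  expect_identical(length(unique(part$module[part$asv_id %in% ids2])), 1L)
  # complete graph: one module, Q = 0
  k6 <- toy_metaweb(cooc = clique_edges(paste0("k", 1:6)))
  p6 <- detect_modules(k6, seed = 1)
  expect_identical(length(unique(p6$module)), 1L)
  expect_equal(attr(p6, "Q"), 0)
  # isolated nodes become singleton modules
  iso <- toy_metaweb(cooc = rbind(c("a", "b")), nodes = c("a", "b", "z"))
  piso <- detect_modules(iso, seed = 1)
  expect_identical(length(unique(piso$module)), 2L)
})

test_that("walktrap recovers planted two-block partitions", {
  aris <- vapply(1:3, function(sd) {
    g <- withr::with_seed(sd, igraph::sample_sbm(
      60, pref.matrix = matrix(c(0.3, 0.01, 0.01, 0.3), 2),
      block.sizes = c(30, 30)))
    part <- partition_graph(g, seed = sd)
    adjusted_rand_index(part$module, rep(1:2, each = 30)[as.integer(sub("v", "", part$asv_id))])
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("modularity matches hand evaluation of the Newman formula", {
  tri2 <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"),
          c("d", "e"), c("e", "f"), c("d", "f")), directed = FALSE)
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(network_modularity(tri2, memb[igraph::V(tri2)$name]), 0.5)
  # any graph under a single-module partition has Q = 0
  g <- withr::with_seed(1, igraph::sample_gnp(12, 0.4))
  expect_equal(network_modularity(g, rep(1L, 12)), 0)
  # edgeless graph: undefined, not 0
  expect_true(is.na(network_modularity(igraph::make_empty_graph(3, directed = FALSE),
                                       1:3)))
  expect_error(network_modularity(tri2, tibble::tibble(asv_id = "a", module = 1)),
               "missing")
})

test_that("modularity agrees with an independent summation oracle", {
  withr::with_seed(5, {
    for (i in 1:5) {
      g <- igraph::sample_gnp(15, 0.3)
      while (igraph::ecount(g) == 0) g <- igraph::sample_gnp(15, 0.3)
      memb <- sample(1:3, 15, replace = TRUE)
      expect_equal(network_modularity(g, memb), oracle_modularity(g, memb))
    }
  })
})

test_that("clustering coefficient matches brute-force triple counting", {
  expect_equal(clustering_coefficient(igraph::make_full_graph(5)), 1)
  expect_equal(clustering_coefficient(igraph::make_star(6, mode = "undirected")), 0)
  # path A-B-C closed by A-C, plus pendant C-D
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                                         c("C", "D")), directed = FALSE)
  expect_equal(clustering_coefficient(g), oracle_transitivity(g))
  expect_equal(clustering_coefficient(g), 0.6)
  # no connected triples: undefined
  single <- igraph::graph_from_edgelist(rbind(c("x", "y")), directed = FALSE)
  expect_true(is.na(clustering_coefficient(single)))
  withr::with_seed(9, {
    g2 <- igraph::sample_gnp(12, 0.35)
    expect_equal(clustering_coefficient(g2), oracle_transitivity(g2))
  })
})

test_that("co-exclusion proportion counts induced edges", {
  expect_equal(coexclusion_proportion(0, 7), 0)
  expect_equal(coexclusion_proportion(5, 0), 1)
  expect_equal(coexclusion_proportion(3, 9), 0.25)
  expect_true(is.na(coexclusion_proportion(0, 0)))
})

test_that("module completeness is the present fraction of each module", {
  part <- tibble::tibble(asv_id = paste0("a", 1:8),
                         module = rep(1:2, c(5, 3)))
  pres <- matrix(0L, 8, 3, dimnames = list(part$asv_id, NULL))
  pres[1:5, 1] <- 1L          # sample 1: all of module 1
  pres[c(1, 2, 3), 2] <- 1L   # sample 2: 3 of 5
  pres[6:8, 2] <- 1L          # ... and all of module 2
  occ <- toy_occurrence(pres)
  comp <- module_completeness(part, occ)
  get <- function(s, m) comp$completeness[comp$sample_id == s & comp$module == m]
  expect_equal(get("s01", 1), 1.0)
  expect_equal(get("s02", 1), 0.6)
  expect_equal(get("s01", 2), 0.0)
  expect_equal(get("s02", 2), 1.0)
  expect_equal(get("s03", 1), 0.0)
  # monotone: adding a present node never decreases completeness
  pres2 <- pres; pres2[4, 2] <- 1L
  comp2 <- module_completeness(part, toy_occurrence(pres2))
  expect_true(all(comp2$completeness >= comp$completeness))
})

test_that("timepoint networks induce exactly the present-node subgraphs", {
  ids <- paste0("n", 1:6)
  cooc <- rbind(c("n1", "n2"), c("n2", "n3"), c("n1", "n3"), c("n4", "n5"))
  coex <- rbind(c("n3", "n4"), c("n5", "n6"))
  mw <- toy_metaweb(cooc = cooc, coex = coex, nodes = ids)
  pres <- matrix(0L, 6, 3, dimnames = list(ids, NULL))
  pres[, 1] <- 1L          # all nodes
  pres[1:3, 2] <- 1L       # triangle only
  pres[1, 3] <- 1L         # single node: metrics undefined
  occ <- toy_occurrence(pres)
  tp <- extract_timepoint_networks(mw, occ, seed = 1)
  expect_identical(tp$n_cooccurrence[tp$sample_id == "s01"], 4L)
  expect_identical(tp$n_coexclusion[tp$sample_id == "s01"], 2L)
  expect_equal(tp$coexclusion_proportion[tp$sample_id == "s01"], 2 / 6)
  expect_identical(tp$n_cooccurrence[tp$sample_id == "s02"], 3L)
  expect_identical(tp$n_coexclusion[tp$sample_id == "s02"], 0L)
  expect_equal(tp$clustering[tp$sample_id == "s02"], 1)
  expect_true(all(is.na(unlist(tp[tp$sample_id == "s03",
                                  c("modularity", "clustering",
                                    "coexclusion_proportion")]))))
  # brute-force check: induced edges = metaweb edges with both endpoints present
  graphs <- attr(tp, "graphs")
  for (s in colnames(pres)) {
    present <- rownames(pres)[pres[, s] > 0]
    manual <- sum(cooc[, 1] %in% present & cooc[, 2] %in% present)
    expect_equal(igraph::ecount(graphs[[s]]$cooccurrence), manual)
  }
})

test_that("seasonal completeness tracks temperature with opposite signs", {
  rhos <- vapply(c(31, 32), function(sd) {
    sim <- simulate_scenario(scenario_spec("seasonal"), seed = sd)
    f <- filter_by_occurrence(sim$counts)
    occ <- occurrence_matrix(f)
    mw <- build_metaweb(occ)
    part <- detect_modules(mw, seed = 1)
    comp <- module_completeness(part, occ)
    sorted <- vapply(1:2, function(m) {
      cm <- comp[comp$module == m, ]
      cor(cm$completeness, sim$temperature[cm$timepoint], method = "spearman")
    }, 0)
    sort(sorted)
  }, numeric(2))
  expect_true(all(rhos[1, ] <= -0.6))
  expect_true(all(rhos[2, ] >= 0.6))
})
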