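#' Scenario specification for the synthetic generator
#'
#' Bundles the parameters that define one of the two emulated study designs:
#' `"seasonal"` — an established plant whose two communities alternate with a
#' sinusoidal temperature cycle (22 monthly timepoints x 3 replicates,
#' 18.0-27.6 degC) — and `"succession"` — a starting-up plant where a large
#' seeded module decays geometrically in favor of two staggered rising
#' modules (23 timepoints x 3 replicates, 11.33-23.50 degC).
#'
#' A configurable number of ASVs is set aside as "rare" (expected abundance
#' in a single timepoint only) and "ubiquitous" (constant expected abundance)
#' to exercise the occurrence filter; the remaining ASVs form the planted
#' modules.
#'
#' @param scenario `"seasonal"` or `"succession"`.
#' @param n_timepoints Number of timepoints (default 22 seasonal / 23
#'   succession).
#' @param n_replicates Replicates per timepoint (default 3).
#' @param module_sizes Planted module sizes (default 60+60 seasonal;
#'   30+30+90 succession, the last being the decaying seeded module).
#' @param n_rare,n_ubiquitous Counts of filter-exercising ASVs (default 15
#'   each).
#' @param temp_range Temperature range in degC over the sinusoid (defaults
#'   18.0-27.6 seasonal, 11.33-23.50 succession).
#' @param sigma_niche Gaussian niche width in degC (default 1.5; seasonal
#'   scenario only).
#' @param niche_spread Within-module standard deviation of niche optima in
#'   degC; scalar or per module (default 1 seasonal; 2, 2, 1 succession —
#'   the rising specialist modules are thermally diverse, the seeded module
#'   homogeneous).
#' @param brownian_rate Brownian-motion rate for tip optima on the
#'   depth-1 tree (default 1).
#' @param depth Sequencing depth per sample (multinomial size; default 5000).
#' @param baseline_sdlog Lognormal sd(log) of within-module ASV baselines;
#'   scalar or one value per module (default 1 seasonal; 1.2, 1.2, 0.6
#'   succession — the decaying module is the most even).
#' @param decay_rate Exponential decay rate per timepoint of the
#'   disappearing module's weight (default 0.35; 0 freezes all module
#'   trends, succession only).
#' @param growth_steepness,growth_midpoints Logistic growth of the rising
#'   modules (steepness scales with `decay_rate` so that `decay_rate = 0`
#'   is stationary).
#' @param initial_dominance Weight multiple of the decaying module at t = 1
#'   (default 6).
#' @param generalist_sigma Niche width of the decaying seeded module
#'   (default 6 degC: a thermal generalist), succession only.
#' @return A `scenario_spec` list; `n_asvs` is derived as
#'   `sum(module_sizes) + n_rare + n_ubiquitous`.
#' @export
scenario_spec <- function(scenario = c("seasonal", "succession"),
                          n_timepoints = NULL, n_replicates = 3L,
                          module_sizes = NULL, n_rare = 15L, n_ubiquitous = 15L,
                          temp_range = NULL, sigma_niche = 1.5,
                          niche_spread = NULL, brownian_rate = 1.0,
                          depth = 5000L, baseline_sdlog = NULL,
                          decay_rate = 0.35, growth_steepness = 0.8,
                          growth_midpoints = c(7, 15), initial_dominance = 6,
                          generalist_sigma = 6) {
  scenario <- match.arg(scenario)
  if (is.null(n_timepoints)) n_timepoints <- if (scenario == "seasonal") 22L else 23L
  if (is.null(module_sizes)) {
    module_sizes <- if (scenario == "seasonal") c(60L, 60L) else c(30L, 30L, 90L)
  }
  if (is.null(temp_range)) {
    temp_range <- if (scenario == "seasonal") c(18.0, 27.6) else c(11.33, 23.50)
  }
  if (is.null(baseline_sdlog)) {
    baseline_sdlog <- if (scenario == "seasonal") rep(1.0, length(module_sizes))
    else c(1.2, 1.2, 0.6)[seq_along(module_sizes)]
  }
  baseline_sdlog <- rep_len(baseline_sdlog, length(module_sizes))
  if (is.null(niche_spread)) {
    niche_spread <- if (scenario == "seasonal") 1.0 else c(2.0, 2.0, 1.0)
  }
  niche_spread <- rep_len(niche_spread, length(module_sizes))
  if (scenario == "seasonal" && length(module_sizes) != 2L) {
    stop("seasonal scenario plants 2 modules", call. = FALSE)
  }
  if (scenario == "succession" && length(module_sizes) != 3L) {
    stop("succession scenario plants 3 modules", call. = FALSE)
  }
  stopifnot(n_timepoints >= 2, n_replicates >= 1, all(module_sizes >= 2),
            depth >= 1, temp_range[2] > temp_range[1], sigma_niche > 0,
            decay_rate >= 0, brownian_rate >= 0)
  structure(list(scenario = scenario, n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 module_sizes = as.integer(module_sizes),
                 n_rare = as.integer(n_rare), n_ubiquitous = as.integer(n_ubiquitous),
                 n_asvs = sum(module_sizes) + n_rare + n_ubiquitous,
                 temp_range = temp_range, sigma_niche = sigma_niche,
                 niche_spread = niche_spread, brownian_rate = brownian_rate,
                 depth = as.integer(depth), baseline_sdlog = baseline_sdlog,
                 decay_rate = decay_rate, growth_steepness = growth_steepness,
                 growth_midpoints = growth_midpoints,
                 initial_dominance = initial_dominance,
                 generalist_sigma = generalist_sigma),
            class = "scenario_spec")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric pure-birth tree with exponential internode times, rescaled so
#' every root-to-tip depth is 1.
#'
#' @param n_tips Number of tips (>= 2); labels `asv001`, `asv002`, ...
#' @param seed Optional integer seed; same seed, same Newick string.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be at least 2", call. = FALSE)
  run <- function() ape::rphylo(n_tips, birth = 1, death = 0)
  tree <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("asv%03d", seq_len(n_tips))
  tree
}

#' Evolve per-tip environmental optima by Brownian motion
#'
#' Simulates a continuous trait along the tree from a root value; the
#' variance of a tip is `rate` times its root-to-tip depth, and tips sharing
#' long root paths covary, so close relatives get similar optima.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param brownian_rate Brownian rate (variance per unit branch length);
#'   0 returns the root value everywhere, negative is an error.
#' @param seed Optional integer seed.
#' @param root_value Trait value at the root (default 0).
#' @return A named numeric vector of tip optima.
#' @export
evolve_optima <- function(tree, brownian_rate, seed = NULL, root_value = 0) {
  if (brownian_rate < 0) stop("brownian_rate must be non-negative", call. = FALSE)
  if (brownian_rate == 0) {
    return(stats::setNames(rep(root_value, length(tree$tip.label)), tree$tip.label))
  }
  run <- function() ape::rTraitCont(tree, model = "BM", sigma = sqrt(brownian_rate),
                                    root.value = root_value)
  x <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  stats::setNames(as.numeric(x), tree$tip.label)
}

#' Temperature series of a scenario
#'
#' Sinusoid spanning the configured range with two full cycles (two years of
#' monthly sampling) over the timepoints.
#'
#' @param spec A [scenario_spec()].
#' @return Numeric vector, one temperature per timepoint.
#' @export
simulate_temperature <- function(spec) {
  t <- seq_len(spec$n_timepoints)
  mid <- mean(spec$temp_range)
  amp <- diff(spec$temp_range) / 2
  mid - amp * cos(2 * pi * 2 * (t - 1) / spec$n_timepoints)
}

# Timepoint x module mixing-weight matrix.
module_weight_series <- function(spec) {
  t <- seq_len(spec$n_timepoints)
  k <- length(spec$module_sizes)
  if (spec$scenario == "seasonal") {
    return(matrix(1, spec$n_timepoints, k))
  }
  s <- spec$growth_steepness * (spec$decay_rate / 0.35)
  w <- matrix(1, spec$n_timepoints, k)
  w[, k] <- spec$initial_dominance * exp(-spec$decay_rate * (t - 1))
  for (m in seq_len(k - 1)) {
    w[, m] <- 1 / (1 + exp(-s * (t - spec$growth_midpoints[m])))
  }
  w
}

#' Simulate a full study scenario
#'
#' Produces the output of an amplicon workflow with the statistical structure
#' the downstream analysis assumes: a [count_data] bundle (multinomial counts
#' at fixed depth per sample), sample metadata (temperature, influent and
#' effluent BOD/TN/TP), the phylogeny, and ground-truth module labels.
#'
#' In the seasonal scenario each planted ASV's expected relative abundance is
#' its lognormal baseline times a Gaussian niche response
#' exp(-(T - optimum)^2 / (2 sigma^2)); module 1 optima sit near the warm end
#' of the range and module 2 near the cold end, with Brownian within-module
#' spread so optima carry phylogenetic signal. In the succession scenario
#' abundances follow module trend weights instead: the seeded module decays
#' exponentially while the other two rise logistically at staggered
#' midpoints. Rare ASVs receive weight in one random timepoint only and
#' ubiquitous ASVs a constant weight.
#'
#' @param spec A [scenario_spec()].
#' @param tree Optional tree (simulated if missing).
#' @param optima Optional named Brownian trait vector (simulated if missing).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `scenario_sim` list: `counts` ([count_data]), `metadata`
#'   (tibble), `tree`, `truth` (tibble: `asv_id`, `module`, `role`,
#'   `optimum`), `temperature` (per timepoint), `spec`.
#' @export
simulate_scenario <- function(spec, tree = NULL, optima = NULL, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(seed, {
    n <- spec$n_asvs
    if (is.null(tree)) tree <- simulate_tree(n)
    if (length(tree$tip.label) != n) stop("tree size does not match spec", call. = FALSE)
    if (is.null(optima)) optima <- evolve_optima(tree, spec$brownian_rate)
    optima <- optima[tree$tip.label]

    ids <- tree$tip.label
    # cladewise plot order: consecutive tips share recent ancestry, so
    # contiguous blocks of this order are (near-)clades
    ord <- ape::reorder.phylo(tree, "cladewise")
    tip_order <- ids[ord$edge[ord$edge[, 2] <= n, 2]]
    special <- sample(ids, spec$n_rare + spec$n_ubiquitous)
    rare_ids <- special[seq_len(spec$n_rare)]
    ubiq_ids <- setdiff(special, rare_ids)
    core_ids <- setdiff(tip_order, special) # clade-contiguous order
    module_of <- stats::setNames(rep(NA_integer_, n), ids)
    if (spec$scenario == "succession") {
      # the decaying seeded module emulates an exogenous inoculum: its taxa
      # are scattered across the tree; the rising adapted modules are clades
      k <- length(spec$module_sizes)
      seeded <- sample(core_ids, spec$module_sizes[k])
      module_of[seeded] <- k
      rest <- setdiff(core_ids, seeded) # keeps cladewise order
      module_of[rest] <- rep(seq_len(k - 1), spec$module_sizes[-k])
    } else {
      module_of[core_ids] <- rep(seq_along(spec$module_sizes), spec$module_sizes)
    }

    temperature <- simulate_temperature(spec)
    w_mod <- module_weight_series(spec)

    # niche optima in degC: module centres at the 20%/80% range quantiles
    # (seasonal), Brownian deviations standardized within module
    centers <- spec$temp_range[1] +
      c(0.8, 0.2, 0.5)[seq_along(spec$module_sizes)] * diff(spec$temp_range)
    pool_sd <- stats::sd(optima[core_ids])
    if (!is.finite(pool_sd) || pool_sd == 0) pool_sd <- 1
    opt_c <- stats::setNames(rep(NA_real_, n), ids)
    for (m in seq_along(spec$module_sizes)) {
      mem <- core_ids[module_of[core_ids] == m]
      dev <- (optima[mem] - mean(optima[mem])) / pool_sd
      opt_c[mem] <- centers[m] + spec$niche_spread[m] * dev
    }

    # per-ASV lognormal baselines, normalized within module
    baseline <- stats::setNames(rep(0, n), ids)
    for (m in seq_along(spec$module_sizes)) {
      mem <- core_ids[module_of[core_ids] == m]
      b <- stats::rlnorm(length(mem), 0, spec$baseline_sdlog[m])
      baseline[mem] <- b / sum(b)
    }
    rare_tp <- stats::setNames(sample.int(spec$n_timepoints, spec$n_rare, replace = TRUE),
                               rare_ids)

    expected <- matrix(0, n, spec$n_timepoints, dimnames = list(ids, NULL))
    for (t in seq_len(spec$n_timepoints)) {
      u <- numeric(n); names(u) <- ids
      for (m in seq_along(spec$module_sizes)) {
        mem <- core_ids[module_of[core_ids] == m]
        # decaying seeded module is a thermal generalist (wide niche);
        # planted/rising modules have narrow, opposed niches
        sigma_m <- if (spec$scenario == "succession" && m == length(spec$module_sizes)) {
          spec$generalist_sigma
        } else spec$sigma_niche
        niche <- exp(-(temperature[t] - opt_c[mem])^2 / (2 * sigma_m^2))
        u[mem] <- baseline[mem] * w_mod[t, m] * niche
      }
      hit <- rare_ids[rare_tp[rare_ids] == t]
      share_special <- 0.005 * length(ubiq_ids) + 0.01 * length(hit)
      u[core_ids] <- u[core_ids] / sum(u[core_ids]) * (1 - share_special)
      u[ubiq_ids] <- 0.005
      u[hit] <- 0.01
      expected[, t] <- u
    }

    sample_ids <- sprintf("t%02dr%d", rep(seq_len(spec$n_timepoints), each = spec$n_replicates),
                          rep(seq_len(spec$n_replicates), spec$n_timepoints))
    counts <- matrix(0L, n, length(sample_ids), dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      t <- (j - 1) %/% spec$n_replicates + 1L
      counts[, j] <- stats::rmultinom(1, spec$depth, expected[, t])[, 1]
    }
    samples <- tibble::tibble(sample_id = sample_ids,
                              timepoint = rep(seq_len(spec$n_timepoints), each = spec$n_replicates),
                              replicate = rep(seq_len(spec$n_replicates), spec$n_timepoints))
    cd <- count_data(tibble::as_tibble(cbind(tibble::tibble(asv_id = ids),
                                             tibble::as_tibble(counts))), samples)
    metadata <- simulate_metadata(spec, samples, temperature)
    truth <- tibble::tibble(
      asv_id = ids,
      module = unname(module_of[ids]),
      role = dplyr::case_when(ids %in% rare_ids ~ "rare",
                              ids %in% ubiq_ids ~ "ubiquitous",
                              TRUE ~ "core"),
      optimum = unname(opt_c[ids]),
      brownian_trait = unname(optima[ids]))
    structure(list(counts = cd, metadata = metadata, tree = tree, truth = truth,
                   temperature = temperature, spec = spec, seed = seed),
              class = "scenario_sim")
  })
}

# Influent concentrations rise with temperature (warm-month loading);
# effluent follows plant efficiency: steady for the established plant,
# ramping up during start-up.
simulate_metadata <- function(spec, samples, temperature) {
  t <- samples$timepoint
  Tt <- temperature[t]
  mid <- mean(spec$temp_range); amp <- diff(spec$temp_range) / 2
  season <- (Tt - mid) / amp # in [-1, 1]
  base <- c(bod = 400, tn = 60, tp = 9)
  infl <- lapply(base, function(b) b * (1 + 0.25 * season))
  eff_frac <- function(start, end) {
    if (spec$scenario == "seasonal") rep(end, length(t))
    else start + (end - start) * (t - 1) / (spec$n_timepoints - 1)
  }
  eff <- list(bod = eff_frac(0.50, 0.95), tn = eff_frac(0.20, 0.80),
              tp = eff_frac(0.20, 0.85))
  noise <- function(n) stats::rlnorm(n, 0, 0.05)
  n <- length(t)
  tibble::tibble(sample_id = samples$sample_id, timepoint = t,
                 replicate = samples$replicate, temperature = Tt,
                 bod_in = infl$bod, bod_out = infl$bod * (1 - eff$bod) * noise(n),
                 tn_in = infl$tn, tn_out = infl$tn * (1 - eff$tn) * noise(n),
                 tp_in = infl$tp, tp_out = infl$tp * (1 - eff$tp) * noise(n))
}

#' @export
print.scenario_sim <- function(x, ...) {
  cat(sprintf("<scenario_sim> %s: %d ASVs, %d timepoints x %d replicates, depth %d\n",
              x$spec$scenario, x$spec$n_asvs, x$spec$n_timepoints,
              x$spec$n_replicates, x$spec$depth))
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' Writes `counts.tsv`, `sample_map.csv`, `metadata.csv`, `tree.nwk` and
#' `truth.json` into a directory.
#'
#' @param sim A [simulate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "sample_map.csv"))
  readr::write_csv(sim$metadata, file.path(dir, "metadata.csv"), progress = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(list(scenario = sim$spec$scenario, seed = sim$seed,
                            temperature = sim$temperature, truth = sim$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 the expectation under random labelings.
#'
#' @param a,b Equal-length label vectors (any type; NAs dropped pairwise).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}
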