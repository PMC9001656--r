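#' Pollutant removal rate
#'
#' 100 x (influent - effluent) / influent, in percent. Negative values
#' (effluent above influent) are retained; non-positive influent is
#' undefined (NA).
#'
#' @param influent,effluent Concentrations (mg/L), vectorized.
#' @return Removal rate in percent.
#' @export
removal_rate <- function(influent, effluent) {
  out <- 100 * (influent - effluent) / influent
  out[influent <= 0] <- NA_real_
  out
}

#' Removal rates for BOD, TN and TP from sample metadata
#'
#' @param metadata Tibble with `sample_id` and `bod_in, bod_out, tn_in,
#'   tn_out, tp_in, tp_out` columns.
#' @return A long tibble: `sample_id`, `pollutant` in {BOD, TN, TP},
#'   `removal` (%).
#' @export
removal_rates <- function(metadata) {
  pieces <- list(BOD = c("bod_in", "bod_out"), TN = c("tn_in", "tn_out"),
                 TP = c("tp_in", "tp_out"))
  purrr::imap_dfr(pieces, function(cols, nm) {
    if (!all(cols %in% names(metadata))) {
      stop("metadata lacks columns ", paste(cols, collapse = "/"), call. = FALSE)
    }
    tibble::tibble(sample_id = metadata$sample_id, pollutant = nm,
                   removal = removal_rate(metadata[[cols[1]]], metadata[[cols[2]]]))
  })
}

#' Spearman correlation with a permutation/t-approximation p-value
#'
#' Mid-rank ties; the p-value uses the t approximation for n > 10, exact
#' enumeration of all permutations for n <= 7, and seeded Monte-Carlo
#' permutation (10000 draws) for 8 <= n <= 10.
#'
#' @param x,y Numeric vectors of equal length.
#' @param seed Seed for the Monte-Carlo branch.
#' @return A list with `rho` and `p` (`rho` NA when either vector is
#'   constant).
#' @keywords internal
spearman_test <- function(x, y, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  if (n > 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else if (n <= 7L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    rhos <- withr::with_seed(seed, replicate(10000, stats::cor(rx, sample(ry))))
    p <- (sum(abs(rhos) >= abs(rho) - 1e-12) + 1) / (10000 + 1)
  }
  list(rho = rho, p = min(1, p))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate metaweb node abundances with pollutant removal
#'
#' Spearman rank correlation between each node's per-sample relative
#' abundance and each pollutant's removal rate, with Benjamini-Hochberg
#' adjustment pooled across all (node x pollutant) tests (per-pollutant
#' adjustment behind `pooled = FALSE`).
#'
#' @param cd A [count_data] object.
#' @param nodes Character vector of node ids to test (e.g.
#'   `metaweb$nodes$asv_id`); defaults to all ASVs.
#' @param rates A [removal_rates()] tibble.
#' @param fdr BH false-discovery-rate level (default 0.05).
#' @param pooled Adjust across all pollutants jointly (default TRUE).
#' @param seed Seed for small-sample permutation p-values.
#' @return A tibble: `asv_id`, `pollutant`, `rho`, `p_value`, `q_value`,
#'   `significant`, `sign`.
#' @export
correlate_nodes <- function(cd, nodes = NULL, rates, fdr = 0.05, pooled = TRUE,
                            seed = 1L) {
  rel <- relative_abundance(cd)
  if (is.null(nodes)) nodes <- rownames(rel)
  nodes <- intersect(nodes, rownames(rel))
  res <- purrr::map_dfr(unique(rates$pollutant), function(pol) {
    rr <- rates[rates$pollutant == pol, ]
    r <- rr$removal[match(colnames(rel), rr$sample_id)]
    if (sum(!is.na(r)) < 4L) {
      stop("need >= 4 samples with defined ", pol, " removal", call. = FALSE)
    }
    purrr::map_dfr(nodes, function(id) {
      st <- spearman_test(rel[id, ], r, seed = seed)
      tibble::tibble(asv_id = id, pollutant = pol, rho = st$rho, p_value = st$p)
    })
  })
  adjust <- function(p) stats::p.adjust(p, method = "BH")
  if (pooled) {
    res$q_value <- adjust(res$p_value)
  } else {
    res <- dplyr::group_by(res, .data$pollutant) |>
      dplyr::mutate(q_value = adjust(.data$p_value)) |>
      dplyr::ungroup()
  }
  res$significant <- !is.na(res$q_value) & res$q_value <= fdr
  res$sign <- dplyr::case_when(is.na(res$rho) ~ NA_character_,
                               res$rho > 0 ~ "positive",
                               res$rho < 0 ~ "negative",
                               TRUE ~ "zero")
  res
}

#' Summed abundance of removal-correlated nodes
#'
#' Per sample and pollutant, the total relative abundance of nodes whose
#' abundance correlates significantly (positively / negatively) with the
#' pollutant's removal rate.
#'
#' @param correlations A [correlate_nodes()] tibble.
#' @param cd The [count_data] the correlations were computed on.
#' @return A tibble: `sample_id`, `timepoint`, `replicate`, `pollutant`,
#'   `direction`, `summed_abundance`.
#' @export
correlated_abundance_series <- function(correlations, cd) {
  rel <- relative_abundance(cd)
  combos <- tidyr::expand_grid(pollutant = unique(correlations$pollutant),
                               direction = c("positive", "negative"))
  out <- purrr::pmap_dfr(combos, function(pollutant, direction) {
    sig <- correlations$asv_id[correlations$pollutant == pollutant &
                                 correlations$significant &
                                 !is.na(correlations$sign) &
                                 correlations$sign == direction]
    tot <- if (length(sig)) colSums(rel[sig, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(rel)), colnames(rel))
    tibble::tibble(sample_id = colnames(rel), pollutant = pollutant,
                   direction = direction, summed_abundance = unname(tot))
  })
  dplyr::left_join(out, cd$samples, by = "sample_id") |>
    dplyr::select("sample_id", "timepoint", "replicate", dplyr::everything()) |>
    dplyr::arrange(.data$pollutant, .data$direction, .data$timepoint, .data$replicate)
}
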