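#' ASV count data bundle
#'
#' Couples a wide ASV-by-sample count table with its sample map (which sample
#' belongs to which timepoint and replicate). All downstream stages take this
#' bundle, so the pairing is validated once, here.
#'
#' @param counts A data frame whose first column is `asv_id` (unique character
#'   ids) and whose remaining columns are per-sample non-negative integer
#'   counts, one column per sample id.
#' @param samples A data frame with columns `sample_id`, `timepoint`,
#'   `replicate` (1-based integer indices). Every count column must appear
#'   exactly once, and each (timepoint, replicate) pair must be unique.
#' @return An object of class `count_data`: a list with elements `counts`
#'   (tibble) and `samples` (tibble).
#' @examples
#' counts <- tibble::tibble(asv_id = c("a1", "a2"), s1 = c(5L, 0L), s2 = c(1L, 3L))
#' samples <- tibble::tibble(sample_id = c("s1", "s2"), timepoint = c(1L, 2L),
#'                           replicate = c(1L, 1L))
#' cd <- count_data(counts, samples)
#' cd
#' @export
count_data <- function(counts, samples) {
  counts <- tibble::as_tibble(counts)
  samples <- tibble::as_tibble(samples)
  if (ncol(counts) < 1L || names(counts)[1] != "asv_id") {
    stop("`counts` must have `asv_id` as its first column", call. = FALSE)
  }
  if (anyDuplicated(counts$asv_id)) {
    stop("duplicate ASV ids in count table", call. = FALSE)
  }
  sample_ids <- names(counts)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in count table", call. = FALSE)
  }
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (length(mat) > 0) {
    if (!is.numeric(mat)) stop("counts must be numeric", call. = FALSE)
    if (anyNA(mat)) stop("counts contain missing values", call. = FALSE)
    if (any(mat < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(mat != round(mat))) stop("counts must be integers", call. = FALSE)
  }
  counts[, -1] <- lapply(counts[, -1, drop = FALSE], function(x) as.integer(round(x)))
  req <- c("sample_id", "timepoint", "replicate")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns sample_id, timepoint, replicate", call. = FALSE)
  }
  missing_map <- setdiff(sample_ids, samples$sample_id)
  if (length(missing_map)) {
    stop("samples missing from sample map: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  samples$timepoint <- as.integer(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples[, c("timepoint", "replicate")])) {
    stop("duplicate (timepoint, replicate) pairs in sample map", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("<count_data> %d ASVs x %d samples (%d timepoints)\n",
              nrow(x$counts), ncol(x$counts) - 1L,
              length(unique(x$samples$timepoint))))
  invisible(x)
}

#' @export
as.matrix.count_data <- function(x, ...) {
  m <- as.matrix(x$counts[, -1, drop = FALSE])
  rownames(m) <- x$counts$asv_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname count_data
#' @param x A `count_data` object.
#' @param ... Unused.
#' @return `tidy.count_data()`: a long tibble with columns `asv_id`,
#'   `sample_id`, `timepoint`, `replicate`, `count`.
#' @method tidy count_data
#' @export
tidy.count_data <- function(x, ...) {
  long <- tidyr::pivot_longer(x$counts, -"asv_id",
                              names_to = "sample_id", values_to = "count")
  dplyr::left_join(long, x$samples, by = "sample_id") |>
    dplyr::select("asv_id", "sample_id", "timepoint", "replicate", "count")
}

asv_ids <- function(cd) cd$counts$asv_id

sample_ids <- function(cd) names(cd$counts)[-1]

#' Relative abundances per sample
#'
#' Divides each sample column by its total count. All-zero samples yield
#' zero columns (flagged with a warning).
#'
#' @param cd A [count_data] object.
#' @return A numeric matrix (ASVs x samples) of per-sample proportions.
#' @export
relative_abundance <- function(cd) {
  m <- as.matrix(cd)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  sweep(m, 2, tot, "/")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
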