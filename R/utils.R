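#' Derive a stage-specific seed from a master seed
#'
#' Pipeline stages draw their randomness from seeds derived deterministically
#' from one master seed keyed by a stage name, so reruns of any stage in
#' isolation reproduce the run-all result.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Internal: counts tibble -> numeric matrix with gene_id rownames
#' @noRd
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$gene_id
  m
}

#' Internal: validate a sample sheet against the columns of a count matrix
#' @noRd
check_sample_sheet <- function(sheet, sample_ids = NULL) {
  need <- c("sample_id", "genotype", "assay", "animal_id")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) abort(paste("sample sheet missing columns:", paste(miss, collapse = ", ")))
  if (!all(sheet$genotype %in% c("control", "mutant")))
    abort("genotype must be 'control' or 'mutant'")
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample_id in sample sheet")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, sheet$sample_id)
    if (length(miss)) abort(paste("samples absent from sheet:", paste(miss, collapse = ", ")))
  }
  invisible(sheet)
}

#' Log-transform a count matrix
#'
#' Optionally rescales each sample to counts-per-million before the
#' `log2(x + 1)` transform, so fold changes are not confounded by sequencing
#' depth.
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @param cpm Scale each column to counts-per-million first (default `TRUE`).
#' @return A tibble of the same shape with transformed values.
#' @export
log_counts <- function(counts, cpm = TRUE) {
  m <- counts_matrix(counts)
  if (cpm) {
    libs <- colSums(m)
    if (any(libs == 0)) abort("sample with zero total counts")
    m <- sweep(m, 2, libs / 1e6, "/")
  }
  m <- log2(m + 1)
  rownames(m) <- NULL
  dplyr::bind_cols(tibble(gene_id = counts$gene_id), as_tibble(m))
}
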