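#' Internal: split paired RNA/TRAP counts into four transformed group matrices
#'
#' Genes are intersected across the two assays (dropped genes reported);
#' columns are grouped by (assay, genotype). Values are log2(x+1) of
#' optionally CPM-scaled counts.
#' @noRd
te_matrices <- function(rna, trap, sample_sheet, cpm = TRUE) {
  check_sample_sheet(sample_sheet)
  common <- intersect(rna$gene_id, trap$gene_id)
  dropped <- length(union(rna$gene_id, trap$gene_id)) - length(common)
  if (dropped > 0)
    inform(paste0("delta_te: dropping ", dropped, " gene(s) absent from one assay"))
  if (!length(common)) abort("insufficient data: no shared genes between assays")
  rna_m <- counts_matrix(log_counts(rna[match(common, rna$gene_id), ], cpm = cpm))
  trap_m <- counts_matrix(log_counts(trap[match(common, trap$gene_id), ], cpm = cpm))
  pick <- function(m, geno) {
    ids <- sample_sheet$sample_id[sample_sheet$genotype == geno &
                                    sample_sheet$sample_id %in% colnames(m)]
    if (length(ids) < 2L)
      abort(paste0("insufficient data: fewer than 2 '", geno, "' samples in an assay"))
    m[, ids, drop = FALSE]
  }
  list(trap_mut = pick(trap_m, "mutant"), trap_ctl = pick(trap_m, "control"),
       rna_mut = pick(rna_m, "mutant"), rna_ctl = pick(rna_m, "control"),
       gene_id = common)
}

#' Per-gene change in translation efficiency
#'
#' Computes, on `log2(count + 1)` scale,
#' `dTE = (TRAP_mutant - TRAP_control) - (RNA_mutant - RNA_control)`
#' using group means, so a gene whose total RNA drops while ribosome-bound
#' levels hold gets a positive dTE.
#'
#' @param rna,trap Count tibbles (`gene_id` + sample columns).
#' @param sample_sheet Sample sheet covering both assays' samples.
#' @param cpm Scale to counts-per-million before transforming (default TRUE).
#' @return Tibble `gene_id`, `delta_te`.
#' @export
delta_te <- function(rna, trap, sample_sheet, cpm = TRUE) {
  m <- te_matrices(rna, trap, sample_sheet, cpm = cpm)
  tibble(
    gene_id = m$gene_id,
    delta_te = unname((rowMeans(m$trap_mut) - rowMeans(m$trap_ctl)) -
                        (rowMeans(m$rna_mut) - rowMeans(m$rna_ctl)))
  )
}

#' @noRd
row_sds <- function(v) {
  n <- ncol(v)
  m <- rowMeans(v)
  sqrt(pmax(rowSums((v - m)^2), 0) / (n - 1L))
}

#' Internal jackknife core over four group matrices
#' @noRd
jackknife_core <- function(m, max_resamples = 100L, seed = 1L) {
  loo <- function(x) {
    n <- ncol(x)
    if (n < 2L) abort("resampling undefined: a group has a single sample")
    (rowSums(x) - x) / (n - 1L)
  }
  L <- map(m[c("trap_mut", "trap_ctl", "rna_mut", "rna_ctl")], loo)
  sizes <- map_int(L, ncol)
  combos <- as.matrix(expand.grid(i = seq_len(sizes[1]), j = seq_len(sizes[2]),
                                  k = seq_len(sizes[3]), l = seq_len(sizes[4])))
  n_comb <- nrow(combos)
  if (n_comb > max_resamples) {
    sel <- withr::with_seed(seed, sample.int(n_comb, max_resamples))
    combos <- combos[sel, , drop = FALSE]
  }
  vals <- vapply(seq_len(nrow(combos)), function(r) {
    (L[[1]][, combos[r, 1]] - L[[2]][, combos[r, 2]]) -
      (L[[3]][, combos[r, 3]] - L[[4]][, combos[r, 4]])
  }, numeric(nrow(L[[1]])))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  list(sd = row_sds(vals), n_resamples = nrow(combos))
}

#' Jackknife spread of the translation-efficiency change
#'
#' Resamples dTE by deleting one sample simultaneously from each of the four
#' groups (TRAP/RNA x mutant/control); the full Cartesian product of
#' deletions is used unless it exceeds `max_resamples`, in which case a
#' seeded uniform subsample of that size is drawn. The spread is the
#' standard deviation of the resampled dTE values.
#'
#' @inheritParams delta_te
#' @param max_resamples Cap on resample count (default 100).
#' @param seed Seed for the subsample draw.
#' @return Tibble `gene_id`, `jackknife_sd`, `n_resamples`.
#' @export
jackknife_sd <- function(rna, trap, sample_sheet, max_resamples = 100L,
                         seed = 1L, cpm = TRUE) {
  m <- te_matrices(rna, trap, sample_sheet, cpm = cpm)
  jk <- jackknife_core(m, max_resamples, seed)
  tibble(gene_id = m$gene_id, jackknife_sd = unname(jk$sd),
         n_resamples = jk$n_resamples)
}

#' Z-score for a translation-efficiency change
#'
#' `z = delta_te / jackknife_sd`. A zero spread with zero dTE gives z = 0; a
#' zero spread with nonzero dTE is unstable and reported as missing.
#'
#' @param delta_te Numeric dTE values.
#' @param jackknife_sd Matching non-negative spreads.
#' @return Tibble `z`, `unstable`.
#' @export
te_zscore <- function(delta_te, jackknife_sd) {
  if (any(jackknife_sd < 0, na.rm = TRUE)) abort("jackknife_sd must be non-negative")
  unstable <- jackknife_sd == 0 & delta_te != 0
  z <- ifelse(jackknife_sd > 0, delta_te / jackknife_sd,
              ifelse(delta_te == 0, 0, NA_real_))
  tibble(z = z, unstable = unstable)
}

#' One-sided upper-tail standard-normal p-value
#'
#' @param z Finite Z-scores.
#' @return `P(N(0,1) >= z)`.
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) abort("z must be finite")
  pnorm(z, lower.tail = FALSE)
}

#' Full translation-efficiency analysis
#'
#' Combines [delta_te()], [jackknife_sd()] and [te_zscore()] into a per-gene
#' result with one- and two-sided tail probabilities and a class label at
#' the `|z| >` threshold.
#'
#' @inheritParams jackknife_sd
#' @param z_threshold Classification threshold on `|z|` (default 4, the
#'   one-sided tail of which is about 3.2e-5).
#' @return Object of class `te_fit`; [tidy()] gives the per-gene table
#'   (`gene_id`, `delta_te`, `jackknife_sd`, `z`, `p_upper`, `p_twosided`,
#'   `unstable`, `class`).
#' @export
te_analysis <- function(rna, trap, sample_sheet, max_resamples = 100L,
                        seed = 1L, cpm = TRUE, z_threshold = 4) {
  m <- te_matrices(rna, trap, sample_sheet, cpm = cpm)
  dte <- (rowMeans(m$trap_mut) - rowMeans(m$trap_ctl)) -
    (rowMeans(m$rna_mut) - rowMeans(m$rna_ctl))
  jk <- jackknife_core(m, max_resamples, seed)
  zs <- te_zscore(unname(dte), unname(jk$sd))
  tbl <- tibble(
    gene_id = m$gene_id, delta_te = unname(dte), jackknife_sd = unname(jk$sd),
    z = zs$z,
    p_upper = ifelse(is.finite(zs$z), pnorm(zs$z, lower.tail = FALSE), NA_real_),
    p_twosided = ifelse(is.finite(zs$z), 2 * pnorm(-abs(zs$z)), NA_real_),
    unstable = zs$unstable,
    class = case_when(
      is.na(zs$z) ~ "unstable",
      zs$z > z_threshold ~ "increased",
      zs$z < -z_threshold ~ "decreased",
      TRUE ~ "unchanged"
    )
  )
  structure(list(table = tbl, z_threshold = z_threshold,
                 n_resamples = jk$n_resamples, cpm = cpm),
            class = "te_fit")
}

#' @export
tidy.te_fit <- function(x, ...) x$table

#' @export
glance.te_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$table), z_threshold = x$z_threshold,
         n_resamples = x$n_resamples,
         n_increased = sum(x$table$class == "increased"),
         n_decreased = sum(x$table$class == "decreased"),
         n_unstable = sum(x$table$class == "unstable"))
}

#' @export
print.te_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Translation-efficiency analysis: %d genes, %d jackknife resamples\n",
              g$n_genes, g$n_resamples))
  cat(sprintf("  |z| > %g: %d increased, %d decreased (%d unstable)\n",
              x$z_threshold, g$n_increased, g$n_decreased, g$n_unstable))
  invisible(x)
}

#' Split TE results into increased / decreased gene lists
#'
#' Strict thresholds: `z > z_threshold` and `z < -z_threshold`.
#'
#' @param te A `te_fit` or its [tidy()] table.
#' @param z_threshold Threshold on z (default 4).
#' @return Tibble `gene_id`, `z`, `direction`.
#' @export
classify_te <- function(te, z_threshold = 4) {
  tbl <- if (inherits(te, "te_fit")) te$table else te
  tbl %>%
    filter(is.finite(.data$z), abs(.data$z) > z_threshold) %>%
    mutate(direction = if_else(.data$z > 0, "increased", "decreased")) %>%
    select("gene_id", "z", "direction")
}

#' Empirical cumulative distribution table
#' @param values Numeric vector.
#' @return Tibble `value`, `cum_fraction`, sorted by value.
#' @export
ecdf_table <- function(values) {
  v <- sort(values[is.finite(values)])
  tibble(value = v, cum_fraction = seq_along(v) / length(v))
}

#' Gene-set shift test on translation-efficiency changes
#'
#' Welch two-sample t-test of dTE for genes in a set against all other
#' genes, with ECDF tables of both groups for plotting.
#'
#' @param te A `te_fit`, its [tidy()] table, or a tibble with `gene_id` and
#'   `delta_te`.
#' @param gene_set Character vector of member gene ids.
#' @return List with `$test` (tibble `t`, `df`, `p`, `mean_in_set`,
#'   `mean_out`, `n_in_set`, `n_out`) and `$ecdf` (tibble `group`, `value`,
#'   `cum_fraction`).
#' @export
group_shift_test <- function(te, gene_set) {
  tbl <- if (inherits(te, "te_fit")) te$table else te
  in_set <- tbl$delta_te[tbl$gene_id %in% gene_set]
  out <- tbl$delta_te[!tbl$gene_id %in% gene_set]
  in_set <- in_set[is.finite(in_set)]; out <- out[is.finite(out)]
  if (length(in_set) < 2L || length(out) < 2L)
    abort("insufficient data: need >= 2 genes in the set and its complement")
  tt <- t.test(in_set, out)
  list(
    test = tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value, mean_in_set = mean(in_set),
                  mean_out = mean(out), n_in_set = length(in_set),
                  n_out = length(out)),
    ecdf = bind_rows(
      mutate(ecdf_table(in_set), group = "in_set"),
      mutate(ecdf_table(out), group = "other")
    ) %>% select("group", "value", "cum_fraction")
  )
}
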