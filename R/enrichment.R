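#' Upper-tail hypergeometric probability of an overlap
#'
#' Exact probability of drawing at least `k` marked genes when `n` genes are
#' drawn without replacement from a universe of `N` containing `K` marked
#' ones: `P(X >= k)`.
#'
#' @param k Observed overlap.
#' @param K Marked genes in the universe (set size).
#' @param n Drawn genes (list size).
#' @param N Universe size.
#' @return The tail probability, in `(0, 1]`.
#' @export
hypergeom_p <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & k <= pmin(K, n) & K <= N & n <= N
  if (!all(ok)) abort("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric overlap test between two gene lists
#'
#' Members outside the universe are dropped (a warning reports how many).
#'
#' @param list_a Gene list of interest (e.g. a selection).
#' @param list_b Gene set to test against.
#' @param universe All genes eligible for either list — typically the genes
#'   passing the expression filter, not the whole annotation.
#' @param set_name Label for the result row.
#' @return Tibble `set_name`, `N`, `K`, `n`, `k`, `p_upper`.
#' @export
list_overlap_test <- function(list_a, list_b, universe, set_name = "overlap") {
  universe <- unique(universe)
  a <- unique(list_a); b <- unique(list_b)
  n_out <- sum(!a %in% universe) + sum(!b %in% universe)
  if (n_out > 0)
    warn(paste0("list_overlap_test: dropped ", n_out, " member(s) outside the universe"))
  a <- a[a %in% universe]; b <- b[b %in% universe]
  k <- length(intersect(a, b))
  tibble(set_name = set_name, N = length(universe), K = length(b),
         n = length(a), k = k,
         p_upper = hypergeom_p(k, length(b), length(a), length(universe)))
}

#' Hypergeometric enrichment of a gene list in each of several gene sets
#'
#' @param gene_list Genes of interest.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Universe of eligible genes.
#' @return Tibble with one row per set, as in [list_overlap_test()].
#' @export
enrichment_test <- function(gene_list, gene_sets, universe) {
  bind_rows(imap(gene_sets, function(members, nm)
    list_overlap_test(gene_list, members, universe, set_name = nm)))
}

#' Expression-matched control gene sample
#'
#' Splits the target genes' expression range into quantile bins and draws,
#' without replacement and deterministically under `seed`, the same number
#' of pool genes per bin — a control set with a matched expression
#' distribution.
#'
#' @param targets Character vector of target gene ids.
#' @param pool Candidate control genes (disjoint from `targets`).
#' @param expression Named numeric vector of expression values covering
#'   targets and pool.
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Seed for the draws.
#' @return Character vector of control gene ids, `length(targets)` long.
#' @export
expression_matched_sample <- function(targets, pool, expression, n_bins = 10L,
                                      seed = 1L) {
  pool <- setdiff(pool, targets)
  miss <- setdiff(c(targets, pool), names(expression))
  if (length(miss)) abort(paste0("expression values missing for ", length(miss), " gene(s)"))
  ex_t <- expression[targets]; ex_p <- expression[pool]
  if (any(!is.finite(c(ex_t, ex_p)))) abort("expression values must be finite")
  breaks <- unique(quantile(ex_t, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2L) breaks <- c(-Inf, Inf) # all targets share one value
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  breaks <- unique(breaks)
  bin_t <- cut(ex_t, breaks, labels = FALSE)
  bin_p <- cut(ex_p, breaks, labels = FALSE)
  need <- table(bin_t)
  have <- table(factor(bin_p, levels = names(need)))
  short <- names(need)[as.integer(have) < as.integer(need)]
  if (length(short))
    abort(paste0("insufficient pool genes in expression bin(s): ",
                 paste(short, collapse = ", ")))
  withr::with_seed(seed, {
    unlist(lapply(names(need), function(b) {
      cand <- pool[!is.na(bin_p) & bin_p == as.integer(b)]
      sample(cand, need[[b]])
    }), use.names = FALSE)
  })
}

#' Mann-Whitney U comparison of two length distributions
#'
#' Two-sided rank-sum test; exact enumeration when the combined sample size
#' is at most 12 and there are no ties, otherwise the tie-corrected normal
#' approximation.
#'
#' @param lengths_a,lengths_b Numeric samples (e.g. transcript or 5'UTR
#'   lengths), each with at least 2 values.
#' @return Tibble `u`, `p`, `n_a`, `n_b`, `median_a`, `median_b`.
#' @export
length_comparison <- function(lengths_a, lengths_b) {
  a <- lengths_a[is.finite(lengths_a)]; b <- lengths_b[is.finite(lengths_b)]
  if (length(a) < 2L || length(b) < 2L)
    abort("insufficient data: need >= 2 values per sample")
  exact <- (length(a) + length(b) <= 12L) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  tibble(u = unname(wt$statistic), p = wt$p.value,
         n_a = length(a), n_b = length(b),
         median_a = median(a), median_b = median(b))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated — name, description, then
#' member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) unique(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  out
}

#' Write gene sets to a GMT file
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], description, gene_sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
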