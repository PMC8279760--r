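#' Invert the trigamma function by Newton iteration
#' @noRd
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Method-of-moments empirical-Bayes prior for gene-wise variances
#'
#' Fits the scaled-F model `s^2 ~ s0^2 * F(d, d0)` to the distribution of
#' log sample variances by matching its first two moments, returning the
#' prior degrees of freedom `d0` and prior variance `s0^2`. When the moment
#' system is infeasible (log-variance spread no larger than the sampling
#' spread), `d0 = Inf` and the prior collapses to the pooled variance.
#'
#' @param s2 Gene-wise residual variances (positive values used).
#' @param df Residual degrees of freedom per gene.
#' @return List with `d0` and `s0_2`.
#' @export
eb_variance_prior <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L) return(list(d0 = Inf, s0_2 = mean(s2)))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated two-group differential expression
#'
#' Per gene, fits the two-group comparison on `log2` scale (optionally
#' CPM-scaled counts, see [log_counts()]): the log2 fold change is the
#' mutant-minus-control difference of means, and the residual variance is
#' shrunk toward an empirical-Bayes prior estimated by moments from all
#' genes ([eb_variance_prior()]). The moderated t statistic uses
#' `s_tilde^2 = (d0*s0^2 + d*s^2) / (d0 + d)` with `d0 + d` degrees of
#' freedom.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param sample_sheet Sample sheet with `sample_id`, `genotype`.
#' @param cpm Scale to counts-per-million before `log2(x+1)` (default TRUE).
#' @param prior_df Optional fixed prior df (overrides the moments estimate;
#'   `0` reduces to the ordinary two-sample t).
#' @param prior_var Optional fixed prior variance `s0^2` to pair with
#'   `prior_df`; defaults to the mean gene-wise variance when only
#'   `prior_df` is given.
#' @param fc_threshold,p_threshold Thresholds stored for the `significant`
#'   flag (linear fold change, raw p; defaults 2 and 0.01).
#' @return Object of class `de_fit`; [tidy()] gives the per-gene table
#'   (`gene_id`, `avg_log2_expr`, `log2FC`, `t`, `p`, `fdr`, `significant`),
#'   [glance()] the prior estimates.
#' @export
moderated_de <- function(counts, sample_sheet, cpm = TRUE, prior_df = NULL,
                         prior_var = NULL, fc_threshold = 2, p_threshold = 0.01) {
  check_sample_sheet(sample_sheet)
  lm_ <- counts_matrix(log_counts(counts, cpm = cpm))
  sheet <- sample_sheet[match(colnames(lm_), sample_sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) abort("sample sheet does not cover all count columns")
  mut <- lm_[, sheet$genotype == "mutant", drop = FALSE]
  ctl <- lm_[, sheet$genotype == "control", drop = FALSE]
  n1 <- ncol(mut); n2 <- ncol(ctl)
  if (n1 < 2L || n2 < 2L) abort("insufficient replication: need >= 2 samples per genotype")

  fc <- rowMeans(mut) - rowMeans(ctl)
  d <- n1 + n2 - 2L
  s2 <- (apply(mut, 1L, var) * (n1 - 1L) + apply(ctl, 1L, var) * (n2 - 1L)) / d

  if (is.null(prior_df)) {
    prior <- eb_variance_prior(s2, d)
  } else if (is.infinite(prior_df)) {
    prior <- list(d0 = Inf, s0_2 = exp(mean(log(s2[s2 > 0])) - digamma(d / 2) + log(d / 2)))
  } else {
    prior <- list(d0 = prior_df,
                  s0_2 = prior_var %||% if (prior_df > 0) mean(s2) else NA_real_)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s_tilde2 <- rep(s0_2, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s_tilde2 <- s2
    df_total <- d
  } else {
    s_tilde2 <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, NA_real_))
  p <- 2 * pt(-abs(t_stat), df = df_total)

  tbl <- tibble(
    gene_id = rownames(lm_),
    avg_log2_expr = unname(rowMeans(lm_)),
    log2FC = unname(fc),
    t = unname(t_stat),
    p = unname(p),
    fdr = p.adjust(p, method = "BH")
  ) %>%
    mutate(significant = abs(.data$log2FC) > log2(fc_threshold) & .data$p < p_threshold)

  structure(list(table = tbl, d0 = d0, s0_2 = s0_2, df_residual = d,
                 df_total = df_total, n_mutant = n1, n_control = n2,
                 cpm = cpm, fc_threshold = fc_threshold,
                 p_threshold = p_threshold),
            class = "de_fit")
}

#' @export
tidy.de_fit <- function(x, ...) x$table

#' @export
glance.de_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$table), prior_df = x$d0, prior_var = x$s0_2,
         df_residual = x$df_residual, df_total = x$df_total,
         n_significant = sum(x$table$significant, na.rm = TRUE))
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("Moderated differential expression: %d genes, %d mutant vs %d control\n",
              nrow(x$table), x$n_mutant, x$n_control))
  cat(sprintf("  prior df = %.2f, prior variance = %.4f\n", x$d0, x$s0_2))
  cat(sprintf("  significant (|log2FC| > %.2f, p < %g): %d\n",
              log2(x$fc_threshold), x$p_threshold,
              sum(x$table$significant, na.rm = TRUE)))
  invisible(x)
}

#' Classify differential-expression results into up / down lists
#'
#' Uses strict thresholds: `log2FC > log2(fc_threshold)` (resp. `<
#' -log2(fc_threshold)`) and `p < p_threshold`.
#'
#' @param de A `de_fit` or its [tidy()] table.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param p_threshold Raw p-value threshold (default 0.01).
#' @return Tibble `gene_id`, `log2FC`, `p`, `direction` (`"up"`/`"down"`).
#' @export
classify_de <- function(de, fc_threshold = 2, p_threshold = 0.01) {
  tbl <- if (inherits(de, "de_fit")) de$table else de
  lfc <- log2(fc_threshold)
  tbl %>%
    filter(!is.na(.data$p), .data$p < p_threshold, abs(.data$log2FC) > lfc) %>%
    mutate(direction = if_else(.data$log2FC > 0, "up", "down")) %>%
    select("gene_id", "log2FC", "p", "direction")
}

#' Pearson correlation between fold change and mean expression
#'
#' Diagnostic for expression-dependent shifts: a negative correlation means
#' highly expressed genes tend to be more downregulated.
#'
#' @param de A `de_fit` or its [tidy()] table.
#' @return Tibble `r`, `p`, `n`.
#' @export
fc_expression_correlation <- function(de) {
  tbl <- if (inherits(de, "de_fit")) de$table else de
  ok <- is.finite(tbl$log2FC) & is.finite(tbl$avg_log2_expr)
  x <- tbl$log2FC[ok]; y <- tbl$avg_log2_expr[ok]
  if (length(x) < 3L) abort("insufficient data: need >= 3 genes with finite values")
  if (sd(x) == 0 || sd(y) == 0) abort("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
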