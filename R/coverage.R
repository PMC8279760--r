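#' @noRd
exon_offsets <- function(exons) {
  len <- exons$end - exons$start
  mutate(exons, offset = cumsum(dplyr::lag(len, default = 0L)), len = len)
}

#' Internal: project weighted genomic intervals onto spliced coordinates
#' @noRd
project_to_spliced <- function(model_row, intervals) {
  L <- model_row$spliced_length
  depth <- numeric(L)
  ex <- exon_offsets(model_row$exons[[1L]])
  minus <- model_row$strand == "-"
  for (j in seq_len(nrow(ex))) {
    es <- ex$start[j]; ee <- ex$end[j]; off <- ex$offset[j]
    ov_s <- pmax(intervals$start, es)
    ov_e <- pmin(intervals$end, ee)
    keep <- which(ov_e > ov_s)
    for (k in keep) {
      if (minus) {
        s <- off + (ee - ov_e[k]); e <- off + (ee - ov_s[k])
      } else {
        s <- off + (ov_s[k] - es); e <- off + (ov_e[k] - es)
      }
      depth[(s + 1L):e] <- depth[(s + 1L):e] + intervals$value[k]
    }
  }
  depth
}

#' Per-base spliced coverage from aligned read blocks
#'
#' Each aligned base that falls inside an exon increments the corresponding
#' spliced position; intronic and flanking bases are ignored. Blocks are the
#' reference-space segments of a (possibly spliced) alignment.
#'
#' @param blocks Tibble of aligned blocks: `chrom`, `start`, `end` (0-based
#'   half-open, genomic) and optionally `sample_id`.
#' @param models Output of [transcript_models()].
#' @return Coverage tibble: `transcript_id`, `sample_id`, `spliced_length`,
#'   and list-column `depth` of per-base counts.
#' @export
per_base_coverage <- function(blocks, models) {
  if (!"sample_id" %in% names(blocks)) blocks$sample_id <- rep("sample", nrow(blocks))
  blocks$value <- rep(1, nrow(blocks))
  samples <- unique(blocks$sample_id)
  if (!length(samples)) samples <- "sample"   # no reads: all-zero vectors
  combos <- expand_grid(ti = seq_len(nrow(models)), sample_id = samples)
  rows <- pmap(combos, function(ti, sample_id) {
    mr <- models[ti, ]
    iv <- filter(blocks, .data$sample_id == !!sample_id, .data$chrom == mr$chrom)
    tibble(transcript_id = mr$transcript_id, sample_id = sample_id,
           spliced_length = mr$spliced_length,
           depth = list(project_to_spliced(mr, iv)))
  })
  bind_rows(rows)
}

#' Per-base spliced coverage from bedGraph depth intervals
#'
#' @param bedgraph Tibble `chrom`, `start`, `end` (0-based half-open),
#'   `depth`, or path to a bedGraph file.
#' @param models Output of [transcript_models()].
#' @param sample_id Label for the resulting coverage rows.
#' @return Coverage tibble as in [per_base_coverage()].
#' @export
coverage_from_bedgraph <- function(bedgraph, models, sample_id = "sample") {
  if (is.character(bedgraph)) bedgraph <- read_bedgraph(bedgraph)
  iv <- mutate(bedgraph, value = .data$depth)
  rows <- map(seq_len(nrow(models)), function(ti) {
    mr <- models[ti, ]
    tibble(transcript_id = mr$transcript_id, sample_id = sample_id,
           spliced_length = mr$spliced_length,
           depth = list(project_to_spliced(mr, filter(iv, .data$chrom == mr$chrom))))
  })
  bind_rows(rows)
}

#' Per-base spliced coverage from a SAM/BAM file
#'
#' Spliced alignments are split into reference blocks (CIGAR `N` gaps
#' respected) before projection onto transcript coordinates.
#'
#' @param path SAM or BAM file.
#' @param models Output of [transcript_models()].
#' @param sample_id Label for the resulting coverage rows.
#' @return Coverage tibble as in [per_base_coverage()].
#' @export
coverage_from_sam <- function(path, models, sample_id = "sample") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(path)
  gr <- unlist(GenomicAlignments::grglist(gal), use.names = FALSE)
  blocks <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    sample_id = sample_id
  )
  per_base_coverage(blocks, models)
}

#' Read a bedGraph file
#' @param path bedGraph path (track lines are skipped).
#' @return Tibble `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "depth"),
                  col_types = "ciid", progress = FALSE)
}

#' Write coverage as bedGraph over spliced coordinates
#' @param coverage Coverage tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  rows <- map(seq_len(nrow(coverage)), function(i) {
    d <- coverage$depth[[i]]
    r <- rle(d)
    e <- cumsum(r$lengths)
    tibble(chrom = coverage$transcript_id[i], start = e - r$lengths, end = e,
           depth = r$values)
  })
  readr::write_tsv(bind_rows(rows), path, col_names = FALSE)
  invisible(path)
}

#' Expression filter: at least one read per nucleotide on average
#'
#' @param depth Numeric per-base depth vector.
#' @return `TRUE` iff mean depth is at least 1.
#' @export
passes_expression_filter <- function(depth) {
  if (length(depth) == 0L) abort("degenerate input: zero-length coverage vector")
  mean(depth) >= 1
}

#' Keep coverage rows passing the expression filter
#' @param coverage Coverage tibble.
#' @return Filtered coverage tibble.
#' @export
filter_expressed <- function(coverage) {
  coverage[map_lgl(coverage$depth, passes_expression_filter), ]
}

#' Read-fraction profile over evenly spaced positional bins
#'
#' Bin `b` (0-based) covers spliced positions `[floor(b*L/n), floor((b+1)*L/n))`;
#' its fraction is the bin's depth sum over the transcript's total depth.
#' Empty bins (possible when `L < n_bins`) get fraction 0.
#'
#' @param depth Numeric per-base depth vector with positive total.
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of `n_bins` fractions summing to 1.
#' @export
bin_fractions <- function(depth, n_bins = 100L) {
  L <- length(depth)
  total <- sum(depth)
  if (total <= 0) abort("undefined profile: total depth is zero")
  cs <- c(0, cumsum(depth))
  edges <- floor((0:n_bins) * L / n_bins)
  (cs[edges[-1L] + 1L] - cs[edges[-(n_bins + 1L)] + 1L]) / total
}

#' Binned read-fraction profiles for a coverage table
#'
#' @param coverage Coverage tibble from [per_base_coverage()] and friends.
#' @param n_bins Number of bins (default 100).
#' @return Long tibble: `transcript_id`, `sample_id`, `bin` (1-based),
#'   `fraction`, `total_reads`.
#' @export
bin_profile <- function(coverage, n_bins = 100L) {
  rows <- map(seq_len(nrow(coverage)), function(i) {
    d <- coverage$depth[[i]]
    tibble(transcript_id = coverage$transcript_id[i],
           sample_id = coverage$sample_id[i],
           bin = seq_len(n_bins),
           fraction = bin_fractions(d, n_bins),
           total_reads = sum(d))
  })
  bind_rows(rows)
}

#' Metagene profile: median across transcripts, mean and SEM across animals
#'
#' Within each sample the per-bin median fraction across transcripts is
#' taken; those per-animal medians are then averaged per genotype, with the
#' SEM across animals as the spread.
#'
#' @param binned Output of [bin_profile()].
#' @param sample_sheet Tibble `sample_id`, `genotype`, `animal_id` (an
#'   `assay` column is allowed and ignored).
#' @return Tibble `genotype`, `bin`, `mean_fraction`, `sem`, `n_animals`.
#' @export
metagene_summary <- function(binned, sample_sheet) {
  per_sample <- binned %>%
    group_by(.data$sample_id, .data$bin) %>%
    summarise(med = median(.data$fraction), .groups = "drop") %>%
    inner_join(select(sample_sheet, "sample_id", "genotype", "animal_id"),
               by = "sample_id")
  out <- per_sample %>%
    group_by(.data$genotype, .data$bin) %>%
    summarise(mean_fraction = mean(.data$med),
              sem = sd(.data$med) / sqrt(n()),
              n_animals = n(), .groups = "drop")
  if (any(out$n_animals < 2L))
    warn("genotype with a single animal: SEM undefined (NA)")
  out
}

#' Region (5'UTR / CDS / 3'UTR) coverage fractions for one transcript
#'
#' @param depth Per-base depth vector with positive total.
#' @param seg_row One row of [segment_transcripts()] with `has_orf = TRUE`.
#' @return Tibble `region`, `depth_sum`, `fraction`, `log2_depth`
#'   (`log2(depth_sum + 1)`).
#' @export
region_fractions <- function(depth, seg_row) {
  if (!isTRUE(seg_row$has_orf)) abort("segmentation missing: transcript has no ORF")
  total <- sum(depth)
  if (total <= 0) abort("undefined fractions: total depth is zero")
  span_sum <- function(s, e) if (e > s) sum(depth[(s + 1L):e]) else 0
  sums <- c(utr5 = span_sum(seg_row$utr5_start, seg_row$utr5_end),
            cds  = span_sum(seg_row$cds_start, seg_row$cds_end),
            utr3 = span_sum(seg_row$utr3_start, seg_row$utr3_end))
  tibble(region = factor(names(sums), levels = c("utr5", "cds", "utr3")),
         depth_sum = unname(sums), fraction = unname(sums) / total,
         log2_depth = log2(unname(sums) + 1))
}

#' Region coverage fractions for a coverage table
#'
#' Transcripts without an ORF segmentation (or with zero total depth) are
#' skipped with a message.
#'
#' @param coverage Coverage tibble.
#' @param segmentation Output of [segment_transcripts()].
#' @return Long tibble: `transcript_id`, `sample_id`, `region`, `depth_sum`,
#'   `fraction`, `log2_depth`.
#' @export
region_coverage <- function(coverage, segmentation) {
  seg <- filter(segmentation, .data$has_orf)
  skipped <- setdiff(unique(coverage$transcript_id), seg$transcript_id)
  if (length(skipped))
    inform(paste0("region_coverage: skipping ", length(skipped),
                  " transcript(s) without ORF segmentation"))
  cov <- filter(coverage, .data$transcript_id %in% seg$transcript_id,
                map_dbl(.data$depth, sum) > 0)
  rows <- map(seq_len(nrow(cov)), function(i) {
    sr <- seg[seg$transcript_id == cov$transcript_id[i], ]
    bind_cols(tibble(transcript_id = cov$transcript_id[i],
                     sample_id = cov$sample_id[i]),
              region_fractions(cov$depth[[i]], sr))
  })
  bind_rows(rows)
}

#' Mutant-minus-control region coverage deltas
#'
#' Aggregation happens at the fraction level: per region, the mean fraction
#' across mutant animals minus the mean across control animals. A region
#' log2 fold change (difference of mean `log2(depth + 1)`) is carried along
#' for the 3'UTR-bias selection. Transcripts absent from one genotype are
#' excluded with a message.
#'
#' @param region_cov Output of [region_coverage()].
#' @param sample_sheet Tibble with `sample_id`, `genotype`.
#' @return Tibble `transcript_id`, `region`, `frac_control`, `frac_mutant`,
#'   `delta`, `region_log2fc`.
#' @export
region_delta <- function(region_cov, sample_sheet) {
  joined <- inner_join(region_cov, select(sample_sheet, "sample_id", "genotype"),
                       by = "sample_id")
  both <- joined %>%
    group_by(.data$transcript_id) %>%
    summarise(n_geno = n_distinct(.data$genotype), .groups = "drop")
  excluded <- both$transcript_id[both$n_geno < 2L]
  if (length(excluded))
    inform(paste0("region_delta: excluding ", length(excluded),
                  " transcript(s) absent from one genotype"))
  joined %>%
    filter(!.data$transcript_id %in% excluded) %>%
    group_by(.data$transcript_id, .data$region) %>%
    summarise(
      frac_control = mean(.data$fraction[.data$genotype == "control"]),
      frac_mutant = mean(.data$fraction[.data$genotype == "mutant"]),
      region_log2fc = mean(.data$log2_depth[.data$genotype == "mutant"]) -
        mean(.data$log2_depth[.data$genotype == "control"]),
      .groups = "drop"
    ) %>%
    mutate(delta = .data$frac_mutant - .data$frac_control)
}

#' One-way ANOVA with Tukey HSD across region delta groups
#'
#' Tests whether the mutant-minus-control coverage change differs between
#' the 5'UTR, CDS and 3'UTR across transcripts.
#'
#' @param deltas Output of [region_delta()] (already restricted to the
#'   transcript set of interest, e.g. downregulated genes).
#' @return An object of class `region_comparison`; see [tidy()] for the
#'   pairwise Tukey table and [glance()] for the overall F test.
#' @export
compare_regions <- function(deltas) {
  counts <- table(deltas$region[!is.na(deltas$delta)])
  counts <- counts[counts > 0]
  if (length(counts) < 2L) abort("insufficient data: need at least two region groups")
  if (any(counts < 2L)) abort("insufficient data: need >= 2 transcripts per region")
  df <- mutate(deltas, region = factor(.data$region, levels = c("utr5", "cds", "utr3")))
  fit <- aov(delta ~ region, data = df)
  tk <- TukeyHSD(fit)$region
  an <- summary(fit)[[1L]]
  structure(list(
    fit = fit,
    anova = tibble(f_statistic = an[["F value"]][1L], p_value = an[["Pr(>F)"]][1L],
                   df_between = an[["Df"]][1L], df_within = an[["Df"]][2L]),
    tukey = tibble(contrast = rownames(tk), diff = tk[, "diff"],
                   conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                   p_adj = tk[, "p adj"]),
    n = nrow(df)
  ), class = "region_comparison")
}

#' @export
tidy.region_comparison <- function(x, ...) x$tukey

#' @export
glance.region_comparison <- function(x, ...) bind_cols(x$anova, tibble(n = x$n))

#' @export
print.region_comparison <- function(x, ...) {
  cat("Region coverage-delta comparison (one-way ANOVA + Tukey HSD)\n")
  cat(sprintf("  F = %.3f on %d/%d df, p = %.3g, n = %d\n",
              x$anova$f_statistic, x$anova$df_between, x$anova$df_within,
              x$anova$p_value, x$n))
  print(x$tukey)
  invisible(x)
}

#' Select transcripts with a 3'UTR change exceeding the transcript change
#'
#' Among downregulated transcripts, keeps those whose 3'UTR log2 fold change
#' is strictly more negative than the transcript-level log2 fold change from
#' the differential-expression stage — the signature of 3'-biased loss.
#'
#' @param de_down Tibble of downregulated transcripts: `gene_id`, `log2FC`.
#' @param deltas Output of [region_delta()].
#' @return Tibble `transcript_id`, `transcript_log2fc`, `utr3_log2fc`.
#' @export
select_3utr_biased <- function(de_down, deltas) {
  utr3 <- filter(deltas, .data$region == "utr3")
  merged <- inner_join(select(de_down, transcript_id = "gene_id", transcript_log2fc = "log2FC"),
                       select(utr3, "transcript_id", utr3_log2fc = "region_log2fc"),
                       by = "transcript_id")
  missing <- nrow(de_down) - nrow(merged)
  if (missing > 0)
    inform(paste0("select_3utr_biased: skipping ", missing,
                  " transcript(s) without region data"))
  filter(merged, .data$utr3_log2fc < .data$transcript_log2fc)
}
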