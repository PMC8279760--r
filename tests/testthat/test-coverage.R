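single_exon_model <- function(len, strand = "+") {
  transcript_models(tibble::tibble(chrom = "c1", start = 0L, end = len,
                                   strand = strand, transcript_id = "t1",
                                   gene_id = "g1"))
}

test_that("per-base coverage maps read blocks onto spliced coordinates", {
  m <- single_exon_model(20L)
  cov <- per_base_coverage(tibble::tibble(chrom = character(), start = integer(),
                                          end = integer()), m)
  expect_equal(cov$depth[[1]], rep(0, 20))

  cov <- per_base_coverage(tibble::tibble(chrom = "c1", start = 0L, end = 10L), m)
  expect_equal(cov$depth[[1]], c(rep(1, 10), rep(0, 10)))

  # spliced read across an intron: [5,25) on exons [0,10)+[20,30)
  m2 <- transcript_models(tibble::tibble(
    chrom = "c1", start = c(0L, 20L), end = c(10L, 30L), strand = "+",
    transcript_id = "t1", gene_id = "g1"))
  blocks <- tibble::tibble(chrom = "c1", start = c(5L, 20L), end = c(10L, 25L))
  cov <- per_base_coverage(blocks, m2)
  expect_equal(which(cov$depth[[1]] > 0) - 1L, 5:14)

  # minus strand: genomic block [0,5) is the transcript's 3' end
  m3 <- single_exon_model(20L, strand = "-")
  cov <- per_base_coverage(tibble::tibble(chrom = "c1", start = 0L, end = 5L), m3)
  expect_equal(which(cov$depth[[1]] > 0) - 1L, 15:19)
})

test_that("SAM alignments with spliced CIGARs are projected correctly", {
  m <- transcript_models(tibble::tibble(
    chrom = "c1", start = c(0L, 30L), end = c(10L, 40L), strand = "+",
    transcript_id = "t1", gene_id = "g1"))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:100",
    # 1-based POS 1, 5M: covers genomic [0,5) -> spliced 0..4
    paste("r1", 0, "c1", 1, 60, "5M", "*", 0, 0, "AAAAA", "*", sep = "\t"),
    # POS 6, 5M20N5M: genomic [5,10) + [30,35) -> spliced 5..9 and 10..14
    paste("r2", 0, "c1", 6, 60, "5M20N5M", "*", 0, 0, strrep("A", 10), "*", sep = "\t")
  ), sam)
  cov <- coverage_from_sam(sam, m, sample_id = "s1")
  expect_equal(cov$depth[[1]], c(rep(1, 15), rep(0, 5)))
})

test_that("expression filter uses mean depth with an inclusive boundary", {
  expect_true(passes_expression_filter(rep(1, 50)))
  expect_false(passes_expression_filter(c(rep(1, 99), 0)))
  d <- rep(0, 100); d[1] <- 100
  expect_true(passes_expression_filter(d))
  expect_error(passes_expression_filter(numeric(0)), "degenerate")
})

test_that("bin fractions follow the floor rule and conserve mass", {
  expect_equal(bin_fractions(rep(3, 200)), rep(0.01, 100))

  d <- rep(0, 100); d[1] <- 10
  expect_equal(bin_fractions(d), c(1, rep(0, 99)))

  # L = 150: bin sizes alternate per floor((b+1)*150/100) - floor(b*150/100)
  f <- bin_fractions(rep(1, 150))
  edges <- floor((0:100) * 150 / 100)
  expect_equal(f, diff(edges) / 150)
  expect_equal(sum(f), 1)

  expect_error(bin_fractions(rep(0, 50)), "undefined profile")
})

test_that("bin fractions conserve mass and ignore depth scaling", {
  withr::with_seed(5, {
    for (i in 1:50) {
      L <- sample(40:2000, 1)
      d <- random_depth(L, seed = i)
      if (sum(d) == 0) d[1] <- 1
      f <- bin_fractions(d)
      expect_equal(sum(f), 1, tolerance = 1e-12)
      expect_true(all(f >= 0 & f <= 1))
      expect_equal(bin_fractions(d * 7), f)
    }
  })
})

test_that("metagene summary is median-within-animal, mean/SEM-across-animals", {
  mk_binned <- function(sample_id, fracs_by_tx) {
    dplyr::bind_rows(lapply(seq_along(fracs_by_tx), function(i)
      tibble::tibble(transcript_id = paste0("t", i), sample_id = sample_id,
                     bin = seq_along(fracs_by_tx[[i]]),
                     fraction = fracs_by_tx[[i]], total_reads = 100)))
  }
  sheet <- tibble::tibble(sample_id = c("a1", "a2", "a3"),
                          genotype = "control", assay = "RNA",
                          animal_id = c("A", "B", "C"))
  # per-animal per-bin medians 0.2/0.3/0.7 in bin 1 -> SEM = sd/sqrt(3)
  b <- dplyr::bind_rows(
    mk_binned("a1", list(c(0.2, 0.8), c(0.2, 0.8), c(0.9, 0.1))),
    mk_binned("a2", list(c(0.3, 0.7), c(0.3, 0.7), c(0.1, 0.9))),
    mk_binned("a3", list(c(0.7, 0.3), c(0.7, 0.3), c(0.2, 0.8)))
  )
  mg <- metagene_summary(b, sheet)
  bin1 <- mg[mg$bin == 1, ]
  expect_equal(bin1$mean_fraction, mean(c(0.2, 0.3, 0.7)))
  expect_equal(bin1$sem, sd(c(0.2, 0.3, 0.7)) / sqrt(3))

  # uniform profiles -> flat at 1/n_bins with zero SEM
  u <- mk_binned("a1", list(rep(0.5, 2), rep(0.5, 2)))
  mg <- metagene_summary(dplyr::bind_rows(
    u, dplyr::mutate(u, sample_id = "a2"), dplyr::mutate(u, sample_id = "a3")), sheet)
  expect_true(all(mg$mean_fraction == 0.5))
  expect_true(all(mg$sem == 0))

  expect_warning(metagene_summary(u, sheet[1, ]), "single animal")
})

test_that("region fractions split depth by segmentation and conserve mass", {
  seg <- tibble::tibble(transcript_id = "t1", has_orf = TRUE,
                        utr5_start = 0L, utr5_end = 10L,
                        cds_start = 10L, cds_end = 90L,
                        utr3_start = 90L, utr3_end = 100L)
  rf <- region_fractions(rep(2, 100), seg)
  expect_equal(rf$fraction, c(0.1, 0.8, 0.1))

  d <- rep(0, 100); d[20:40] <- 5
  expect_equal(region_fractions(d, seg)$fraction, c(0, 1, 0))

  # hand sum: utr5 len 2 (depth 2), cds len 6 (depth 2), utr3 len 2 (depth 1)
  seg2 <- tibble::tibble(transcript_id = "t1", has_orf = TRUE,
                         utr5_start = 0L, utr5_end = 2L, cds_start = 2L,
                         cds_end = 8L, utr3_start = 8L, utr3_end = 10L)
  d2 <- c(2, 2, 2, 2, 2, 2, 2, 2, 1, 1)
  rf2 <- region_fractions(d2, seg2)
  expect_equal(rf2$depth_sum, c(4, 12, 2))
  expect_equal(rf2$fraction, c(4, 12, 2) / 18)
  expect_equal(sum(rf2$fraction), 1)

  expect_error(region_fractions(rep(1, 10), dplyr::mutate(seg2, has_orf = FALSE)),
               "segmentation missing")
})

test_that("region deltas are differences of per-genotype mean fractions", {
  rc <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "t1", sample_id = c("c1", "c2", "m1", "m2")),
    tibble::tibble(transcript_id = "t2", sample_id = c("c1", "c2", "m1", "m2"))
  ) |>
    dplyr::group_by(transcript_id, sample_id) |>
    dplyr::reframe(region = factor(c("utr5", "cds", "utr3"),
                                   levels = c("utr5", "cds", "utr3")),
                   fraction = NA_real_, log2_depth = 1)
  # distinct per-animal fractions: delta must equal difference of means
  fr <- c(c1 = 0.10, c2 = 0.14, m1 = 0.06, m2 = 0.04)
  rc$fraction <- ifelse(rc$region == "utr3", fr[rc$sample_id],
                        (1 - fr[rc$sample_id]) / 2)
  sheet <- tibble::tibble(sample_id = c("c1", "c2", "m1", "m2"),
                          genotype = c("control", "control", "mutant", "mutant"))
  rd <- region_delta(rc, sheet)
  utr3 <- rd[rd$region == "utr3" & rd$transcript_id == "t1", ]
  expect_equal(utr3$delta, mean(c(0.06, 0.04)) - mean(c(0.10, 0.14)))

  # identical genotypes -> all deltas zero
  rc0 <- rc; rc0$fraction <- 1 / 3
  expect_true(all(region_delta(rc0, sheet)$delta == 0))

  # transcript observed in one genotype only is excluded with a message
  rc_miss <- dplyr::filter(rc, !(transcript_id == "t2" & sample_id %in% c("m1", "m2")))
  expect_message(rd2 <- region_delta(rc_miss, sheet), "excluding")
  expect_false("t2" %in% rd2$transcript_id)
})

test_that("region ANOVA + Tukey matches hand arithmetic and flags shifts", {
  # identical groups -> F ~ 0, all pairwise p ~ 1
  d0 <- tibble::tibble(
    transcript_id = rep(paste0("t", 1:4), 3),
    region = rep(c("utr5", "cds", "utr3"), each = 4),
    delta = rep(c(0.01, -0.01, 0.02, -0.02), 3))
  cr <- compare_regions(d0)
  expect_lt(glance(cr)$f_statistic, 1e-10)
  expect_true(all(tidy(cr)$p_adj > 0.999))

  # textbook 3-group toy: groups (1,2,3), (2,3,4), (6,7,8)
  vals <- list(utr5 = c(1, 2, 3), cds = c(2, 3, 4), utr3 = c(6, 7, 8))
  d1 <- dplyr::bind_rows(lapply(names(vals), function(r)
    tibble::tibble(transcript_id = paste0(r, 1:3), region = r, delta = vals[[r]])))
  gm <- mean(unlist(vals))
  ssb <- 3 * sum((sapply(vals, mean) - gm)^2)
  ssw <- sum(sapply(vals, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(glance(compare_regions(d1))$f_statistic, f_hand, tolerance = 1e-12)

  # one group shifted by ~10 SD -> both of its pairwise p-values < 0.001
  withr::with_seed(8, {
    d2 <- dplyr::bind_rows(
      tibble::tibble(transcript_id = paste0("a", 1:30), region = "utr5",
                     delta = rnorm(30, 0, 0.01)),
      tibble::tibble(transcript_id = paste0("b", 1:30), region = "cds",
                     delta = rnorm(30, 0, 0.01)),
      tibble::tibble(transcript_id = paste0("c", 1:30), region = "utr3",
                     delta = rnorm(30, -0.1, 0.01)))
  })
  tk <- tidy(compare_regions(d2))
  expect_true(all(tk$p_adj[grepl("utr3", tk$contrast)] < 0.001))

  expect_error(compare_regions(d0[d0$region == "cds", ]), "insufficient")
})

test_that("3'UTR-biased selection uses a strict inequality on log2FC", {
  deltas <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    region = "utr3",
    region_log2fc = c(-2.0, -0.5, -1.0))
  down <- tibble::tibble(gene_id = c("t1", "t2", "t3", "t4"),
                         log2FC = c(-1, -1, -1, -1))
  expect_message(sel <- select_3utr_biased(down, deltas), "skipping")
  expect_equal(sel$transcript_id, "t1") # -0.5 not selected; -1.0 tie excluded
})

test_that("bedGraph round-trip preserves per-base depth", {
  cfg <- sim_config(seed = 2)
  d <- simulate_coverage(500L, 100L, 75L, 0.1, seed = 4)
  cov <- tibble::tibble(transcript_id = "tx1", sample_id = "s",
                        spliced_length = 500L, depth = list(as.numeric(d)))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(cov, bg)
  tbl <- read_bedgraph(bg)
  back <- numeric(500)
  for (r in seq_len(nrow(tbl))) back[(tbl$start[r] + 1):tbl$end[r]] <- tbl$depth[r]
  expect_equal(back, as.numeric(d))
})
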