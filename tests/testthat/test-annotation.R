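exon_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(chrom = r[[1]], start = r[[2]], end = r[[3]], strand = r[[4]],
                   transcript_id = r[[5]], gene_id = r[[6]])))
}

test_that("transcript models order exons 5'->3' and sum spliced length", {
  m <- transcript_models(exon_tbl(list("c1", 100L, 200L, "+", "t1", "g1")))
  expect_equal(m$spliced_length, 100L)
  expect_equal(m$n_exons, 1L)

  m <- transcript_models(exon_tbl(list("c1", 0L, 10L, "+", "t1", "g1"),
                                  list("c1", 20L, 30L, "+", "t1", "g1")))
  expect_equal(m$spliced_length, 20L)
  expect_equal(m$exons[[1]]$start, c(0L, 20L))

  m <- transcript_models(exon_tbl(list("c1", 0L, 10L, "-", "t1", "g1"),
                                  list("c1", 20L, 30L, "-", "t1", "g1")))
  expect_equal(m$spliced_length, 20L)
  expect_equal(m$exons[[1]]$start, c(20L, 0L)) # downstream exon first on minus
})

test_that("minus-strand spliced position 0 maps to the 3'-most genomic base", {
  # genomic base 29 marked: a minus-strand transcript over [0,10)+[20,30)
  # must start with the complement of that base
  chrom <- paste0(strrep("A", 29), "G") # base 29 (0-based) is G
  m <- transcript_models(exon_tbl(list("c1", 0L, 10L, "-", "t1", "g1"),
                                  list("c1", 20L, 30L, "-", "t1", "g1")))
  seq <- spliced_sequence(m, c(c1 = chrom))$sequence
  expect_equal(substring(seq, 1, 1), "C") # revcomp of G
  expect_equal(nchar(seq), 20L)
})

test_that("malformed annotations are rejected", {
  expect_error(transcript_models(exon_tbl(list("c1", 0L, 10L, "+", "t1", "g1"),
                                          list("c2", 20L, 30L, "+", "t1", "g1"))),
               "malformed")
  expect_error(transcript_models(exon_tbl(list("c1", 0L, 10L, "+", "t1", "g1"),
                                          list("c1", 5L, 30L, "+", "t1", "g1"))),
               "overlap")
  expect_error(transcript_models(exon_tbl(list("c1", 0L, 10L, "+", "t1", "g1"),
                                          list("c1", 20L, 30L, "-", "t1", "g1"))),
               "malformed")
})

test_that("spliced_sequence splices and reverse-complements", {
  m <- transcript_models(exon_tbl(list("c1", 0L, 4L, "+", "t1", "g1")))
  expect_equal(spliced_sequence(m, c(c1 = "ACGTTT"))$sequence, "ACGT")

  m <- transcript_models(exon_tbl(list("c1", 0L, 4L, "-", "t1", "g1")))
  expect_equal(spliced_sequence(m, c(c1 = "AAGTTT"))$sequence, "ACTT")

  m <- transcript_models(exon_tbl(list("c1", 0L, 2L, "+", "t1", "g1"),
                                  list("c1", 4L, 6L, "+", "t1", "g1")))
  expect_equal(spliced_sequence(m, c(c1 = "ACGTTT"))$sequence, "ACTT")

  expect_error(spliced_sequence(m, c(c1 = "ACG")), "bounds")
  expect_error(spliced_sequence(m, c(other = "ACGTTT")), "unknown chromosome")
})

test_that("plus-strand and reverse-complemented minus-strand loci agree", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      L <- sample(30:80, 1)
      chrom <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      cuts <- sort(sample(seq_len(L - 1), 3))
      ex_plus <- exon_tbl(list("c", 0L, cuts[1], "+", "t", "g"),
                          list("c", cuts[2], cuts[3], "+", "t", "g"))
      s_plus <- spliced_sequence(transcript_models(ex_plus), c(c = chrom))$sequence
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
      ex_minus <- exon_tbl(list("c", L - cuts[3], L - cuts[2], "-", "t", "g"),
                           list("c", L - cuts[1], L, "-", "t", "g"))
      s_minus <- spliced_sequence(transcript_models(ex_minus), c(c = rc))$sequence
      expect_identical(s_plus, s_minus)
    }
  })
})

test_that("find_longest_orf handles the canonical cases", {
  r <- find_longest_orf("ATGAAATAA")
  expect_true(r$has_orf)
  expect_equal(c(r$cds_start, r$cds_end), c(0L, 9L))
  expect_equal(r$utr5_end - r$utr5_start, 0L)
  expect_equal(r$utr3_end - r$utr3_start, 0L)

  expect_false(find_longest_orf("CCCCCCCC")$has_orf)

  r <- find_longest_orf("GGATGAAATAAGG")
  expect_equal(c(r$cds_start, r$cds_end), c(2L, 11L))
  expect_equal(c(r$utr5_start, r$utr5_end), c(0L, 2L))
  expect_equal(c(r$utr3_start, r$utr3_end), c(11L, 13L))

  expect_error(find_longest_orf(""), "empty")
  # ATG with no in-frame stop runs to the last complete codon
  r <- find_longest_orf("ATGAAAAAAA")
  expect_equal(c(r$cds_start, r$cds_end), c(0L, 9L))
  # codons containing N never match start or stop
  expect_false(find_longest_orf("ATNAAATAA")$has_orf)
})

test_that("longest-ORF search matches the brute-force enumerator", {
  withr::with_seed(42, {
    for (i in 1:200) {
      L <- sample(10:600, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      got <- find_longest_orf(seq)
      want <- orf_oracle(seq)
      if (is.null(want)) {
        expect_false(got$has_orf)
      } else {
        expect_true(got$has_orf)
        expect_equal(got$cds_start, want$start)
        expect_equal(got$cds_end, want$end)
      }
      if (got$has_orf) { # regions tile the transcript
        expect_equal((got$utr5_end - got$utr5_start) + (got$cds_end - got$cds_start) +
                       (got$utr3_end - got$utr3_start), L)
      }
    }
  })
})

test_that("GTF round-trip preserves models and BED export is well-formed", {
  cfg <- sim_config(seed = 3)
  tx <- simulate_transcripts(cfg, n_transcripts = 8)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(tx$models, gtf)
  back <- transcript_models(read_exons_gtf(gtf))
  back <- back[match(tx$models$transcript_id, back$transcript_id), ]
  expect_equal(back$spliced_length, tx$models$spliced_length)
  expect_equal(back$strand, tx$models$strand)
  expect_equal(spliced_sequence(back, tx$genome)$sequence, tx$models$sequence)

  seg <- segment_transcripts(tx$models)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segmentation_bed(seg, bed)
  tbl <- readr::read_tsv(bed, col_names = c("tx", "start", "end", "name"),
                         show_col_types = FALSE)
  expect_true(all(tbl$end > tbl$start))
  expect_true(all(tbl$name %in% c("utr5", "cds", "utr3")))
  spans <- tbl |> dplyr::group_by(tx) |> dplyr::summarise(total = sum(end - start))
  m <- seg[match(spans$tx, seg$transcript_id), ]
  expect_equal(spans$total, m$spliced_length)
})
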