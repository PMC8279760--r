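#' Build spliced transcript models from exon records
#'
#' Groups exon intervals by transcript and orders them in transcript
#' (5' to 3') orientation: ascending genomic coordinate on the plus strand,
#' descending on the minus strand. All coordinates are 0-based, half-open.
#'
#' @param exons Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `transcript_id`, `gene_id`.
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `spliced_length`, and a list-column
#'   `exons` of `(start, end)` tibbles in transcript order.
#' @export
transcript_models <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  miss <- setdiff(need, names(exons))
  if (length(miss)) abort(paste("exon table missing columns:", paste(miss, collapse = ", ")))
  if (any(exons$end <= exons$start)) abort("malformed annotation: empty or inverted exon")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")

  exons %>%
    group_by(.data$transcript_id) %>%
    dplyr::group_modify(function(df, key) {
      if (n_distinct(df$chrom) > 1L || n_distinct(df$strand) > 1L)
        abort(paste0("malformed annotation: transcript ", key$transcript_id,
                     " mixes chromosomes or strands"))
      if (n_distinct(df$gene_id) > 1L)
        abort(paste0("malformed annotation: transcript ", key$transcript_id,
                     " assigned to several genes"))
      df <- arrange(df, .data$start)
      if (nrow(df) > 1L && any(df$end[-nrow(df)] > df$start[-1L]))
        abort(paste0("malformed annotation: overlapping exons in ", key$transcript_id))
      if (df$strand[1L] == "-") df <- arrange(df, dplyr::desc(.data$start))
      tibble(
        gene_id = df$gene_id[1L], chrom = df$chrom[1L], strand = df$strand[1L],
        n_exons = nrow(df), spliced_length = sum(df$end - df$start),
        exons = list(tibble(start = df$start, end = df$end))
      )
    }) %>%
    ungroup()
}

#' Extract the spliced (mature mRNA) sequence of each transcript
#'
#' Concatenates exon sequences; minus-strand transcripts are
#' reverse-complemented so position 0 of the returned string is the 5' end.
#'
#' @param models Output of [transcript_models()].
#' @param genome Named character vector, `Biostrings::DNAStringSet`, or path
#'   to a FASTA file.
#' @return `models` with an added character column `sequence`.
#' @export
spliced_sequence <- function(models, genome) {
  genome <- as_genome(genome)
  seqs <- map_chr(seq_len(nrow(models)), function(i) {
    chrom <- models$chrom[i]
    if (!chrom %in% names(genome)) abort(paste("unknown chromosome:", chrom))
    chr <- genome[[chrom]]
    ex <- arrange(models$exons[[i]], .data$start)
    if (any(ex$start < 0) || any(ex$end > length(chr)))
      abort(paste("exon outside chromosome bounds for", models$transcript_id[i]))
    pieces <- Biostrings::DNAStringSet(map(seq_len(nrow(ex)), function(j)
      Biostrings::subseq(chr, start = ex$start[j] + 1L, end = ex$end[j])))
    s <- Reduce(Biostrings::xscat, pieces)
    if (models$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  mutate(models, sequence = seqs)
}

#' @noRd
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome character vector must be named by chromosome")
    return(Biostrings::DNAStringSet(genome))
  }
  if (methods::is(genome, "DNAStringSet")) return(genome)
  abort("genome must be a named character vector, DNAStringSet or FASTA path")
}

ORF_STOPS <- c("TAA", "TAG", "TGA")

#' Find the longest ATG-initiated open reading frame
#'
#' Scans all three forward frames for ATG...stop spans and returns the
#' longest; ties are broken toward the 5'-most start. An ATG with no in-frame
#' stop is accepted and the reading frame runs to the last complete codon
#' (3'-incomplete assembled transcripts are common). Codons containing `N`
#' never match ATG or a stop.
#'
#' @param sequence Character vector of nucleotide sequences over `A,C,G,T,N`.
#' @return Tibble with one row per sequence: `length`, `has_orf`, and 0-based
#'   half-open spliced intervals `utr5_start/utr5_end`, `cds_start/cds_end`,
#'   `utr3_start/utr3_end` (all `NA` when `has_orf` is `FALSE`).
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(nchar(sequence) == 0L)) abort("degenerate input: empty sequence")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) abort("sequence contains characters outside A,C,G,T,N")

  one <- function(seq) {
    L <- nchar(seq)
    best_start <- NA_integer_; best_end <- NA_integer_; best_len <- 0L
    for (f in 0:2) {
      n_codons <- (L - f) %/% 3L
      if (n_codons < 1L) next
      starts <- f + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(seq, starts + 1L, starts + 3L)
      open <- NA_integer_
      for (ci in seq_len(n_codons)) {
        cd <- codons[ci]
        if (is.na(open) && cd == "ATG") open <- starts[ci]
        else if (!is.na(open) && cd %in% ORF_STOPS) {
          len <- starts[ci] + 3L - open
          if (len > best_len || (len == best_len && open < best_start)) {
            best_len <- len; best_start <- open; best_end <- starts[ci] + 3L
          }
          open <- NA_integer_
        }
      }
      if (!is.na(open)) {                       # runs to last complete codon
        end <- starts[n_codons] + 3L
        len <- end - open
        if (len > best_len || (len == best_len && open < best_start)) {
          best_len <- len; best_start <- open; best_end <- end
        }
      }
    }
    if (is.na(best_start))
      tibble(length = L, has_orf = FALSE,
             utr5_start = NA_integer_, utr5_end = NA_integer_,
             cds_start = NA_integer_, cds_end = NA_integer_,
             utr3_start = NA_integer_, utr3_end = NA_integer_)
    else
      tibble(length = L, has_orf = TRUE,
             utr5_start = 0L, utr5_end = best_start,
             cds_start = best_start, cds_end = best_end,
             utr3_start = best_end, utr3_end = L)
  }
  bind_rows(map(sequence, one))
}

#' Segment transcripts into 5'UTR / CDS / 3'UTR by longest-ORF search
#'
#' @param models Output of [transcript_models()]; a `sequence` column is
#'   added via [spliced_sequence()] if absent.
#' @param genome Required when `models` lacks a `sequence` column.
#' @return Tibble: `transcript_id`, `gene_id`, `spliced_length`, `has_orf`,
#'   interval columns from [find_longest_orf()], and region lengths
#'   `utr5_len`, `cds_len`, `utr3_len`.
#' @export
segment_transcripts <- function(models, genome = NULL) {
  if (!"sequence" %in% names(models)) {
    if (is.null(genome)) abort("provide `genome` or a `sequence` column")
    models <- spliced_sequence(models, genome)
  }
  seg <- find_longest_orf(models$sequence)
  bind_cols(
    select(models, "transcript_id", "gene_id", "spliced_length"),
    select(seg, -"length")
  ) %>%
    mutate(
      utr5_len = if_else(.data$has_orf, .data$utr5_end - .data$utr5_start, NA_integer_),
      cds_len  = if_else(.data$has_orf, .data$cds_end - .data$cds_start, NA_integer_),
      utr3_len = if_else(.data$has_orf, .data$utr3_end - .data$utr3_start, NA_integer_)
    )
}

#' Read exon records from a GTF/GFF file
#'
#' @param path GTF path; only `exon` features are kept. 1-based closed GTF
#'   coordinates are converted to the package's 0-based half-open convention.
#' @return Exon tibble suitable for [transcript_models()].
#' @export
read_exons_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id
  )
}

#' Write transcript models as a GTF file
#' @param models Output of [transcript_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(models, path) {
  rows <- models %>%
    select("transcript_id", "gene_id", "chrom", "strand", "exons") %>%
    unnest("exons") %>%
    arrange(.data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\ttrapte\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    rows$chrom, rows$start + 1L, rows$end, rows$strand, rows$gene_id, rows$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write UTR/CDS segmentations as BED (0-based half-open)
#'
#' Emits one line per region in transcript coordinates with columns
#' transcript, start, end, region name. Transcripts without an ORF are
#' skipped.
#' @param segmentation Output of [segment_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(segmentation, path) {
  seg <- filter(segmentation, .data$has_orf)
  long <- bind_rows(
    tibble(transcript = seg$transcript_id, start = seg$utr5_start, end = seg$utr5_end, name = "utr5"),
    tibble(transcript = seg$transcript_id, start = seg$cds_start, end = seg$cds_end, name = "cds"),
    tibble(transcript = seg$transcript_id, start = seg$utr3_start, end = seg$utr3_end, name = "utr3")
  ) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$transcript, .data$start)
  readr::write_tsv(long, path, col_names = FALSE)
  invisible(path)
}
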