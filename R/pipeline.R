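#' Read a count matrix TSV (first column gene_id)
#' @param path TSV path.
#' @return Count tibble.
#' @export
read_counts_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "gene_id"
  tbl
}

#' Read a sample sheet TSV
#' @param path TSV with header `sample_id`, `genotype`, `assay`, `animal_id`.
#' @return Sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_sample_sheet(sheet)
  sheet
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Executes annotation -> coverage -> differential expression -> translation
#' efficiency -> enrichment on the files of a dataset directory (the layout
#' written by [simulate_dataset()]), writes each stage's table under
#' `output_dir`, and returns a JSON-serialisable manifest (thresholds, seed,
#' row counts, output paths). Reruns with the same inputs and seed are
#' byte-identical.
#'
#' @param input_dir Directory with `rna_counts.tsv`, `trap_counts.tsv`,
#'   `sample_sheet.tsv`, and optionally `transcripts.gtf`, `genome.fasta`,
#'   `coverage_*.bedgraph`, `gene_sets.gmt`.
#' @param output_dir Where stage tables and `manifest.json` are written.
#' @param seed Master seed (per-stage seeds derived from it).
#' @param fc_threshold,p_threshold DE thresholds (defaults 2 and 0.01).
#' @param z_threshold TE Z threshold (default 4).
#' @param n_bins Positional bins (default 100).
#' @param max_resamples Jackknife cap (default 100).
#' @param cpm Library-size scaling before log transform (default TRUE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, seed = 1L,
                         fc_threshold = 2, p_threshold = 0.01, z_threshold = 4,
                         n_bins = 100L, max_resamples = 100L, cpm = TRUE) {
  need <- c("rna_counts.tsv", "trap_counts.tsv", "sample_sheet.tsv")
  for (f in need) {
    if (!file.exists(file.path(input_dir, f)))
      abort(paste0("pipeline input missing: ", f))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  manifest <- list(
    package_version = as.character(utils::packageVersion("trapte")),
    seed = seed,
    thresholds = list(fc = fc_threshold, p = p_threshold, z = z_threshold,
                      coverage_filter = 1, n_bins = n_bins,
                      max_resamples = max_resamples),
    stages = list(), complete = FALSE
  )

  rna <- read_counts_tsv(file.path(input_dir, "rna_counts.tsv"))
  trap <- read_counts_tsv(file.path(input_dir, "trap_counts.tsv"))
  sheet <- read_sample_sheet(file.path(input_dir, "sample_sheet.tsv"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }

  # --- differential expression, both assays -------------------------------
  de_tables <- stage("de", {
    res <- list()
    for (assay in c("RNA", "TRAP")) {
      counts <- if (assay == "RNA") rna else trap
      ss <- filter(sheet, .data$assay == !!assay,
                   .data$sample_id %in% names(counts))
      fit <- moderated_de(counts, ss, cpm = cpm,
                          fc_threshold = fc_threshold, p_threshold = p_threshold)
      tab <- tidy(fit)
      readr::write_tsv(tab, out(sprintf("de_%s.tsv", tolower(assay))))
      res[[assay]] <- tab
    }
    res
  })
  de_classes <- classify_de(de_tables$RNA, fc_threshold, p_threshold)
  readr::write_tsv(de_classes, out("de_rna_classified.tsv"))
  manifest$stages$de <- list(
    n_genes_rna = nrow(de_tables$RNA), n_genes_trap = nrow(de_tables$TRAP),
    n_up = sum(de_classes$direction == "up"),
    n_down = sum(de_classes$direction == "down"),
    outputs = c("de_rna.tsv", "de_trap.tsv", "de_rna_classified.tsv")
  )
  fc_corr <- fc_expression_correlation(de_tables$RNA)
  manifest$stages$de$fc_expression_r <- fc_corr$r
  manifest$stages$de$fc_expression_p <- fc_corr$p

  # --- translation efficiency ---------------------------------------------
  te_fit <- stage("te", te_analysis(rna, trap, sheet,
                                    max_resamples = max_resamples,
                                    seed = derive_seed(seed, "te"),
                                    cpm = cpm, z_threshold = z_threshold))
  te_tab <- tidy(te_fit)
  readr::write_tsv(te_tab, out("te_results.tsv"))
  manifest$stages$te <- c(as.list(glance(te_fit)),
                          list(outputs = "te_results.tsv"))

  # --- coverage stage (optional inputs) -----------------------------------
  gtf <- file.path(input_dir, "transcripts.gtf")
  bedgraphs <- list.files(input_dir, pattern = "^coverage_.*\\.bedgraph$",
                          full.names = TRUE)
  biased <- NULL
  if (file.exists(gtf) && length(bedgraphs)) {
    covres <- stage("coverage", {
      models <- transcript_models(read_exons_gtf(gtf))
      fasta <- file.path(input_dir, "genome.fasta")
      seg <- segment_transcripts(models, genome = fasta)
      readr::write_tsv(seg, out("segmentation.tsv"))
      write_segmentation_bed(seg, out("segmentation.bed"))
      cov <- bind_rows(map(bedgraphs, function(bg) {
        sid <- sub("^coverage_(.*)\\.bedgraph$", "\\1", basename(bg))
        # bedGraphs are written in spliced coordinates keyed by transcript id
        bgt <- read_bedgraph(bg)
        tibble(transcript_id = unique(bgt$chrom)) %>%
          inner_join(select(models, "transcript_id", "spliced_length"),
                     by = "transcript_id") %>%
          mutate(sample_id = sid,
                 depth = map2(.data$transcript_id, .data$spliced_length, function(tid, L) {
                   d <- numeric(L)
                   rows <- filter(bgt, .data$chrom == tid)
                   for (r in seq_len(nrow(rows)))
                     d[(rows$start[r] + 1L):rows$end[r]] <- rows$depth[r]
                   d
                 })) %>%
          select("transcript_id", "sample_id", "spliced_length", "depth")
      }))
      cov <- filter_expressed(cov)
      binned <- bin_profile(cov, n_bins = n_bins)
      readr::write_tsv(binned, out("binned_profiles.tsv"))
      mg <- metagene_summary(binned, sheet)
      readr::write_tsv(mg, out("metagene.tsv"))
      rc <- region_coverage(cov, seg)
      rd <- region_delta(rc, sheet)
      readr::write_tsv(rd, out("region_deltas.tsv"))
      list(seg = seg, deltas = rd, n_transcripts = n_distinct(cov$transcript_id))
    })
    manifest$stages$coverage <- list(
      n_transcripts = covres$n_transcripts,
      n_with_orf = sum(covres$seg$has_orf),
      outputs = c("segmentation.tsv", "segmentation.bed", "binned_profiles.tsv",
                  "metagene.tsv", "region_deltas.tsv")
    )
    # region deltas are keyed by transcript id; translate to gene ids so the
    # selection can be joined against the gene-level DE table
    tx2gene <- select(covres$seg, "transcript_id", "gene_id")
    deltas_gene <- covres$deltas %>%
      inner_join(tx2gene, by = "transcript_id") %>%
      mutate(transcript_id = .data$gene_id) %>%
      select(-"gene_id")
    down <- filter(de_classes, .data$direction == "down")
    if (any(down$gene_id %in% deltas_gene$transcript_id)) {
      biased <- select_3utr_biased(down, deltas_gene)
      writeLines(biased$transcript_id, out("utr3_biased_transcripts.txt"))
      manifest$stages$coverage$n_utr3_biased <- nrow(biased)
    }
  }

  # --- enrichment (optional GMT) ------------------------------------------
  gmt <- file.path(input_dir, "gene_sets.gmt")
  if (file.exists(gmt)) {
    enr <- stage("enrichment", {
      sets <- read_gmt(gmt)
      universe <- te_tab$gene_id
      down <- filter(de_classes, .data$direction == "down")$gene_id
      increased <- filter(classify_te(te_fit, z_threshold),
                          .data$direction == "increased")$gene_id
      bind_rows(
        enrichment_test(down, sets, universe) %>% mutate(list = "rna_down"),
        enrichment_test(increased, sets, universe) %>% mutate(list = "te_increased"),
        list_overlap_test(down, increased, universe,
                          set_name = "te_increased") %>% mutate(list = "rna_down")
      )
    })
    readr::write_tsv(enr, out("enrichment.tsv"))
    manifest$stages$enrichment <- list(n_tests = nrow(enr), outputs = "enrichment.tsv")
  }

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
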