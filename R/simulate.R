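#' Simulation configuration for the synthetic study
#'
#' Defaults emulate the study design the pipeline targets: 4 vs 4 total-RNA
#' animals and 3 vs 3 TRAP animals, negative-binomial counts with dispersion
#' 0.1 at a median baseline of about 50 counts, and four planted gene
#' groups — `fmrp_like` (total RNA halved, ribosome binding unchanged:
#' RNA log2FC -1, TRAP 0, so true dTE = +1), `top_like` (RNA 0, TRAP +0.5),
#' `down_both` (-1, -1, dTE 0) and `null` genes. Coverage simulation thins
#' reads toward the 3' end of mutant transcripts at `decay_rate`.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_genes Number of genes (default 2000).
#' @param n_rna,n_trap Samples per genotype for each assay.
#' @param proportions Named numeric proportions for `fmrp_like`, `top_like`,
#'   `down_both`, `null`; must sum to 1.
#' @param effects Named list of `c(rna =, trap =)` log2 fold changes per group.
#' @param dispersion NB dispersion (1/size), shared across genes.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean counts (defaults give median 50).
#' @param length_meanlog,length_sdlog Log-normal transcript length
#'   parameters (median about 1500 nt).
#' @param decay_rate Per-100-nt read-survival decrement applied to mutant
#'   coverage, in `[0, 1)`.
#' @param read_length Simulated read length (nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L,
                       n_rna = c(control = 4L, mutant = 4L),
                       n_trap = c(control = 3L, mutant = 3L),
                       proportions = c(fmrp_like = 0.10, top_like = 0.10,
                                       down_both = 0.05, null = 0.75),
                       effects = list(fmrp_like = c(rna = -1, trap = 0),
                                      top_like = c(rna = 0, trap = 0.5),
                                      down_both = c(rna = -1, trap = -1),
                                      null = c(rna = 0, trap = 0)),
                       dispersion = 0.1,
                       baseline_meanlog = log(50), baseline_sdlog = 1,
                       length_meanlog = log(1500), length_sdlog = 0.35,
                       decay_rate = 0.2, read_length = 75L) {
  if (abs(sum(proportions) - 1) > 1e-8) abort("group proportions must sum to 1")
  if (dispersion <= 0) abort("dispersion must be positive")
  if (any(c(n_rna, n_trap) < 2L)) abort("need >= 2 samples per group")
  if (decay_rate < 0 || decay_rate >= 1) abort("decay_rate must be in [0, 1)")
  structure(list(seed = seed, n_genes = n_genes, n_rna = n_rna, n_trap = n_trap,
                 proportions = proportions, effects = effects,
                 dispersion = dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 decay_rate = decay_rate, read_length = read_length),
            class = "sim_config")
}

#' Largest-remainder rounding of proportions to integer group sizes
#' @noRd
round_sizes <- function(proportions, total) {
  raw <- proportions * total
  sizes <- floor(raw)
  rem <- total - sum(sizes)
  if (rem > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

#' Simulate the per-gene ground truth table
#'
#' @param config A [sim_config()].
#' @return Tibble `gene_id`, `group`, `true_fc_rna`, `true_fc_trap`,
#'   `true_delta_te`, `baseline_mean`; deterministic given the config seed.
#' @export
simulate_gene_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- round_sizes(config$proportions, config$n_genes)
  groups <- rep(names(config$proportions), sizes)
  withr::with_seed(derive_seed(config$seed, "truth"), {
    groups <- sample(groups)
    baseline <- rlnorm(config$n_genes, config$baseline_meanlog, config$baseline_sdlog)
  })
  eff <- config$effects
  tibble(
    gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
    group = groups,
    true_fc_rna = map_dbl(groups, ~ eff[[.x]][["rna"]]),
    true_fc_trap = map_dbl(groups, ~ eff[[.x]][["trap"]]),
    baseline_mean = baseline
  ) %>%
    mutate(true_delta_te = .data$true_fc_trap - .data$true_fc_rna)
}

#' @noRd
nb_group <- function(mu, n, size) {
  matrix(rnbinom(length(mu) * n, mu = rep(mu, n), size = size), ncol = n)
}

#' Simulate paired RNA and TRAP count matrices
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(true log2FC of the group in that assay)` for mutant
#' samples and `baseline` for controls, with the configured shared
#' dispersion.
#'
#' @param truth Output of [simulate_gene_truth()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return List `rna`, `trap` (count tibbles) and `sample_sheet`.
#' @export
simulate_count_matrices <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  size <- 1 / config$dispersion
  base <- truth$baseline_mean
  if (any(base <= 0)) abort("non-positive baseline mean")
  sheet <- bind_rows(
    tibble(sample_id = sprintf("rna_ctl_%d", seq_len(config$n_rna[["control"]])),
           genotype = "control", assay = "RNA",
           animal_id = sprintf("R%d", seq_len(config$n_rna[["control"]]))),
    tibble(sample_id = sprintf("rna_mut_%d", seq_len(config$n_rna[["mutant"]])),
           genotype = "mutant", assay = "RNA",
           animal_id = sprintf("R%d", config$n_rna[["control"]] +
                                 seq_len(config$n_rna[["mutant"]]))),
    tibble(sample_id = sprintf("trap_ctl_%d", seq_len(config$n_trap[["control"]])),
           genotype = "control", assay = "TRAP",
           animal_id = sprintf("T%d", seq_len(config$n_trap[["control"]]))),
    tibble(sample_id = sprintf("trap_mut_%d", seq_len(config$n_trap[["mutant"]])),
           genotype = "mutant", assay = "TRAP",
           animal_id = sprintf("T%d", config$n_trap[["control"]] +
                                 seq_len(config$n_trap[["mutant"]])))
  )
  mats <- withr::with_seed(derive_seed(config$seed, "counts"), {
    list(
      rna_ctl = nb_group(base, config$n_rna[["control"]], size),
      rna_mut = nb_group(base * 2^truth$true_fc_rna, config$n_rna[["mutant"]], size),
      trap_ctl = nb_group(base, config$n_trap[["control"]], size),
      trap_mut = nb_group(base * 2^truth$true_fc_trap, config$n_trap[["mutant"]], size)
    )
  })
  rna <- cbind(mats$rna_ctl, mats$rna_mut)
  colnames(rna) <- sheet$sample_id[sheet$assay == "RNA"]
  trap <- cbind(mats$trap_ctl, mats$trap_mut)
  colnames(trap) <- sheet$sample_id[sheet$assay == "TRAP"]
  list(
    rna = bind_cols(tibble(gene_id = truth$gene_id), as_tibble(rna)),
    trap = bind_cols(tibble(gene_id = truth$gene_id), as_tibble(trap)),
    sample_sheet = sheet
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' @noRd
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate one spliced sequence with a planted ORF
#' @noRd
planted_sequence <- function(utr5_len, n_codons, utr3_len) {
  body <- paste(sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L, replace = TRUE),
                collapse = "")
  cds <- paste0("ATG", body, sample(STOP_CODONS, 1L))
  # the 5'UTR is drawn without G so it cannot contain an upstream ATG that
  # would extend the planted reading frame; the 3'UTR is unconstrained (any
  # ORF it hosts is shorter than the planted CDS)
  utr5 <- if (utr5_len > 0)
    paste(sample(c("A", "C", "T"), utr5_len, replace = TRUE), collapse = "") else ""
  utr3 <- if (utr3_len > 0)
    paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE), collapse = "") else ""
  paste0(utr5, cds, utr3)
}

#' Simulate transcript models with planted ORFs
#'
#' Each transcript receives a planted ATG...stop reading frame (about 60% of
#' its length) flanked by UTRs, is split into 1-4 exons separated by random
#' introns, assigned a strand, and placed on its own synthetic chromosome
#' with flanking sequence. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param n_transcripts How many transcripts (defaults to `config$n_genes`).
#' @return List: `models` (with `sequence` column), `genome` (named
#'   character vector of chromosome sequences), and `truth` (planted
#'   `utr5_len`, `cds_len`, `utr3_len` per transcript).
#' @export
simulate_transcripts <- function(config, n_transcripts = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- n_transcripts %||% config$n_genes
  withr::with_seed(derive_seed(config$seed, "transcripts"), {
    lens <- pmin(pmax(round(rlnorm(n, config$length_meanlog, config$length_sdlog)), 300L), 8000L)
    rows <- vector("list", n); chrom_seqs <- character(n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      L <- lens[i]
      n_codons <- max(10L, floor(L * 0.6 / 3))
      cds_len <- 3L * n_codons
      rest <- L - cds_len
      utr5 <- floor(rest * runif(1, 0.2, 0.5))
      utr3 <- rest - utr5
      seq_spliced <- planted_sequence(utr5, n_codons, utr3)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(1:4, 1L)
      # split spliced length into exon pieces
      if (n_ex > 1L) {
        cuts <- sort(sample(seq_len(L - 1L), n_ex - 1L))
        piece <- diff(c(0L, cuts, L))
      } else piece <- L
      introns <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE) else integer(0)
      flank5 <- sample(100:300, 1L); flank3 <- sample(100:300, 1L)
      # sense-strand layout: flank5 | exon1 | intron1 | ... | exonN | flank3
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- flank5
      layout_pieces <- character(2L * n_ex + 1L)
      layout_pieces[1L] <- random_dna(flank5)
      off <- 0L
      for (e in seq_len(n_ex)) {
        starts[e] <- pos; ends[e] <- pos + piece[e]
        layout_pieces[2L * e] <- substring(seq_spliced, off + 1L, off + piece[e])
        off <- off + piece[e]
        pos <- pos + piece[e]
        if (e < n_ex) {
          layout_pieces[2L * e + 1L] <- random_dna(introns[e])
          pos <- pos + introns[e]
        }
      }
      layout_pieces[2L * n_ex + 1L] <- random_dna(flank3)
      chrom_seq <- paste(layout_pieces, collapse = "")
      clen <- nchar(chrom_seq)
      if (strand == "-") {
        chrom_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom_seq)))
        new_starts <- clen - ends; new_ends <- clen - starts
        starts <- rev(new_starts); ends <- rev(new_ends)
      }
      tid <- sprintf("tx%05d", i)
      chrom <- sprintf("chr_%s", tid)
      rows[[i]] <- tibble(chrom = chrom, start = starts, end = ends,
                          strand = strand, transcript_id = tid,
                          gene_id = sprintf("gene%05d", i))
      chrom_seqs[i] <- chrom_seq
      names(chrom_seqs)[i] <- chrom
      truth[[i]] <- tibble(transcript_id = tid, spliced_length = L,
                           utr5_len = utr5, cds_len = cds_len, utr3_len = utr3)
    }
    models <- transcript_models(bind_rows(rows))
    models <- spliced_sequence(models, chrom_seqs)
    list(models = models, genome = chrom_seqs, truth = bind_rows(truth))
  })
}

#' Simulate per-base coverage with 3'-directed read loss
#'
#' Read 5'-start positions are uniform along the transcript; each read
#' survives with probability `(1 - decay_rate)^(d / 100)` where `d` is the
#' distance of its 3'-most base from the transcript 5' end, emulating
#' 3'->5' degradation. Surviving reads increment per-base depth, so
#' coverage stays an integer read-level quantity.
#'
#' @param spliced_length Transcript length (nt).
#' @param n_reads Reads attempted.
#' @param read_length Read length (nt); must not exceed the transcript.
#' @param decay_rate Survival decrement per 100 nt, in `[0, 1)`.
#' @param seed Seed.
#' @return Integer depth vector of length `spliced_length`.
#' @export
simulate_coverage <- function(spliced_length, n_reads, read_length = 75L,
                              decay_rate = 0, seed = 1L) {
  if (read_length > spliced_length) abort("read_length exceeds transcript length")
  if (decay_rate < 0 || decay_rate >= 1) abort("decay_rate must be in [0, 1)")
  if (n_reads < 0) abort("n_reads must be non-negative")
  depth <- integer(spliced_length)
  if (n_reads == 0) return(depth)
  withr::with_seed(seed, {
    starts <- sample.int(spliced_length - read_length + 1L, n_reads, replace = TRUE) - 1L
    ends <- starts + read_length           # half-open; 3'-most base is ends - 1
    keep <- runif(n_reads) < (1 - decay_rate)^((ends - 1L) / 100)
    starts <- starts[keep]; ends <- ends[keep]
  })
  if (!length(starts)) return(depth)
  tab_s <- tabulate(starts + 1L, nbins = spliced_length)
  tab_e <- tabulate(ends + 1L, nbins = spliced_length + 1L)
  as.integer(cumsum(tab_s - tab_e[seq_len(spliced_length)]))
}

#' Simulate a multi-animal coverage experiment
#'
#' Draws per-base coverage for every transcript in every animal of both
#' genotypes; 3' decay (`config$decay_rate`) is applied to mutant animals
#' only, controls are uniform. Read counts target a mean depth of
#' `mean_depth` per transcript.
#'
#' @param models Transcript models (only `spliced_length` is used).
#' @param config A [sim_config()].
#' @param n_animals Animals per genotype (default 4).
#' @param mean_depth Target mean per-base depth (default 10).
#' @return List: `coverage` (coverage tibble across all samples) and
#'   `sample_sheet`.
#' @export
simulate_coverage_experiment <- function(models, config, n_animals = 4L,
                                         mean_depth = 10) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- tibble(
    sample_id = c(sprintf("cov_ctl_%d", seq_len(n_animals)),
                  sprintf("cov_mut_%d", seq_len(n_animals))),
    genotype = rep(c("control", "mutant"), each = n_animals),
    assay = "RNA",
    animal_id = c(sprintf("C%d", seq_len(n_animals)), sprintf("M%d", seq_len(n_animals)))
  )
  base_seed <- derive_seed(config$seed, "coverage")
  rows <- vector("list", nrow(models) * nrow(sheet)); idx <- 1L
  for (s in seq_len(nrow(sheet))) {
    decay <- if (sheet$genotype[s] == "mutant") config$decay_rate else 0
    for (ti in seq_len(nrow(models))) {
      L <- models$spliced_length[ti]
      n_reads <- ceiling(mean_depth * L / config$read_length)
      rows[[idx]] <- tibble(
        transcript_id = models$transcript_id[ti], sample_id = sheet$sample_id[s],
        spliced_length = L,
        depth = list(simulate_coverage(L, n_reads, config$read_length, decay,
                                       seed = (base_seed + 131L * s + 7919L * ti) %% 2147483647L))
      )
      idx <- idx + 1L
    }
  }
  list(coverage = bind_rows(rows), sample_sheet = sheet)
}

#' Write a complete self-consistent synthetic dataset directory
#'
#' Emits everything the pipeline consumes: `transcripts.gtf`,
#' `genome.fasta`, per-sample coverage bedGraphs (spliced coordinates),
#' `rna_counts.tsv`, `trap_counts.tsv`, `sample_sheet.tsv`, `truth.tsv` and
#' `gene_sets.gmt` (the planted `fmrp_like` / `top_like` labels).
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param n_coverage_transcripts Transcripts to include in the coverage
#'   stage (default 50; coverage files grow quickly).
#' @return Invisibly, a list of the written paths.
#' @export
simulate_dataset <- function(dir, config = sim_config(),
                             n_coverage_transcripts = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  truth <- simulate_gene_truth(config)
  cm <- simulate_count_matrices(truth, config)
  tx <- simulate_transcripts(config, n_transcripts = n_coverage_transcripts)
  cov <- simulate_coverage_experiment(tx$models, config)

  readr::write_tsv(cm$rna, p("rna_counts.tsv"))
  readr::write_tsv(cm$trap, p("trap_counts.tsv"))
  readr::write_tsv(bind_rows(cm$sample_sheet, cov$sample_sheet), p("sample_sheet.tsv"))
  readr::write_tsv(truth, p("truth.tsv"))
  write_transcripts_gtf(tx$models, p("transcripts.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$genome), p("genome.fasta"))
  for (sid in unique(cov$coverage$sample_id)) {
    write_bedgraph(filter(cov$coverage, .data$sample_id == sid),
                   p(sprintf("coverage_%s.bedgraph", sid)))
  }
  write_gmt(list(fmrp_like = truth$gene_id[truth$group == "fmrp_like"],
                 top_like = truth$gene_id[truth$group == "top_like"]),
            p("gene_sets.gmt"))
  invisible(list(dir = dir,
                 files = list.files(dir, full.names = TRUE)))
}
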