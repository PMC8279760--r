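# Independent brute-force oracles used to check the implementation.

# Enumerate every (ATG start, in-frame stop-or-end) span in all three forward
# frames and return the longest (ties: 5'-most start). Mirrors the documented
# contract but by exhaustive enumeration, codon by codon.
orf_oracle <- function(seq) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (start in 0:(L - 3)) {
    if (substring(seq, start + 1, start + 3) != "ATG") next
    end <- NA
    pos <- start
    while (pos + 3 <= L) {
      cd <- substring(seq, pos + 1, pos + 3)
      if (pos > start && cd %in% stops) { end <- pos + 3; break }
      pos <- pos + 3
    }
    if (is.na(end)) end <- pos            # last complete codon boundary
    len <- end - start
    if (len >= 3 && (is.null(best) || len > best$len ||
                     (len == best$len && start < best$start)))
      best <- list(start = start, end = end, len = len)
  }
  best
}

# Hypergeometric upper tail by explicit combinatorial sum.
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exhaustive jackknife: sd of delta-TE over every Cartesian single-deletion
# combination, computed directly from the four transformed group matrices.
jackknife_oracle <- function(trap_mut, trap_ctl, rna_mut, rna_ctl) {
  grids <- expand.grid(i = seq_len(ncol(trap_mut)), j = seq_len(ncol(trap_ctl)),
                       k = seq_len(ncol(rna_mut)), l = seq_len(ncol(rna_ctl)))
  vals <- apply(grids, 1L, function(g) {
    tm <- rowMeans(trap_mut[, -g[1], drop = FALSE])
    tc <- rowMeans(trap_ctl[, -g[2], drop = FALSE])
    rm_ <- rowMeans(rna_mut[, -g[3], drop = FALSE])
    rc <- rowMeans(rna_ctl[, -g[4], drop = FALSE])
    (tm - tc) - (rm_ - rc)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  apply(vals, 1L, sd)
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# combined sample to the two groups (no ties assumed).
mw_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  comb <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) # count of x > y pairs
  u_obs <- u_stat(x, y)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2L, function(ii) u_stat(comb[ii], comb[-ii]))
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Random depth vector with mixed smooth and spiky structure.
random_depth <- function(L, seed) {
  withr::with_seed(seed, {
    base <- stats::rpois(L, lambda = stats::runif(1, 0.5, 20))
    spikes <- sample.int(L, size = max(1L, L %/% 50))
    base[spikes] <- base[spikes] + stats::rpois(length(spikes), 100)
    as.numeric(base)
  })
}

# Tiny deterministic count tibbles for TE toys: one gene, fixed group values.
toy_counts <- function(rna_ctl, rna_mut, trap_ctl, trap_mut, n_genes = 1L) {
  mk <- function(vals, prefix) {
    m <- matrix(rep(vals, each = n_genes), nrow = n_genes)
    colnames(m) <- paste0(prefix, seq_along(vals))
    m
  }
  rna <- cbind(mk(rna_ctl, "rc"), mk(rna_mut, "rm"))
  trap <- cbind(mk(trap_ctl, "tc"), mk(trap_mut, "tm"))
  sheet <- tibble::tibble(
    sample_id = c(colnames(rna), colnames(trap)),
    genotype = c(rep(c("control", "mutant"), c(length(rna_ctl), length(rna_mut))),
                 rep(c("control", "mutant"), c(length(trap_ctl), length(trap_mut)))),
    assay = c(rep("RNA", ncol(rna)), rep("TRAP", ncol(trap))),
    animal_id = c(paste0("r", seq_len(ncol(rna))), paste0("t", seq_len(ncol(trap))))
  )
  list(
    rna = dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_len(n_genes))),
                           tibble::as_tibble(rna)),
    trap = dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_len(n_genes))),
                            tibble::as_tibble(trap)),
    sheet = sheet
  )
}
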