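# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: exhaustive scans via Biostrings primitives,
# plain-R dynamic programming, and direct-definition statistics.

# Exhaustive seed-constrained Hamming scan: for every read, every start
# position on every entry and both strands is examined; placements whose
# first seed_len bases mismatch, or whose total mismatches exceed max_mm,
# or which do not fit inside a single entry, are discarded. Returns the
# per-read optimum and the number of surviving placements.
oracle_align <- function(sequences, reads, seed_len = 20, max_mm = 3) {
  spacer <- strrep("N", max(nchar(reads)))
  concat <- paste(sequences, collapse = spacer)
  subj <- Biostrings::DNAString(concat)
  ent_start <- cumsum(c(0, utils::head(nchar(sequences), -1) +
                          nchar(spacer)))
  ent_len <- nchar(sequences)
  out_mm <- rep(NA_integer_, length(reads))
  out_n <- integer(length(reads))
  for (i in seq_along(reads)) {
    rl <- nchar(reads[i])
    if (rl < seed_len) next
    starts_all <- seq_len(nchar(concat) - rl + 1)
    best <- NA_integer_; n <- 0L
    for (strand in 1:2) {
      s <- if (strand == 1) reads[i] else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(reads[i])))
      seed <- substr(s, 1, seed_len)
      if (grepl("N", seed)) next
      hit <- Biostrings::isMatchingStartingAt(
        Biostrings::DNAString(seed), subj, starting.at = starts_all,
        max.mismatch = 0)
      cand <- starts_all[hit]
      if (!length(cand)) next
      e <- findInterval(cand - 1, ent_start)
      cand <- cand[(cand - 1 + rl) <= (ent_start[e] + ent_len[e])]
      if (!length(cand)) next
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(s), subj,
                                        starting.at = cand,
                                        with.indels = FALSE)
      mm <- mm[mm <= max_mm]
      n <- n + length(mm)
      if (length(mm)) best <- min(c(best, mm), na.rm = TRUE)
    }
    out_mm[i] <- best
    out_n[i] <- n
  }
  data.frame(best_mm = out_mm, n_hits = out_n)
}

# Quadratic Smith-Waterman (score only), affine gaps: gap of length L
# costs gap_open + L * gap_extend; N never matches.
sw_oracle_score <- function(read, ref, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      FF[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      FF[i - 1, j] - gap_extend)
      s <- if (rd[i - 1] == rf[j - 1] &&
               rd[i - 1] %in% c("A", "C", "G", "T")) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Conditional exact test in the Poisson limit, by direct enumeration.
poisson_exact_oracle <- function(k_a, k_b, mu_a, mu_b) {
  S <- k_a + k_b
  prods <- stats::dpois(0:S, mu_a) * stats::dpois(S:0, mu_b)
  pobs <- prods[k_a + 1]
  sum(prods[prods <= pobs * (1 + 1e-10)]) / sum(prods)
}

# Step-up FDR adjustment straight from the definition (quadratic).
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    min(1, min(p[r >= r[i]] * n / r[r >= r[i]]))
  }, 0)
}

# scaled-down family panel so tiny test genomes can hold every family
tiny_families <- function() {
  f <- default_synthetic_families()
  f$consensus_len <- c(300, 1500, 800, 260, 600, 400, 500, 400, 300,
                       500, 400, 300)
  f$mean_truncated_len <- c(NA, 400, 250, NA, NA, NA, NA, NA, NA, NA,
                            NA, NA)
  f
}

# small deterministic synthetic genome shared by several tests
tiny_genome <- function(seed = 11, chrom = 40000, genes = 6,
                        gene_repeat_fraction = 0) {
  make_genome(synthetic_genome_config(
    chrom_lengths = c(chr1 = chrom), families = tiny_families(),
    n_genes = genes, gene_repeat_fraction = gene_repeat_fraction,
    gene_length_meanlog = log(700), seed = seed))
}

# independent point-mutation helper for building diverged panel variants
mutate_test_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

random_reads <- function(n, len = 76) {
  r <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  stats::setNames(r, sprintf("rnd%04d", seq_len(n)))
}
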