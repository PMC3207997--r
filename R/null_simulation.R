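#' Configuration for the uniform-transcription null simulation
#'
#' The null model of random background transcription: fixed-length reads
#' drawn uniformly at random over all valid start positions of the repeat
#' (or coding) sequence database, then aligned and counted exactly like
#' observed reads. 100 datasets is the standard replication; desk-scale
#' read numbers default to 50,000 per dataset (full-scale values can be
#' configured).
#'
#' @param n_datasets number of simulated datasets (default 100).
#' @param reads_per_dataset reads per dataset (default 50,000).
#' @param read_len read length (default 76).
#' @param source \code{"repeats"} or \code{"ccds"} — which sequence space
#'   reads are drawn from.
#' @param seed optional integer seed; dataset i uses subseed
#'   \code{seed + i - 1} so datasets are independent and individually
#'   reproducible.
#' @return list of class \code{null_config}.
#' @export
null_config <- function(n_datasets = 100, reads_per_dataset = 50000,
                        read_len = 76, source = c("repeats", "ccds"),
                        seed = NULL) {
  source <- match.arg(source)
  stopifnot(n_datasets >= 1, reads_per_dataset >= 1, read_len >= 1)
  structure(list(n_datasets = as.integer(n_datasets),
                 reads_per_dataset = as.integer(reads_per_dataset),
                 read_len = as.integer(read_len), source = source,
                 seed = seed),
            class = "null_config")
}

db_sequences <- function(db) {
  if (inherits(db, "repeat_db")) db$sequences
  else if (inherits(db, "coding_db")) unname(db$sequences)
  else unname(as_genome_vector(db))
}

db_ids <- function(db) {
  if (inherits(db, "repeat_db")) db$entries$entry_id
  else if (inherits(db, "coding_db")) names(db$sequences)
  else names(as_genome_vector(db))
}

#' Valid start positions and family start-shares
#'
#' An entry of length L has \code{max(L - read_len + 1, 0)} valid read
#' start positions. A family's start-share — its fraction of all valid
#' start positions in the database — is the expected origin frequency of
#' its reads under the uniform null.
#'
#' @param db a \code{repeat_db} (family shares) or any sequence database
#'   (entry shares only).
#' @param read_len read length (default 76).
#' @return list with \code{valid_starts} (per entry), \code{total} and,
#'   for a \code{repeat_db}, \code{family_shares} (named numeric summing
#'   to 1).
#' @export
start_shares <- function(db, read_len = 76) {
  lens <- nchar(db_sequences(db))
  v <- pmax(lens - read_len + 1, 0)
  out <- list(valid_starts = stats::setNames(v, db_ids(db)), total = sum(v))
  if (inherits(db, "repeat_db")) {
    fam <- tapply(v, db$entries$family, sum)
    shares <- fam / sum(fam)
    out$family_shares <- stats::setNames(as.numeric(shares), names(shares))
  }
  out
}

#' Draw one dataset of uniform random reads
#'
#' Each read is a verbatim \code{read_len}-bp substring of a database entry
#' whose start position is uniform over all valid (entry, offset) pairs;
#' strand is uniform +/- (unstranded libraries); no sequencing errors are
#' introduced. Entries shorter than \code{read_len} contribute no reads.
#'
#' @param db a \code{repeat_db}, \code{coding_db} or named sequence vector.
#' @param n_reads number of reads.
#' @param read_len read length (default 76).
#' @param prefix read id prefix.
#' @return named character vector of read sequences with attribute
#'   \code{origin}: data.frame \code{entry_id, family, offset, strand}
#'   (family NA for non-repeat databases).
#' @export
simulate_uniform_reads <- function(db, n_reads, read_len = 76,
                                   prefix = "sim") {
  seqs <- db_sequences(db)
  ids <- db_ids(db)
  v <- pmax(nchar(seqs) - read_len + 1, 0)
  total <- sum(v)
  if (total == 0)
    stop("no entry is at least read_len (", read_len, ") bp long")
  cum <- cumsum(as.numeric(v))
  pos <- floor(stats::runif(n_reads) * total) + 1  # 1..total uniform
  e <- findInterval(pos - 1, cum) + 1L           # entry index
  off <- as.integer(pos - c(0, cum)[e] - 1)      # 0-based offset
  reads <- substr(seqs[e], off + 1L, off + read_len)
  minus <- stats::runif(n_reads) < 0.5
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  names(reads) <- sprintf("%s%07d", prefix, seq_len(n_reads))
  fam <- if (inherits(db, "repeat_db")) db$entries$family[e]
         else rep(NA_character_, n_reads)
  attr(reads, "origin") <- data.frame(
    entry_id = ids[e], family = fam, offset = off,
    strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
  reads
}

#' Simulated-null family counts
#'
#' Generates \code{cfg$n_datasets} uniform read sets from the source
#' database, aligns each against the repeat index with the same aligner
#' parameters as observed reads, and accumulates family counts. With
#' \code{source = "ccds"}, coding-space reads are still aligned to the
#' repeat database (testing whether uniform coding expression explains the
#' observed repeat counts).
#'
#' @param db source database reads are drawn from (\code{repeat_db} for
#'   repeat-space, \code{coding_db} for coding-space nulls).
#' @param cfg a \code{\link{null_config}}.
#' @param index \code{seed_index} built from the repeat database used for
#'   the observed reads.
#' @param aligner_cfg the \code{\link{aligner_config}} used for observed
#'   reads.
#' @param taxonomy a \code{\link{family_taxonomy}}.
#' @return \code{\link{family_count_matrix}} with one column per dataset,
#'   condition \code{"simulated_repeats"} or \code{"simulated_ccds"}.
#' @export
null_counts <- function(db, cfg, index, aligner_cfg = aligner_config(),
                        taxonomy = family_taxonomy()) {
  stopifnot(inherits(cfg, "null_config"))
  cond <- paste0("simulated_", cfg$source)
  cols <- matrix(0L, nrow = length(taxonomy$families),
                 ncol = cfg$n_datasets,
                 dimnames = list(taxonomy$families,
                                 sprintf("%s%03d", cond, seq_len(cfg$n_datasets))))
  for (i in seq_len(cfg$n_datasets)) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed + i - 1L)
    reads <- simulate_uniform_reads(db, cfg$reads_per_dataset, cfg$read_len,
                                    prefix = sprintf("d%03d_", i))
    tbl <- align_reads(reads, index, aligner_cfg)
    cols[, i] <- count_by_family(tbl, taxonomy)
  }
  family_count_matrix(cols, cond)
}
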