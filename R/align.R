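#' Aligner configuration
#'
#' Parameters of the seed-and-extend aligner: candidate placements must
#' match the first \code{seed_len} read bases exactly (zero mismatches in
#' the seed); the remainder of the read is compared base-by-base (ungapped)
#' and placements with more than \code{max_mismatches} mismatches outside
#' the seed are discarded. One best alignment is kept per read.
#'
#' @param seed_len exact-match seed length at the 5' end of the read
#'   (default 20).
#' @param max_mismatches mismatch cap outside the seed (default 3). N in
#'   read or reference counts as a mismatch.
#' @param read_len reads are trimmed 3'-ward to this length before
#'   alignment (default 76); the 5' end is kept.
#' @param both_strands search the reverse complement as well (default TRUE).
#' @return list of class \code{aligner_config}.
#' @export
aligner_config <- function(seed_len = 20, max_mismatches = 3, read_len = 76,
                           both_strands = TRUE) {
  stopifnot(seed_len >= 1, seed_len <= read_len, max_mismatches >= 0)
  structure(list(seed_len = as.integer(seed_len),
                 max_mismatches = as.integer(max_mismatches),
                 read_len = as.integer(read_len),
                 both_strands = isTRUE(both_strands)),
            class = "aligner_config")
}

#' Build an exact-seed lookup index over a sequence database
#'
#' Indexes every \code{seed_len}-mer of every entry (forward orientation;
#' minus-strand placements are found by seeding the reverse complement of
#' the read). Seeds containing N are not indexed. Entries shorter than
#' \code{seed_len} are unalignable and trigger a warning.
#'
#' @param db a \code{repeat_db}, \code{coding_db}, or named character vector
#'   of sequences (e.g. genome chromosomes).
#' @param seed_len seed length; must match the aligner configuration used
#'   later.
#' @return object of class \code{seed_index} holding the index and entry
#'   metadata.
#' @export
build_seed_index <- function(db, seed_len = 20) {
  if (inherits(db, "repeat_db")) {
    seqs <- db$sequences
    ids <- db$entries$entry_id
    fams <- db$entries$family
  } else if (inherits(db, "coding_db")) {
    seqs <- unname(db$sequences)
    ids <- names(db$sequences)
    fams <- NULL
  } else {
    seqs <- as_genome_vector(db)
    ids <- names(seqs)
    seqs <- unname(seqs)
    fams <- NULL
  }
  if (!length(seqs)) stop("cannot index an empty database")
  ptr <- cpp_build_index(toupper(seqs), as.integer(seed_len))
  st <- cpp_index_stats(ptr)
  if (st$n_short_entries > 0)
    warning(st$n_short_entries, " entr(ies) shorter than seed_len ",
            seed_len, " cannot be aligned to")
  structure(list(ptr = ptr, entry_ids = ids, families = fams,
                 seed_len = as.integer(seed_len),
                 n_positions = st$n_positions,
                 sequences = seqs),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index:", length(x$entry_ids), "entries,",
      format(x$n_positions, big.mark = ","), "indexed seed positions",
      "(seed_len", paste0(x$seed_len, ")\n"))
  invisible(x)
}

#' Number of indexed forward seed positions
#' @param index a \code{seed_index}.
#' @return numeric count of indexed seed start positions.
#' @export
seed_index_size <- function(index) index$n_positions

#' Align a batch of short reads
#'
#' Each read is trimmed to \code{cfg$read_len} (keeping the 5' end) and
#' aligned with the seed-and-extend strategy; at most one best hit is
#' reported per read (ties broken by lowest entry, then + strand before -,
#' then lowest offset — deterministic and stable for family assignment).
#'
#' @param reads a named character vector of read sequences, an unnamed
#'   character vector (ids are generated), or a path to a FASTQ file.
#' @param index a \code{seed_index}.
#' @param cfg an \code{\link{aligner_config}} (its \code{seed_len} must
#'   equal the index's).
#' @param keep_unaligned if TRUE, unaligned reads appear with NA fields.
#' @return data.frame with columns \code{read_id, entry_id, family, offset,
#'   strand, mismatches, n_hits} (one row per aligned read; \code{offset}
#'   is the 0-based start on the entry; \code{n_hits} the number of
#'   placements surviving the mismatch cap). Attribute \code{summary} holds
#'   \code{total}, \code{aligned} and \code{unaligned} counts.
#' @export
align_reads <- function(reads, index, cfg = aligner_config(),
                        keep_unaligned = FALSE) {
  stopifnot(inherits(index, "seed_index"), inherits(cfg, "aligner_config"))
  if (cfg$seed_len != index$seed_len)
    stop("aligner seed_len (", cfg$seed_len, ") differs from index (",
         index$seed_len, ")")
  reads <- as_read_vector(reads)
  seqs <- trim_reads(unname(reads), cfg$read_len)
  if (length(seqs)) {
    hits <- cpp_align(index$ptr, toupper(seqs), cfg$max_mismatches,
                      cfg$both_strands)
  } else {
    hits <- data.frame(entry = integer(), offset = integer(),
                       strand = character(), mismatches = integer(),
                       n_hits = integer(), stringsAsFactors = FALSE)
  }
  tbl <- data.frame(
    read_id = as.character(names(reads)),
    entry_id = ifelse(is.na(hits$entry), NA_character_,
                      index$entry_ids[hits$entry]),
    family = if (is.null(index$families))
      rep(NA_character_, length(reads)) else
      ifelse(is.na(hits$entry), NA_character_, index$families[hits$entry]),
    offset = hits$offset,
    strand = hits$strand,
    mismatches = hits$mismatches,
    n_hits = hits$n_hits,
    stringsAsFactors = FALSE)
  aligned <- !is.na(tbl$entry_id)
  out <- if (keep_unaligned) tbl else tbl[aligned, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(total = nrow(tbl), aligned = sum(aligned),
                            unaligned = sum(!aligned))
  out
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read a single read sequence (character scalar).
#' @return one-row data.frame as in \code{\link{align_reads}}, or NULL when
#'   the read does not align.
#' @export
align_read <- function(read, index, cfg = aligner_config()) {
  stopifnot(length(read) == 1)
  res <- align_reads(c(read1 = unname(read)), index, cfg)
  if (nrow(res) == 0) NULL else res
}

#' Genome-unique alignment
#'
#' Aligns reads against a whole-genome index and retains only reads with
#' exactly one surviving placement (seed-exact, within the mismatch cap)
#' across the entire genome, counting placements on both strands.
#'
#' @param reads as in \code{\link{align_reads}}.
#' @param genome_index a \code{seed_index} built over genome chromosomes.
#' @param cfg an \code{\link{aligner_config}}.
#' @return data.frame of uniquely aligning reads (columns as in
#'   \code{\link{align_reads}}; \code{entry_id} is the chromosome).
#'   Attribute \code{summary} adds a \code{unique} count.
#' @export
align_unique_genome <- function(reads, genome_index, cfg = aligner_config()) {
  tbl <- align_reads(reads, genome_index, cfg)
  s <- attr(tbl, "summary")
  out <- tbl[tbl$n_hits == 1, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(s, unique = nrow(out))
  out
}

#' Read / write FASTQ
#'
#' Thin wrappers around Biostrings FASTQ I/O. Base qualities are ignored by
#' the aligner (its constraints are purely sequence-based); written files
#' carry a constant placeholder quality.
#'
#' @param path FASTQ file path.
#' @return \code{read_fastq}: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fastq
#' @param reads named character vector of read sequences.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

trim_reads <- function(seqs, read_len) {
  substr(seqs, 1L, read_len)
}

as_read_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]*$", reads))
    reads <- read_fastq(reads)
  if (!is.character(reads)) stop("reads must be a character vector or FASTQ path")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  if (anyDuplicated(names(reads)))
    stop("duplicate read ids in input")
  reads
}
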