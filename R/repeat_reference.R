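#' Parse repeat annotations from BED6 or RepeatMasker .out
#'
#' Reads repeat annotations and maps each record to a taxonomy family.
#' Two formats are auto-detected (or forced with \code{format}):
#' \itemize{
#'   \item BED6: \code{chrom start end name family strand}, 0-based
#'     half-open coordinates, with the repeat class/family string in
#'     column 5 (the score column is repurposed).
#'   \item RepeatMasker \code{.out}: standard 15-column table with 2 header
#'     lines plus a blank line; 1-based inclusive coordinates are converted
#'     to 0-based half-open; strand \code{"C"} becomes \code{"-"}.
#' }
#'
#' @param path annotation file.
#' @param taxonomy a \code{\link{family_taxonomy}} used to collapse repeat
#'   classes into family labels.
#' @param format \code{"auto"}, \code{"bed"} or \code{"rmout"}.
#' @return data.frame with columns \code{chrom, start, end, strand, name,
#'   family} (0-based half-open coordinates).
#' @export
parse_repeat_annotations <- function(path, taxonomy = family_taxonomy(),
                                     format = c("auto", "bed", "rmout")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (is_rmout(lines)) "rmout" else "bed"
  }
  ann <- if (format == "rmout") parse_rmout_lines(lines)
         else parse_bed6_lines(lines)
  ann$family <- assign_family(ann$raw_class, taxonomy)
  ann$raw_class <- NULL
  bad <- ann$start >= ann$end
  if (any(bad))
    stop("malformed annotation (start >= end) at line ",
         ann$line[which(bad)[1]])
  ann$line <- NULL
  rownames(ann) <- NULL
  ann
}

is_rmout <- function(lines) {
  h <- lines[nzchar(lines)][1]
  !is.na(h) && grepl("SW|score", h) && grepl("perc|div", h)
}

parse_bed6_lines <- function(lines) {
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_ok <- vapply(fields, length, 0L) >= 6
  if (any(!n_ok))
    stop("malformed BED line ", keep[which(!n_ok)[1]],
         ": expected at least 6 fields")
  f <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", keep[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  strand <- f(6)
  if (!all(strand %in% c("+", "-")))
    stop("malformed BED line ", keep[which(!strand %in% c("+", "-"))[1]],
         ": strand must be + or -")
  data.frame(chrom = f(1), start = start, end = end, strand = strand,
             name = f(4), raw_class = f(5), line = keep,
             stringsAsFactors = FALSE)
}

parse_rmout_lines <- function(lines) {
  # skip the 2 header lines and the blank separator
  body <- which(nzchar(trimws(lines)))
  body <- body[body > 2]
  if (!length(body)) stop("RepeatMasker file has no data rows")
  fields <- strsplit(trimws(lines[body]), "[ \t]+")
  n_ok <- vapply(fields, length, 0L) >= 11
  if (any(!n_ok))
    stop("malformed RepeatMasker line ", body[which(!n_ok)[1]])
  f <- function(i) vapply(fields, `[[`, "", i)
  begin <- suppressWarnings(as.integer(f(6)))
  end <- suppressWarnings(as.integer(f(7)))
  if (anyNA(begin) || anyNA(end))
    stop("malformed RepeatMasker line ",
         body[which(is.na(begin) | is.na(end))[1]], ": bad coordinates")
  strand <- ifelse(f(9) == "C", "-", f(9))
  data.frame(chrom = f(5), start = begin - 1L, end = end, strand = strand,
             name = f(10), raw_class = f(11), line = body,
             stringsAsFactors = FALSE)
}

#' Build the flank-extended repeat reference database
#'
#' Extracts, for every annotated repeat, the genomic sequence extended by
#' \code{flank_bp} of flanking sequence on each side (clipped at chromosome
#' ends). Flanks let junction-spanning reads align; overlapping annotations
#' yield duplicated sequence by design (no merging). Entries are stored in
#' genome-forward orientation regardless of annotation strand; the aligner
#' searches both strands.
#'
#' @param genome named character vector of chromosome sequences, a
#'   \code{Biostrings::DNAStringSet}, or a path to a genome FASTA.
#' @param annotations data.frame from \code{\link{parse_repeat_annotations}}.
#' @param flank_bp flank width in bp (default 50).
#' @return an object of class \code{repeat_db}: list with \code{entries}
#'   (data.frame: entry_id, family, chrom, start, end, flanked_start,
#'   flanked_end, length), \code{sequences} (character, uppercase),
#'   \code{flank_bp} and \code{total_bp}.
#' @export
build_repeat_db <- function(genome, annotations, flank_bp = 50) {
  genome <- as_genome_vector(genome)
  missing_chr <- setdiff(unique(annotations$chrom), names(genome))
  if (length(missing_chr))
    stop("annotation chromosomes missing from genome: ",
         paste(missing_chr, collapse = ", "))
  chrom_len <- nchar(genome)[annotations$chrom]
  if (any(annotations$end > chrom_len))
    stop("annotation ends beyond chromosome length: ",
         paste(which(annotations$end > chrom_len), collapse = ", "))
  fs <- pmax(0L, annotations$start - as.integer(flank_bp))
  fe <- pmin(as.integer(chrom_len), annotations$end + as.integer(flank_bp))
  seqs <- toupper(substr(genome[annotations$chrom], fs + 1L, fe))
  check_alphabet(seqs, "repeat entry")
  entries <- data.frame(
    entry_id = sprintf("rep%05d", seq_along(fs)),
    family = annotations$family,
    chrom = annotations$chrom,
    start = annotations$start,
    end = annotations$end,
    flanked_start = fs,
    flanked_end = fe,
    length = fe - fs,
    stringsAsFactors = FALSE)
  names(seqs) <- entries$entry_id
  structure(list(entries = entries, sequences = unname(seqs),
                 flank_bp = flank_bp, total_bp = sum(entries$length)),
            class = "repeat_db")
}

#' @export
print.repeat_db <- function(x, ...) {
  cat("repeat_db:", nrow(x$entries), "entries,", x$total_bp, "bp total,",
      "flank", x$flank_bp, "bp\n")
  print(sort(table(x$entries$family), decreasing = TRUE))
  invisible(x)
}

#' Build the coding-sequence database
#'
#' @param source path to a FASTA of coding (CCDS-like) transcript sequences,
#'   or a named character vector of sequences. Records consisting only of N
#'   are dropped with a warning. Entry ids are the first whitespace-delimited
#'   token of each FASTA header.
#' @return object of class \code{coding_db}: list with \code{sequences}
#'   (named uppercase character vector) and \code{total_bp}.
#' @export
build_coding_db <- function(source) {
  seqs <- if (is.character(source) && length(source) == 1 &&
              file.exists(source)) {
    x <- Biostrings::readDNAStringSet(source)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else as_genome_vector(source)
  if (!length(seqs)) stop("coding FASTA contains no records")
  seqs <- toupper(seqs)
  check_alphabet(seqs, "coding sequence")
  only_n <- !grepl("[ACGT]", seqs)
  if (any(only_n)) {
    warning("dropping ", sum(only_n), " all-N coding record(s): ",
            paste(names(seqs)[only_n], collapse = ", "))
    seqs <- seqs[!only_n]
  }
  if (!length(seqs)) stop("no usable coding sequences after filtering")
  structure(list(sequences = seqs, total_bp = sum(nchar(seqs))),
            class = "coding_db")
}

#' @export
print.coding_db <- function(x, ...) {
  cat("coding_db:", length(x$sequences), "sequences,", x$total_bp, "bp\n")
  invisible(x)
}

#' Persist / reload a repeat database
#'
#' The database is written as a FASTA (headers
#' \code{"entry_id|family|chrom:start-end"}, 1-based inclusive coordinates
#' for readability) plus a TSV index carrying the exact 0-based half-open
#' coordinates.
#'
#' @param db a \code{repeat_db}.
#' @param dir output directory (created if needed).
#' @return \code{write_repeat_db} returns the directory invisibly;
#'   \code{read_repeat_db} returns the reconstructed \code{repeat_db}.
#' @export
write_repeat_db <- function(db, dir) {
  stopifnot(inherits(db, "repeat_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- db$entries
  headers <- sprintf("%s|%s|%s:%d-%d", e$entry_id, e$family, e$chrom,
                     e$flanked_start + 1L, e$flanked_end)
  x <- Biostrings::DNAStringSet(db$sequences)
  names(x) <- headers
  Biostrings::writeXStringSet(x, file.path(dir, "repeat_db.fa"))
  idx <- cbind(e, flank_bp = db$flank_bp)
  utils::write.table(idx, file.path(dir, "repeat_db.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_repeat_db
#' @export
read_repeat_db <- function(dir) {
  idx <- utils::read.table(file.path(dir, "repeat_db.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  x <- Biostrings::readDNAStringSet(file.path(dir, "repeat_db.fa"))
  ids <- sub("\\|.*$", "", names(x))
  if (!identical(ids, idx$entry_id))
    stop("repeat_db FASTA and TSV index disagree")
  flank <- idx$flank_bp[1]
  idx$flank_bp <- NULL
  structure(list(entries = idx, sequences = unname(as.character(x)),
                 flank_bp = flank, total_bp = sum(idx$length)),
            class = "repeat_db")
}

# ---- internal helpers ----

as_genome_vector <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- stats::setNames(as.character(genome),
                           sub("\\s.*$", "", names(genome)))
    return(out)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  genome
}

check_alphabet <- function(seqs, what) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(what, " contains ambiguity characters other than N (record ",
         which(bad)[1], "); only A, C, G, T, N are accepted")
  invisible(TRUE)
}

# sequence utilities used across modules
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
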