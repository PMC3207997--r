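#' Family count matrix
#'
#' Container for per-family read counts across samples. Rows are the
#' taxonomy's families in order; columns are samples; each column's sum is
#' the number of aligned reads in that sample. The per-sample
#' \code{condition} distinguishes observed libraries from uniform-null
#' simulations.
#'
#' @param counts integer matrix (families x samples) with dimnames.
#' @param condition character vector, one of \code{"observed"},
#'   \code{"simulated_repeats"}, \code{"simulated_ccds"} per sample.
#' @return object of class \code{family_counts}.
#' @export
family_count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have family rownames and sample colnames")
  if (length(condition) == 1) condition <- rep(condition, ncol(counts))
  if (length(condition) != ncol(counts))
    stop("one condition label per sample required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, condition = condition),
            class = "family_counts")
}

#' @export
print.family_counts <- function(x, ...) {
  cat("family_counts:", nrow(x$counts), "families x", ncol(x$counts),
      "samples (", paste(unique(x$condition), collapse = ", "), ")\n")
  print(utils::head(x$counts, 12))
  invisible(x)
}

#' Count aligned reads per repeat family
#'
#' Accumulates a one-hit-per-read alignment table into family counts (the
#' "consensus element" accumulation: reads aligning anywhere in a family's
#' entries count toward that family). Reads aligning only within a flank
#' still count toward the entry's family.
#'
#' @param alignments alignment table from \code{\link{align_reads}} (must
#'   have at most one row per read and a \code{family} column, or an
#'   \code{entry_id} resolvable through \code{db}).
#' @param taxonomy a \code{\link{family_taxonomy}} fixing the family order.
#' @param db optional \code{repeat_db} used to resolve \code{entry_id} to
#'   family when the table lacks a family column.
#' @return named integer vector over \code{taxonomy$families} (zero for
#'   families with no reads).
#' @export
count_by_family <- function(alignments, taxonomy = family_taxonomy(),
                            db = NULL) {
  if (anyDuplicated(alignments$read_id))
    stop("alignment table must have at most one row per read")
  fam <- alignments$family
  if ((is.null(fam) || all(is.na(fam))) && nrow(alignments) > 0) {
    if (is.null(db)) stop("no family column; supply db to resolve entry_id")
    m <- match(alignments$entry_id, db$entries$entry_id)
    if (anyNA(m))
      stop("alignment references unknown entry_id: ",
           alignments$entry_id[which(is.na(m))[1]])
    fam <- db$entries$family[m]
  }
  fam <- fam[!is.na(fam)]
  unknown <- setdiff(unique(fam), taxonomy$families)
  if (length(unknown))
    stop("alignment families not in taxonomy: ",
         paste(unknown, collapse = ", "))
  tab <- table(factor(fam, levels = taxonomy$families))
  stats::setNames(as.integer(tab), taxonomy$families)
}

#' Pool technical-replicate samples
#'
#' Elementwise sum of count columns belonging to the same biological
#' sample (mate-1/mate-2 files and lanes are treated as technical
#' replicates and pooled before testing).
#'
#' @param fcm a \code{\link{family_count_matrix}}.
#' @param pool_map named character vector mapping sample id (name) to
#'   pooled sample id (value).
#' @return pooled \code{family_counts}; condition labels must agree within
#'   each pool.
#' @export
pool_samples <- function(fcm, pool_map) {
  stopifnot(inherits(fcm, "family_counts"))
  ids <- colnames(fcm$counts)
  if (!all(ids %in% names(pool_map)))
    stop("pool_map missing samples: ",
         paste(setdiff(ids, names(pool_map)), collapse = ", "))
  grp <- factor(pool_map[ids], levels = unique(pool_map[ids]))
  pooled <- vapply(levels(grp),
                   function(g) rowSums(fcm$counts[, grp == g, drop = FALSE]),
                   numeric(nrow(fcm$counts)))
  cond <- vapply(levels(grp), function(g) {
    u <- unique(fcm$condition[grp == g])
    if (length(u) > 1) stop("pool ", g, " mixes conditions")
    u
  }, "")
  family_count_matrix(pooled, cond)
}

#' Per-sample family frequencies
#'
#' Normalizes each sample's counts to frequencies and summarizes each
#' condition by the across-sample pooled mean and standard deviation of the
#' per-sample frequencies (the quantities behind family frequency bar
#' charts with error bars).
#'
#' @param fcm a \code{\link{family_count_matrix}}.
#' @return list with \code{freq} (matrix, columns sum to 1 for samples with
#'   reads), \code{summary} (data.frame: family, condition, mean, sd) and
#'   \code{zero_samples} (ids of samples with no aligned reads, whose
#'   frequencies are NA).
#' @export
family_frequencies <- function(fcm) {
  stopifnot(inherits(fcm, "family_counts"))
  tot <- colSums(fcm$counts)
  freq <- sweep(fcm$counts, 2, ifelse(tot > 0, tot, NA_real_), "/")
  conds <- unique(fcm$condition)
  summ <- do.call(rbind, lapply(conds, function(cc) {
    f <- freq[, fcm$condition == cc & tot > 0, drop = FALSE]
    data.frame(family = rownames(freq), condition = cc,
               mean = rowMeans(f),
               sd = apply(f, 1, stats::sd),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(freq = freq, summary = summ,
       zero_samples = colnames(fcm$counts)[tot == 0])
}

#' Compartment counts for uniquely aligning reads
#'
#' Counts genome-unique reads falling entirely within repeat-masked
#' intronic / intergenic compartments (supplied as disjoint interval sets).
#'
#' @param unique_alignments table from \code{\link{align_unique_genome}}.
#' @param compartments named list of data.frames with columns
#'   \code{chrom, start, end} (0-based half-open); compartments must be
#'   mutually disjoint.
#' @param read_len read length used to form the aligned interval.
#' @param mappable_total denominator for fractions (default: total reads
#'   recorded in the alignment summary).
#' @return data.frame with one row per compartment: \code{compartment,
#'   count, fraction}.
#' @export
compartment_counts <- function(unique_alignments, compartments,
                               read_len = 76, mappable_total = NULL) {
  grl <- lapply(compartments, function(d)
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(d$start + 1L, d$end)))
  if (length(grl) > 1) {
    for (i in seq_along(grl)[-1]) for (j in seq_len(i - 1)) {
      if (length(GenomicRanges::intersect(grl[[i]], grl[[j]])) > 0)
        stop("compartments overlap: ", names(compartments)[j], " and ",
             names(compartments)[i])
    }
  }
  if (is.null(mappable_total)) {
    s <- attr(unique_alignments, "summary")
    mappable_total <- if (is.null(s)) nrow(unique_alignments) else s[["total"]]
  }
  if (nrow(unique_alignments) > 0) {
    reads <- GenomicRanges::GRanges(
      unique_alignments$entry_id,
      IRanges::IRanges(unique_alignments$offset + 1L,
                       unique_alignments$offset + read_len))
    counts <- vapply(grl, function(g)
      sum(IRanges::overlapsAny(reads, g, type = "within")), 0L)
  } else counts <- stats::setNames(rep(0L, length(grl)), names(grl))
  data.frame(compartment = names(compartments), count = as.integer(counts),
             fraction = if (mappable_total > 0) counts / mappable_total
                        else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of mappable reads derived from repeats
#'
#' @param aligned_to_repeats number of reads aligned to the repeat database.
#' @param mappable_total number of mappable reads (denominator; by default
#'   the reads aligning to the genome index, configurable by the caller).
#' @return fraction in [0, 1].
#' @export
repeat_fraction <- function(aligned_to_repeats, mappable_total) {
  if (mappable_total <= 0) stop("mappable_total must be positive")
  f <- aligned_to_repeats / mappable_total
  if (f < 0 || f > 1) stop("fraction outside [0, 1]; check inputs")
  f
}
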