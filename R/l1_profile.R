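#' Local alignment scoring parameters
#'
#' Smith-Waterman scoring used for consensus-panel realignment: match
#' reward, mismatch penalty, and affine gap penalties where a gap of
#' length L costs \code{gap_open + L * gap_extend}. Defaults (+1 / -1 /
#' 2 / 1, minimum score 50 on 76 bp reads) demand a mostly matching read
#' while tolerating a few substitutions and short indels.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0). N never matches.
#' @param gap_open gap opening penalty (>= 0, applied once per gap).
#' @param gap_extend per-base gap extension penalty (> 0).
#' @param min_score minimum local alignment score for a reported hit.
#' @return list of class \code{sw_scoring}.
#' @export
sw_scoring <- function(match = 1, mismatch = -1, gap_open = 2,
                       gap_extend = 1, min_score = 50) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score),
            class = "sw_scoring")
}

#' Local alignment of a read against a consensus panel
#'
#' Smith-Waterman local alignment (full dynamic programming, no heuristics)
#' of the read and its reverse complement against each panel sequence. The
#' best alignment per consensus is kept (ties resolved to the smallest
#' subject start, + strand preferred) and hits below \code{min_score} are
#' dropped.
#'
#' @param read a single read sequence.
#' @param panel named character vector (or \code{DNAStringSet}) of
#'   consensus sequences.
#' @param scoring an \code{\link{sw_scoring}}.
#' @param both_strands also align the reverse complement (default TRUE).
#' @return data.frame \code{consensus_id, start, end, score, strand} with
#'   1-based subject coordinates; zero rows when nothing reaches
#'   \code{min_score}.
#' @export
local_align <- function(read, panel, scoring = sw_scoring(),
                        both_strands = TRUE) {
  panel <- as_genome_vector(panel)
  if (!length(panel)) stop("consensus panel is empty")
  rc <- if (both_strands) revcomp(read) else NULL
  rows <- lapply(seq_along(panel), function(i) {
    fw <- cpp_sw(read, panel[[i]], scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
    best <- c(fw, strand = "+")
    if (both_strands) {
      rv <- cpp_sw(rc, panel[[i]], scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
      better <- rv$score > fw$score ||
        (rv$score == fw$score && fw$score > 0 && !is.na(rv$start) &&
         (is.na(fw$start) || rv$start < fw$start))
      if (better) best <- c(rv, strand = "-")
    }
    data.frame(consensus_id = names(panel)[i], start = best$start,
               end = best$end, score = best$score, strand = best$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$start) & out$score >= scoring$min_score, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 5' start-position profile on a consensus panel
#'
#' Realigns family-assigned reads (typically LINE-1 reads from the repeat
#' database alignment) to a panel of full-length consensus sequences. A
#' read usually hits several similar consensuses, so its position is
#' summarized as the mean 1-based start coordinate over its panel hits;
#' the profile is the histogram of these per-read mean starts. Comparing
#' the observed profile with a uniform-null profile reveals 5' enrichment
#' from promoter-driven full-length copies.
#'
#' @param reads named character vector of read sequences (pre-filtered to
#'   the family of interest by the quantification step).
#' @param panel named character vector of full-length consensus sequences.
#' @param scoring an \code{\link{sw_scoring}}.
#' @param bin_width histogram bin width in bp (default 100).
#' @param condition label stored with the profile
#'   (\code{"observed"}/\code{"simulated"}).
#' @return object of class \code{l1_profile}: list with \code{per_read}
#'   (data.frame read_id, n_hits, mean_start), \code{histogram}
#'   (data.frame bin_start, bin_end, count; 1-based inclusive bins),
#'   \code{n_no_hit}, \code{n_reads}, \code{bin_width}, \code{condition}.
#' @export
start_profile <- function(reads, panel, scoring = sw_scoring(),
                          bin_width = 100, condition = "observed") {
  panel <- as_genome_vector(panel)
  reads <- as_read_vector(reads)
  per <- lapply(seq_along(reads), function(i) {
    hits <- local_align(reads[[i]], panel, scoring)
    if (nrow(hits) == 0) return(NULL)
    data.frame(read_id = names(reads)[i], n_hits = nrow(hits),
               mean_start = mean(hits$start), stringsAsFactors = FALSE)
  })
  per_read <- do.call(rbind, per)
  if (is.null(per_read))
    per_read <- data.frame(read_id = character(), n_hits = integer(),
                           mean_start = numeric(), stringsAsFactors = FALSE)
  max_len <- max(nchar(panel))
  breaks <- seq(1, max_len + bin_width, by = bin_width)
  bin <- findInterval(per_read$mean_start, breaks)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  hist <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_end = pmin(breaks[-1] - 1, max_len),
                     count = counts)
  structure(list(per_read = per_read, histogram = hist,
                 n_no_hit = length(reads) - nrow(per_read),
                 n_reads = length(reads), bin_width = bin_width,
                 condition = condition),
            class = "l1_profile")
}

#' @export
print.l1_profile <- function(x, ...) {
  cat("l1_profile (", x$condition, "): ", nrow(x$per_read), " of ",
      x$n_reads, " reads profiled, bin width ", x$bin_width, " bp\n",
      sep = "")
  invisible(x)
}

#' Side-by-side observed vs simulated start histograms
#'
#' @param observed,simulated \code{l1_profile} objects built with the same
#'   panel and bin width.
#' @return data.frame \code{bin_start, bin_end, observed, simulated}
#'   (counts) plus \code{observed_frac, simulated_frac}.
#' @export
profile_comparison <- function(observed, simulated) {
  stopifnot(inherits(observed, "l1_profile"),
            inherits(simulated, "l1_profile"))
  ho <- observed$histogram; hs <- simulated$histogram
  n <- max(nrow(ho), nrow(hs))
  pad <- function(h) c(h$count, rep(0L, n - nrow(h)))
  bs <- if (nrow(ho) >= nrow(hs)) ho else hs
  data.frame(bin_start = bs$bin_start, bin_end = bs$bin_end,
             observed = pad(ho), simulated = pad(hs),
             observed_frac = pad(ho) / max(1, sum(ho$count)),
             simulated_frac = pad(hs) / max(1, sum(hs$count)))
}
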