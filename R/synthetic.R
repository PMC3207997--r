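#' Synthetic genome configuration
#'
#' Describes a toy genome with planted repeat families: per family a random
#' consensus is generated and copies are planted after per-copy divergence
#' (random substitutions) and 5' truncation (LINE-style: new copies keep a
#' 3' suffix; only a configurable fraction are full length). Family bp
#' budgets are filled until the target repeat fraction of the genome is
#' realized. A set of protein-coding-like genes is planted as well, a
#' fraction of which carry an embedded repeat copy (repeats inside
#' transcripts drive the coding-space null).
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param families data.frame with columns \code{family, consensus_len,
#'   weight, divergence, full_length_fraction, mean_truncated_len} (see
#'   \code{\link{default_synthetic_families}}).
#' @param repeat_fraction target fraction of the genome covered by planted
#'   repeat copies (default 0.45, emulating the roughly half-repetitive
#'   human genome).
#' @param n_genes number of planted genes.
#' @param gene_length_meanlog,gene_length_sdlog log-normal parameters of
#'   gene (transcript) length.
#' @param gene_repeat_fraction fraction of genes carrying an embedded
#'   repeat copy.
#' @param seed optional integer seed.
#' @return list of class \code{synth_genome_config}.
#' @export
synthetic_genome_config <- function(chrom_lengths = c(chr1 = 250000,
                                                      chr2 = 150000),
                                    families = default_synthetic_families(),
                                    repeat_fraction = 0.45,
                                    n_genes = 30,
                                    gene_length_meanlog = log(1500),
                                    gene_length_sdlog = 0.3,
                                    gene_repeat_fraction = 0.1,
                                    seed = NULL) {
  stopifnot(repeat_fraction > 0, repeat_fraction < 1,
            all(families$weight > 0),
            all(families$divergence >= 0 & families$divergence <= 1),
            all(families$full_length_fraction >= 0 &
                families$full_length_fraction <= 1))
  structure(list(chrom_lengths = chrom_lengths, families = families,
                 repeat_fraction = repeat_fraction, n_genes = n_genes,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 gene_repeat_fraction = gene_repeat_fraction, seed = seed),
            class = "synth_genome_config")
}

#' Default synthetic family panel
#'
#' Twelve families with human-like relative abundances and element sizes:
#' short abundant SINEs (Alu-like, MIR), a long autonomous LINE (L1-like,
#' 6 kb, mostly 5'-truncated copies with a 10 percent full-length
#' fraction), an older LINE (L2-like, heavily truncated), LTR/ERV
#' elements, DNA transposons, satellite and a small catch-all family.
#' Weights are shares of the repeat bp budget; divergence is the per-base
#' substitution rate applied to each planted copy.
#'
#' @return data.frame with one row per family.
#' @export
default_synthetic_families <- function() {
  data.frame(
    family = c("Alu_SINE", "L1", "L2", "MIR", "ERV", "LTR", "TcMar",
               "hAT", "DNA", "CR1", "Satellite", "Other"),
    consensus_len = c(300, 6000, 3000, 260, 1200, 500, 800, 600, 400,
                      1500, 1000, 500),
    weight = c(0.28, 0.30, 0.08, 0.05, 0.07, 0.05, 0.04, 0.03, 0.03,
               0.03, 0.03, 0.01),
    divergence = rep(0.05, 12),
    full_length_fraction = c(1, 0.10, 0.05, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    mean_truncated_len = c(NA, 1000, 600, NA, NA, NA, NA, NA, NA, NA,
                           NA, NA),
    stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# 5'-truncated copy length: full length with prob flf, else a minimum core
# of 50 bp plus a geometric number of extra bases (mean mean_trunc - 50),
# capped at the consensus length.
draw_copy_len <- function(L, flf, mean_trunc) {
  if (stats::runif(1) < flf || is.na(mean_trunc)) return(L)
  min(L, 50L + stats::rgeom(1, 1 / max(1, mean_trunc - 50)))
}

#' Generate a synthetic genome with planted repeats and genes
#'
#' See \code{\link{synthetic_genome_config}} for the generative model. The
#' truth table records every planted element so downstream results can be
#' scored against the plant.
#'
#' @param cfg a \code{\link{synthetic_genome_config}}.
#' @return list of class \code{synth_genome}: \code{genome} (named
#'   character), \code{annotations} (repeat BED-like data.frame: chrom,
#'   start, end, strand, name, family; 0-based half-open),
#'   \code{consensus} (named character, one per family), \code{genes}
#'   (data.frame), \code{transcripts} (named character, sense strand),
#'   \code{truth} (every planted element incl. copy length, full-length
#'   flag, divergence), \code{config}.
#' @export
make_genome <- function(cfg = synthetic_genome_config()) {
  stopifnot(inherits(cfg, "synth_genome_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fams <- cfg$families
  total_len <- sum(cfg$chrom_lengths)
  target_bp <- cfg$repeat_fraction * total_len

  consensus <- stats::setNames(
    vapply(fams$consensus_len, random_dna, ""), fams$family)

  # draw copies per family until the family's bp budget is filled; the
  # final copy is forced to the remaining budget so the realized repeat
  # fraction tracks the target closely
  copies <- list()
  for (i in seq_len(nrow(fams))) {
    f <- fams[i, ]
    budget <- target_bp * f$weight
    acc <- 0; k <- 0
    while (acc < budget) {
      # truncating families always get one full-length (active source) copy
      len <- if (k == 0 && f$full_length_fraction > 0 &&
                 f$full_length_fraction < 1) f$consensus_len
             else draw_copy_len(f$consensus_len, f$full_length_fraction,
                                f$mean_truncated_len)
      remaining <- budget - acc
      if (len > remaining && k > 0) {
        len <- max(50L, min(f$consensus_len, as.integer(round(remaining))))
      }
      k <- k + 1
      full <- len == f$consensus_len
      core <- substr(consensus[[f$family]],
                     f$consensus_len - len + 1, f$consensus_len)
      seq <- mutate_seq(core, f$divergence)
      strand <- sample(c("+", "-"), 1)
      copies[[length(copies) + 1]] <- list(
        family = f$family, name = sprintf("%s_c%03d", f$family, k),
        seq = if (strand == "-") revcomp(seq) else seq,
        len = nchar(seq), strand = strand, full_length = full,
        divergence = f$divergence)
      acc <- acc + len
    }
  }

  # genes: random coding-like sequences; a fraction carries an embedded
  # repeat copy at a random internal position
  gene_len <- pmax(300L, as.integer(round(stats::rlnorm(
    cfg$n_genes, cfg$gene_length_meanlog, cfg$gene_length_sdlog))))
  has_rep <- stats::runif(cfg$n_genes) < cfg$gene_repeat_fraction
  genes <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    seq <- random_dna(gene_len[g])
    emb <- NULL
    if (has_rep[g]) {
      fi <- sample.int(nrow(fams), 1, prob = fams$weight)
      f <- fams[fi, ]
      len <- draw_copy_len(f$consensus_len, f$full_length_fraction,
                           f$mean_truncated_len)
      core <- mutate_seq(substr(consensus[[f$family]],
                                f$consensus_len - len + 1,
                                f$consensus_len), f$divergence)
      at <- sample.int(nchar(seq) - 1, 1)  # insert after position 'at'
      seq <- paste0(substr(seq, 1, at), core,
                    substr(seq, at + 1, nchar(seq)))
      emb <- list(family = f$family, offset = at, len = len,
                  full_length = len == f$consensus_len,
                  divergence = f$divergence)
    }
    strand <- sample(c("+", "-"), 1)
    genes[[g]] <- list(gene_id = sprintf("gene%03d", g),
                       transcript = seq,
                       seq = if (strand == "-") revcomp(seq) else seq,
                       len = nchar(seq), strand = strand, embedded = emb)
  }

  elements <- c(
    lapply(copies, function(cp) c(cp, kind = "repeat")),
    lapply(genes, function(gn) list(family = NA_character_,
                                    name = gn$gene_id, seq = gn$seq,
                                    len = gn$len, strand = gn$strand,
                                    full_length = NA, divergence = NA,
                                    kind = "gene", embedded = gn$embedded)))
  elem_bp <- sum(vapply(elements, function(e) e$len, 0))
  if (elem_bp >= total_len)
    stop("planted elements (", elem_bp, " bp) exceed genome capacity (",
         total_len, " bp)")

  # distribute elements over chromosomes proportionally to length, then
  # interleave with random background gaps
  elements <- elements[sample.int(length(elements))]
  chrom_target <- elem_bp * cfg$chrom_lengths / total_len
  assignment <- integer(length(elements))
  acc <- numeric(length(cfg$chrom_lengths)); ci <- 1
  for (i in seq_along(elements)) {
    while (ci < length(cfg$chrom_lengths) && acc[ci] >= chrom_target[ci])
      ci <- ci + 1
    assignment[i] <- ci
    acc[ci] <- acc[ci] + elements[[i]]$len
  }
  truth <- list(); genome <- character(0)
  for (c_i in seq_along(cfg$chrom_lengths)) {
    chrom <- names(cfg$chrom_lengths)[c_i]
    el <- elements[assignment == c_i]
    el_bp <- sum(vapply(el, function(e) e$len, 0))
    bg_bp <- cfg$chrom_lengths[[c_i]] - el_bp
    if (bg_bp < 0) stop("chromosome ", chrom, " too small for its elements")
    gaps <- as.vector(stats::rmultinom(1, bg_bp, rep(1, length(el) + 1)))
    parts <- character(2 * length(el) + 1)
    pos <- 0
    for (i in seq_along(el)) {
      parts[2 * i - 1] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      parts[2 * i] <- el[[i]]$seq
      e <- el[[i]]
      truth[[length(truth) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = pos + e$len, strand = e$strand,
        name = e$name, family = e$family, kind = e$kind,
        copy_len = e$len, full_length = e$full_length,
        divergence = e$divergence, stringsAsFactors = FALSE)
      # embedded repeat copy inside a gene gets its own annotation
      if (identical(e$kind, "gene") && !is.null(e$embedded)) {
        emb <- e$embedded
        if (e$strand == "+") {
          rs <- pos + emb$offset
        } else {
          rs <- pos + e$len - emb$offset - emb$len
        }
        truth[[length(truth) + 1]] <- data.frame(
          chrom = chrom, start = rs, end = rs + emb$len,
          strand = e$strand, name = paste0(e$name, "_emb"),
          family = emb$family, kind = "repeat_embedded",
          copy_len = emb$len, full_length = emb$full_length,
          divergence = emb$divergence, stringsAsFactors = FALSE)
      }
      pos <- pos + e$len
    }
    parts[2 * length(el) + 1] <- random_dna(gaps[length(el) + 1])
    genome[chrom] <- paste(parts, collapse = "")
  }
  truth <- do.call(rbind, truth)
  ann <- truth[truth$kind %in% c("repeat", "repeat_embedded"),
               c("chrom", "start", "end", "strand", "name", "family")]
  rownames(ann) <- NULL
  gene_truth <- truth[truth$kind == "gene", , drop = FALSE]
  tx <- stats::setNames(vapply(genes, function(g) g$transcript, ""),
                        vapply(genes, function(g) g$gene_id, ""))
  gene_df <- merge(
    data.frame(gene_id = names(tx), tx_len = nchar(tx),
               has_repeat = has_rep, stringsAsFactors = FALSE),
    gene_truth[, c("name", "chrom", "start", "end", "strand")],
    by.x = "gene_id", by.y = "name")
  structure(list(genome = genome, annotations = ann, consensus = consensus,
                 genes = gene_df, transcripts = tx, truth = truth,
                 config = cfg),
            class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  rep_bp <- sum(x$annotations$end - x$annotations$start)
  cat("synth_genome:", length(x$genome), "chromosome(s),",
      sum(nchar(x$genome)), "bp;", nrow(x$annotations),
      "planted repeat copies (", round(100 * rep_bp / sum(nchar(x$genome)), 1),
      "% of genome);", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Realized repeat fraction of a synthetic genome
#' @param sg a \code{synth_genome}.
#' @return fraction of genome bp covered by planted repeat annotations.
#' @export
realized_repeat_fraction <- function(sg) {
  sum(sg$annotations$end - sg$annotations$start) / sum(nchar(sg$genome))
}

#' Expression configuration for synthetic reads
#'
#' Reads are drawn from a three-component mixture: repeat transcription
#' (family chosen with weight proportional to \code{multiplier x start
#' share}; all multipliers 1 reproduces the uniform random-transcription
#' null at the family level), gene transcripts (log-normal expression
#' levels), and uniform background transcription across the genome.
#' Families listed in \code{full_length_only} emit reads only from their
#' full-length copies (promoter-driven expression), while their family
#' weight still uses the whole-family start share.
#'
#' @param n_reads reads per sample (default 20,000).
#' @param read_len read length (default 76).
#' @param error_rate per-base substitution error rate (default 0.005,
#'   Illumina-like).
#' @param repeat_read_fraction expected fraction of reads from the repeat
#'   component (default 0.08, matching repeat-derived shares seen in
#'   poly-A cortex libraries).
#' @param background_fraction fraction of reads from uniform genomic
#'   background (default 0.02).
#' @param family_multipliers named numeric, expression multiplier per
#'   family relative to its genomic start share (default all 1).
#' @param full_length_only families restricted to full-length source
#'   copies (default \code{"L1"}).
#' @param flank_bp repeat transcripts extend this far into flanking
#'   genomic sequence (default 50, matching the reference database flank),
#'   emulating junction-spanning transcription; with all multipliers at 1
#'   the repeat component is then exactly uniform over the flank-extended
#'   repeat sequence space.
#' @param gene_meanlog,gene_sdlog log-normal gene expression parameters.
#' @param seed optional integer seed.
#' @return list of class \code{expression_config}.
#' @export
expression_config <- function(n_reads = 20000, read_len = 76,
                              error_rate = 0.005,
                              repeat_read_fraction = 0.08,
                              background_fraction = 0.02,
                              family_multipliers = NULL,
                              full_length_only = "L1",
                              flank_bp = 50,
                              gene_meanlog = 0, gene_sdlog = 1,
                              seed = NULL) {
  stopifnot(n_reads >= 1, error_rate >= 0, error_rate < 1,
            repeat_read_fraction >= 0, background_fraction >= 0,
            repeat_read_fraction + background_fraction <= 1)
  if (!is.null(family_multipliers) && any(family_multipliers <= 0))
    stop("family multipliers must be positive")
  structure(list(n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len), error_rate = error_rate,
                 repeat_read_fraction = repeat_read_fraction,
                 background_fraction = background_fraction,
                 family_multipliers = family_multipliers,
                 full_length_only = full_length_only,
                 flank_bp = as.integer(flank_bp),
                 gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
                 seed = seed),
            class = "expression_config")
}

add_read_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Generate synthetic sequencing reads
#'
#' Draws one sample's reads from the mixture described in
#' \code{\link{expression_config}}. Mates of a pair are treated as
#' independent draws from the same law, so a paired run is simply two
#' calls with different seeds.
#'
#' @param sg a \code{\link{make_genome}} result.
#' @param expr an \code{\link{expression_config}}.
#' @param sample_id prefix for read ids.
#' @return named character vector of reads with attribute \code{origin}:
#'   data.frame \code{component} (repeat/gene/background), \code{family},
#'   \code{source} (copy name, gene id or chromosome), \code{pos} (0-based
#'   start on the source), \code{strand}.
#' @export
make_reads <- function(sg, expr = expression_config(), sample_id = "s1") {
  stopifnot(inherits(sg, "synth_genome"),
            inherits(expr, "expression_config"))
  if (!is.null(expr$seed)) set.seed(expr$seed)
  rl <- expr$read_len
  ann <- sg$truth[sg$truth$kind %in% c("repeat", "repeat_embedded"), ]
  # repeat transcripts span the flank-extended copy (junction transcription)
  chrom_len <- nchar(sg$genome)
  ann$fstart <- pmax(0L, ann$start - expr$flank_bp)
  ann$fend <- pmin(chrom_len[ann$chrom], ann$end + expr$flank_bp)
  ann$valid <- pmax(ann$fend - ann$fstart - rl + 1, 0)
  fam_share <- tapply(ann$valid, ann$family, sum)
  fam_share <- fam_share / sum(fam_share)
  mult <- stats::setNames(rep(1, length(fam_share)), names(fam_share))
  if (!is.null(expr$family_multipliers)) {
    common <- intersect(names(expr$family_multipliers), names(mult))
    mult[common] <- expr$family_multipliers[common]
  }
  fam_w <- mult * as.numeric(fam_share)
  fam_w <- fam_w / sum(fam_w)

  n <- expr$n_reads
  comp <- sample(c("repeat", "background", "gene"), n, replace = TRUE,
                 prob = c(expr$repeat_read_fraction,
                          expr$background_fraction,
                          max(0, 1 - expr$repeat_read_fraction -
                                expr$background_fraction)))
  origin <- data.frame(component = comp, family = NA_character_,
                       source = NA_character_, pos = NA_integer_,
                       strand = NA_character_, stringsAsFactors = FALSE)
  reads <- character(n)

  # repeat component
  ir <- which(comp == "repeat")
  if (length(ir)) {
    fam_pick <- sample(names(fam_w), length(ir), replace = TRUE,
                       prob = fam_w)
    for (f in unique(fam_pick)) {
      rows <- ann[ann$family == f & ann$valid > 0, ]
      if (f %in% expr$full_length_only) {
        fl <- rows[which(rows$full_length), ]
        if (nrow(fl) == 0)
          stop("family ", f, " restricted to full-length copies but ",
               "none are planted")
        rows <- fl
      }
      ii <- ir[fam_pick == f]
      ci <- sample.int(nrow(rows), length(ii), replace = TRUE,
                       prob = rows$valid)
      off <- floor(stats::runif(length(ii)) * rows$valid[ci])
      gs <- rows$fstart[ci] + off
      seg <- substr(sg$genome[rows$chrom[ci]], gs + 1, gs + rl)
      flip <- stats::runif(length(ii)) < 0.5
      seg[flip] <- revcomp(seg[flip])
      reads[ii] <- seg
      origin$family[ii] <- f
      origin$source[ii] <- rows$name[ci]
      origin$pos[ii] <- as.integer(off)
      origin$strand[ii] <- ifelse(flip, "-", "+")
    }
  }

  # background component: uniform over the genome
  ib <- which(comp == "background")
  if (length(ib)) {
    v <- nchar(sg$genome) - rl + 1
    cum <- cumsum(as.numeric(v))
    pos <- floor(stats::runif(length(ib)) * sum(v)) + 1
    ci <- findInterval(pos - 1, cum) + 1L
    off <- as.integer(pos - c(0, cum)[ci] - 1)
    seg <- substr(sg$genome[ci], off + 1, off + rl)
    flip <- stats::runif(length(ib)) < 0.5
    seg[flip] <- revcomp(seg[flip])
    reads[ib] <- seg
    origin$source[ib] <- names(sg$genome)[ci]
    origin$pos[ib] <- off
    origin$strand[ib] <- ifelse(flip, "-", "+")
  }

  # gene component: log-normal expression, length-weighted
  ig <- which(comp == "gene")
  if (length(ig)) {
    tx <- sg$transcripts
    ok <- nchar(tx) >= rl
    tx <- tx[ok]
    level <- stats::rlnorm(length(tx), expr$gene_meanlog, expr$gene_sdlog)
    w <- level * (nchar(tx) - rl + 1)
    gi <- sample.int(length(tx), length(ig), replace = TRUE, prob = w)
    off <- floor(stats::runif(length(ig)) * (nchar(tx)[gi] - rl + 1))
    seg <- substr(tx[gi], off + 1, off + rl)
    flip <- stats::runif(length(ig)) < 0.5
    seg[flip] <- revcomp(seg[flip])
    reads[ig] <- seg
    origin$source[ig] <- names(tx)[gi]
    origin$pos[ig] <- as.integer(off)
    origin$strand[ig] <- ifelse(flip, "-", "+")
  }

  reads <- add_read_errors(reads, expr$error_rate)
  names(reads) <- sprintf("%s_r%06d", sample_id, seq_len(n))
  attr(reads, "origin") <- origin
  reads
}
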