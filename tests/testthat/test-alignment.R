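make_test_db <- function(seed = 8, chrom = 30000) {
  sg <- tiny_genome(seed = seed, chrom = chrom, genes = 4)
  db <- build_repeat_db(sg$genome, sg$annotations)
  list(sg = sg, db = db, idx = build_seed_index(db))
}

test_that("index counts seed positions and warns on short entries", {
  idx <- build_seed_index(c(e1 = strrep("ACGT", 25)), seed_len = 20)
  expect_equal(seed_index_size(idx), 81)  # 100 - 20 + 1
  expect_warning(build_seed_index(c(e1 = strrep("A", 19)), seed_len = 20),
                 "shorter than seed_len")
  # seeds containing N are not indexed
  idx2 <- build_seed_index(
    c(e1 = paste0(strrep("A", 30), "N", strrep("C", 30))), seed_len = 20)
  expect_equal(seed_index_size(idx2), 22)  # 11 valid starts per N-free arm
})

test_that("exact substrings align at their origin with zero mismatches", {
  f <- make_test_db()
  e <- 5
  read <- substr(f$db$sequences[e], 38, 113)
  hit <- align_read(read, f$idx)
  expect_equal(hit$entry_id, f$db$entries$entry_id[e])
  expect_equal(hit$mismatches, 0)
  # note: offset may name a different equally exact placement in a
  # repetitive db, but the hit itself must be perfect
  ref_at <- substr(f$db$sequences[match(hit$entry_id,
                                        f$db$entries$entry_id)],
                   hit$offset + 1, hit$offset + nchar(read))
  expect_equal(if (hit$strand == "+") ref_at else
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref_at))), read)
})

test_that("a mismatch inside the seed kills the alignment", {
  set.seed(30)
  # a unique random entry: no other placement can rescue the read
  db_seq <- c(u1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                         collapse = ""))
  idx <- build_seed_index(db_seq)
  read <- substr(db_seq, 51, 126)
  sub <- function(s, i, b) { substr(s, i, i) <- b; s }
  base10 <- substr(read, 10, 10)
  flip <- setdiff(c("A", "C", "G", "T"), base10)[1]
  expect_null(align_read(sub(read, 10, flip), idx))
  # the same substitution outside the seed is tolerated and counted
  base30 <- substr(read, 30, 30)
  hit <- align_read(sub(read, 30, setdiff(c("A", "C", "G", "T"), base30)[1]),
                    idx)
  expect_equal(hit$mismatches, 1)
  expect_equal(hit$offset, 50)
})

test_that("best-hit mismatch counts match the exhaustive scan oracle", {
  f <- make_test_db(seed = 9, chrom = 20000)
  set.seed(31)
  ec <- expression_config(n_reads = 300, error_rate = 0.02,
                          repeat_read_fraction = 0.7,
                          background_fraction = 0.3, seed = 32)
  reads <- make_reads(f$sg, ec, "t")
  cfg <- aligner_config()
  tbl <- align_reads(reads, f$idx, cfg, keep_unaligned = TRUE)
  orc <- oracle_align(f$db$sequences, toupper(unname(reads)),
                      cfg$seed_len, cfg$max_mismatches)
  expect_equal(tbl$mismatches, orc$best_mm)
  expect_equal(tbl$n_hits, orc$n_hits)
})

test_that("no emitted hit has a mismatch inside its seed", {
  f <- make_test_db(seed = 12, chrom = 15000)
  set.seed(33)
  reads <- make_reads(f$sg, expression_config(
    n_reads = 400, error_rate = 0.03, repeat_read_fraction = 1,
    background_fraction = 0, seed = 34), "t")
  tbl <- align_reads(reads, f$idx)
  seqs <- toupper(reads[tbl$read_id])
  for (i in seq_len(nrow(tbl))) {
    s <- if (tbl$strand[i] == "+") seqs[[i]] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs[[i]])))
    ref <- substr(f$db$sequences[match(tbl$entry_id[i],
                                       f$db$entries$entry_id)],
                  tbl$offset[i] + 1, tbl$offset[i] + 20)
    expect_equal(substr(s, 1, 20), ref)
  }
})

test_that("alignment is deterministic and monotone in the mismatch cap", {
  f <- make_test_db(seed = 13, chrom = 15000)
  set.seed(35)
  reads <- make_reads(f$sg, expression_config(
    n_reads = 500, error_rate = 0.03, seed = 36,
    repeat_read_fraction = 0.8, background_fraction = 0.2), "t")
  t1 <- align_reads(reads, f$idx)
  t2 <- align_reads(reads, f$idx)
  expect_identical(t1, t2)
  n_aligned <- vapply(0:4, function(mm)
    nrow(align_reads(reads, f$idx, aligner_config(max_mismatches = mm))),
    0L)
  expect_true(all(diff(n_aligned) >= 0))
})

test_that("empty and degenerate batches behave", {
  idx <- build_seed_index(c(e = strrep("ACGT", 50)))
  empty <- align_reads(character(0), idx)
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "summary")), c(0L, 0L, 0L))
  # reads shorter than the seed are unalignable
  short <- align_reads(c(r1 = "ACGTACGT"), idx, keep_unaligned = TRUE)
  expect_true(is.na(short$entry_id))
})

test_that("genome-unique mode drops multi-placement reads", {
  set.seed(37)
  unique_part <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                       collapse = "")
  dup <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  genome <- c(chr1 = paste0(unique_part, dup, dup))
  gidx <- build_seed_index(genome)
  reads <- c(uniq = substr(unique_part, 1001, 1076),
             dupl = substr(dup, 100, 175))
  out <- align_unique_genome(reads, gidx)
  expect_equal(out$read_id, "uniq")
  expect_equal(out$n_hits, 1)
  # and the survivor set matches the exhaustive oracle's multiplicity
  orc <- oracle_align(genome, unname(reads))
  expect_equal(orc$n_hits, c(1L, 2L))
})

test_that("fastq round-trip preserves reads", {
  reads <- random_reads(20)
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)
})
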