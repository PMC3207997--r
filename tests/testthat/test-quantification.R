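tax <- family_taxonomy()

test_that("family counts conserve aligned reads and match a group-by", {
  tbl <- data.frame(
    read_id = sprintf("r%02d", 1:15),
    entry_id = "e", offset = 0L, strand = "+", mismatches = 0L,
    n_hits = 1L,
    family = c(rep("Alu_SINE", 10), rep("L1", 5)),
    stringsAsFactors = FALSE)
  cnt <- count_by_family(tbl, tax)
  expect_equal(unname(cnt["Alu_SINE"]), 10L)
  expect_equal(unname(cnt["L1"]), 5L)
  expect_equal(sum(cnt), nrow(tbl))
  expect_equal(names(cnt), tax$families)
  # permutation invariance
  expect_equal(count_by_family(tbl[sample(15), ], tax), cnt)
  # brute-force group-by oracle on a random table
  set.seed(40)
  fam <- sample(tax$families, 200, TRUE)
  tbl2 <- data.frame(read_id = sprintf("q%03d", 1:200), entry_id = "e",
                     offset = 0L, strand = "+", mismatches = 0L,
                     n_hits = 1L, family = fam, stringsAsFactors = FALSE)
  cnt2 <- count_by_family(tbl2, tax)
  for (f in tax$families)
    expect_equal(unname(cnt2[f]), sum(fam == f))
})

test_that("empty alignment table yields an all-zero column", {
  tbl <- data.frame(read_id = character(), entry_id = character(),
                    family = character(), stringsAsFactors = FALSE)
  expect_equal(sum(count_by_family(tbl, tax)), 0L)
})

test_that("duplicate reads in the table are rejected", {
  tbl <- data.frame(read_id = c("r1", "r1"), family = c("L1", "L1"),
                    stringsAsFactors = FALSE)
  expect_error(count_by_family(tbl, tax), "one row per read")
})

test_that("frequencies normalize columns and match direct recomputation", {
  m <- matrix(c(30, 70, 10, 90), nrow = 2,
              dimnames = list(c("Alu_SINE", "L1"), c("s1", "s2")))
  fcm <- family_count_matrix(m, "observed")
  fr <- family_frequencies(fcm)
  expect_equal(unname(fr$freq[, "s1"]), c(0.3, 0.7))
  expect_equal(colSums(fr$freq), c(s1 = 1, s2 = 1))
  # identical columns give zero sd
  m2 <- matrix(rep(c(5, 15), 4), nrow = 2,
               dimnames = list(c("Alu_SINE", "L1"), paste0("s", 1:4)))
  fr2 <- family_frequencies(family_count_matrix(m2, "observed"))
  expect_equal(fr2$summary$sd, c(0, 0))
  # random matrix against direct mean/sd
  set.seed(41)
  m3 <- matrix(rpois(120, 50), nrow = 12,
               dimnames = list(tax$families, paste0("s", 1:10)))
  fr3 <- family_frequencies(family_count_matrix(m3, "observed"))
  direct <- sweep(m3, 2, colSums(m3), "/")
  expect_equal(fr3$summary$mean, unname(rowMeans(direct)))
  expect_equal(fr3$summary$sd, unname(apply(direct, 1, sd)))
})

test_that("pooling sums technical replicates and keeps conditions", {
  m <- matrix(1:8, nrow = 2,
              dimnames = list(c("Alu_SINE", "L1"),
                              c("a_1", "a_2", "b_1", "b_2")))
  fcm <- family_count_matrix(m, "observed")
  pooled <- pool_samples(fcm, c(a_1 = "a", a_2 = "a", b_1 = "b", b_2 = "b"))
  expect_equal(dim(pooled$counts), c(2L, 2L))
  expect_equal(unname(pooled$counts[, "a"]), c(1 + 3, 2 + 4))
  expect_error(
    pool_samples(family_count_matrix(m, c("observed", "observed",
                                          "observed", "simulated_repeats")),
                 c(a_1 = "a", a_2 = "a", b_1 = "b", b_2 = "b")),
    "mixes conditions")
})

test_that("pooled frequencies equal the count-weighted mean of samples", {
  set.seed(42)
  m <- matrix(rpois(36, 80), nrow = 12,
              dimnames = list(tax$families, c("x_1", "x_2", "x_3")))
  fcm <- family_count_matrix(m, "observed")
  pooled <- pool_samples(fcm, c(x_1 = "x", x_2 = "x", x_3 = "x"))
  fr <- family_frequencies(pooled)
  w <- colSums(m) / sum(m)
  per_sample <- sweep(m, 2, colSums(m), "/")
  expect_equal(unname(fr$freq[, "x"]), unname(per_sample %*% w)[, 1])
})

test_that("compartment counts recover planted reads and demand disjointness", {
  set.seed(43)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 12000, TRUE),
                           collapse = ""))
  gidx <- build_seed_index(genome)
  comp <- list(intronic = data.frame(chrom = "chr1", start = 1000,
                                     end = 3000),
               intergenic = data.frame(chrom = "chr1", start = 5000,
                                       end = 8000))
  # plant reads: 3 intronic, 2 intergenic, 1 elsewhere
  starts <- c(1100, 1500, 2500, 5100, 7000, 9000)
  reads <- stats::setNames(
    vapply(starts, function(s) substr(genome, s + 1, s + 76), ""),
    sprintf("p%d", seq_along(starts)))
  ua <- align_unique_genome(reads, gidx)
  cc <- compartment_counts(ua, comp, read_len = 76)
  expect_equal(cc$count[cc$compartment == "intronic"], 3L)
  expect_equal(cc$count[cc$compartment == "intergenic"], 2L)
  expect_true(sum(cc$fraction) <= 1)
  # a read straddling the boundary is not contained
  straddle <- c(s1 = substr(genome, 2990 + 1, 2990 + 76))
  cc2 <- compartment_counts(align_unique_genome(straddle, gidx), comp)
  expect_equal(sum(cc2$count), 0L)
  overlapping <- list(a = data.frame(chrom = "chr1", start = 0, end = 100),
                      b = data.frame(chrom = "chr1", start = 50, end = 150))
  expect_error(compartment_counts(ua, overlapping), "overlap")
})

test_that("repeat fraction is a guarded ratio", {
  expect_equal(repeat_fraction(8, 100), 0.08)
  expect_equal(repeat_fraction(0, 100), 0)
  expect_error(repeat_fraction(5, 0), "positive")
})
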