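test_that("BED6 annotations parse with direct field mapping", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tAluY\tSINE/Alu\t+",
               "chr1\t500\t900\tL1HS\tLINE/L1\t-",
               "chr2\t10\t60\tweird\tUnknown/XYZ\t+"), bed)
  ann <- parse_repeat_annotations(bed)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$family, c("Alu_SINE", "L1", "Other"))
  expect_equal(ann$start, c(100, 500, 10))
  expect_equal(ann$end, c(200, 900, 60))
  expect_equal(ann$strand, c("+", "-", "+"))
})

test_that("RepeatMasker coordinates convert from 1-based inclusive", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    "  463  1.3  0.6  1.7  chr1        101     200 (1000) +  AluY           SINE/Alu            1  100    (0)      1",
    "  300 10.0  0.6  1.7  chr1        301     400  (800) C  MIR3           SINE/MIR          100    1    (0)      2"),
    out)
  ann <- parse_repeat_annotations(out)
  expect_equal(ann$start, c(100, 300))
  expect_equal(ann$end, c(200, 400))
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(ann$family, c("Alu_SINE", "MIR"))
})

test_that("malformed annotation lines are reported by line number", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tAluY\tSINE/Alu\t+",
               "chr1\tnotanumber\t300\tx\ty\t+"), bed)
  expect_error(parse_repeat_annotations(bed), "line 2")
})

test_that("flanks are added and clipped at chromosome bounds", {
  genome <- c(chrA = paste(rep("ACGT", 2500), collapse = ""))  # 10 kb
  ann <- data.frame(chrom = "chrA",
                    start = c(100, 10, 9900),
                    end = c(200, 60, 9995),
                    strand = "+", name = c("a", "b", "c"),
                    family = c("Alu_SINE", "L1", "L2"),
                    stringsAsFactors = FALSE)
  db <- build_repeat_db(genome, ann, flank_bp = 50)
  expect_equal(db$entries$flanked_start, c(50, 0, 9850))
  expect_equal(db$entries$flanked_end, c(250, 110, 10000))
  expect_equal(nchar(db$sequences), db$entries$length)
  expect_equal(db$entries$length, c(200, 110, 150))
  # total_bp is recomputable and reorder-invariant
  expect_equal(db$total_bp, sum(db$entries$length))
  db2 <- build_repeat_db(genome, ann[c(3, 1, 2), ], flank_bp = 50)
  expect_equal(db2$total_bp, db$total_bp)
})

test_that("flanked total bp follows the sum oracle", {
  set.seed(4)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                           collapse = ""))
  ann <- data.frame(chrom = "chrA", start = c(200, 1000, 3000),
                    end = c(320, 1080, 3300), strand = "+",
                    name = c("x", "y", "z"),
                    family = c("Alu_SINE", "L1", "ERV"),
                    stringsAsFactors = FALSE)
  db <- build_repeat_db(genome, ann, flank_bp = 50)
  expect_equal(db$total_bp, (120 + 100) + (80 + 100) + (300 + 100))
})

test_that("overlapping annotations duplicate sequence", {
  genome <- c(chrA = paste(rep("ACGT", 500), collapse = ""))
  ann <- data.frame(chrom = "chrA", start = c(100, 150),
                    end = c(300, 350), strand = "+",
                    name = c("a", "b"), family = c("L1", "L1"),
                    stringsAsFactors = FALSE)
  db <- build_repeat_db(genome, ann, flank_bp = 0)
  distinct <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(ann$start + 1, ann$end))))
  expect_gt(db$total_bp, distinct)
  expect_equal(db$total_bp, 400)
  expect_equal(distinct, 250)
})

test_that("missing chromosomes are reported", {
  genome <- c(chrA = "ACGTACGTAC")
  ann <- data.frame(chrom = "chrZ", start = 1, end = 5, strand = "+",
                    name = "a", family = "L1", stringsAsFactors = FALSE)
  expect_error(build_repeat_db(genome, ann), "chrZ")
})

test_that("repeat db round-trips through FASTA + TSV", {
  sg <- tiny_genome(seed = 3, chrom = 20000, genes = 3)
  db <- build_repeat_db(sg$genome, sg$annotations)
  dir <- tempfile()
  write_repeat_db(db, dir)
  db2 <- read_repeat_db(dir)
  expect_equal(db2$entries, db$entries)
  expect_equal(db2$sequences, db$sequences)
  expect_equal(db2$total_bp, db$total_bp)
  expect_equal(db2$flank_bp, db$flank_bp)
})

test_that("coding db drops all-N records and round-trips", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1 some description", strrep("ACGT", 75),
               ">tx2", strrep("ACGTA", 180),
               ">txN", strrep("N", 60)), fa)
  expect_warning(cdb <- build_coding_db(fa), "all-N")
  expect_equal(names(cdb$sequences), c("tx1", "tx2"))
  expect_equal(cdb$total_bp, 300 + 900)
  # round trip
  fa2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cdb$sequences), fa2)
  cdb2 <- build_coding_db(fa2)
  expect_equal(cdb2$sequences, cdb$sequences)
  expect_error(build_coding_db(tempfile()), ".")
})

test_that("non-N ambiguity codes are rejected at build", {
  genome <- c(chrA = paste0(strrep("ACGT", 50), "R", strrep("ACGT", 50)))
  ann <- data.frame(chrom = "chrA", start = 150, end = 250, strand = "+",
                    name = "a", family = "L1", stringsAsFactors = FALSE)
  expect_error(build_repeat_db(genome, ann), "ambiguity")
})

test_that("taxonomy patterns collapse classes with catch-all", {
  tax <- family_taxonomy()
  expect_equal(assign_family(c("LTR/ERVL-MaLR", "LTR/Gypsy", "DNA/hAT-Charlie",
                               "DNA/TcMar-Tigger", "DNA/MuDR", "LINE/CR1",
                               "Satellite/centr", "banana"), tax),
               c("ERV", "LTR", "hAT", "TcMar", "DNA", "CR1", "Satellite",
                 "Other"))
  expect_error(family_taxonomy(families = c("A", "A")), "unique")
})
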