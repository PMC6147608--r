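write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_fasta folds case, concatenates lines and tokenises names", {
  fa <- write_tmp(c(">chr1", "acgt", "ACGT"), ".fa")
  expect_identical(read_fasta(fa), c(chr1 = "ACGTACGT"))

  fa <- write_tmp(c(">chr1 extra words here", "AC"), ".fa")
  expect_identical(names(read_fasta(fa)), "chr1")

  fa <- write_tmp(c(">chr1", "ACRYacgt"), ".fa")
  expect_warning(g <- read_fasta(fa), "mapped to N")
  expect_identical(unname(g), "ACNNACGT")
})

test_that("read_fasta rejects malformed files and accepts empty records", {
  fa <- write_tmp("ACGT", ".fa")
  expect_error(read_fasta(fa), "line 1")
  fa <- write_tmp(c("ACGT", ">chr1", "AC"), ".fa")
  expect_error(read_fasta(fa), "before any")
  fa <- write_tmp(character(0), ".fa")
  expect_error(read_fasta(fa), "empty")
  # header with no sequence: zero-length chromosome accepted with a warning
  fa <- write_tmp(c(">chr1", "ACGT", ">chr2"), ".fa")
  expect_warning(g <- read_fasta(fa), "zero-length")
  expect_identical(g[["chr2"]], "")
})

test_that("fasta round-trips through write_fasta", {
  g <- rand_genome(c(153, 71))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, fa, width = 60)
  expect_identical(read_fasta(fa), g)
})

test_that("read_bed parses BED6 with placeholder handling", {
  bed <- write_tmp("chr1\t100\t200", ".bed")
  x <- read_bed(bed)
  expect_identical(x$chrom, "chr1")
  expect_identical(x$start, 100L)
  expect_identical(x$end, 200L)
  expect_true(is.na(x$name) && is.na(x$score))
  expect_identical(x$strand, ".")

  bed <- write_tmp(c("chr1\t0\t10\tpk1\t5\t+", "chr2\t5\t6\t.\t.\t-"), ".bed")
  x <- read_bed(bed)
  expect_identical(x$name, c("pk1", NA))
  expect_identical(x$score, c(5, NA))
  expect_identical(x$strand, c("+", "-"))
})

test_that("read_bed rejects malformed rows with the line number", {
  bed <- write_tmp(c("chr1\t1\t10", "chr1\t200\t100"), ".bed")
  expect_error(read_bed(bed), "line 2")
  bed <- write_tmp("chr1\tx\t10", ".bed")
  expect_error(read_bed(bed), "non-integer")
  bed <- write_tmp("chr1\t10", ".bed")
  expect_error(read_bed(bed), "columns")
  bed <- write_tmp("chr1\t1\t2\t3\t4\t5\t6\t7\t8", ".bed")
  expect_error(read_bed(bed, "narrowpeak"), "columns")
})

test_that("narrowPeak columns and the -1 summit sentinel are handled", {
  np <- write_tmp(c(
    "chr1\t100\t400\tpk1\t800\t.\t12.5\t30.1\t25.2\t150",
    "chr1\t500\t700\tpk2\t600\t.\t9.0\t20.0\t15.0\t-1"
  ), ".narrowPeak")
  x <- read_bed(np, "narrowpeak", source = "dll_chip")
  expect_identical(x$summit_offset, c(150L, NA))
  expect_identical(x$signal, c(12.5, 9.0))
  expect_identical(x$source, c("dll_chip", "dll_chip"))
  # summit offset must lie within the peak
  np <- write_tmp("chr1\t100\t200\tpk\t0\t.\t1\t1\t1\t100", ".narrowPeak")
  expect_error(read_bed(np, "narrowpeak"), "summit")
})

test_that("BED6 write/read round-trip is lossless (property, 100 cases)", {
  withr::local_seed(42)
  for (case in 1:100) {
    n <- sample(1:50, 1)
    x <- rand_intervals(n, with_annot = TRUE)
    # scores representable at the writer's 4-decimal precision
    path <- withr::local_tempfile(fileext = ".bed")
    write_bed(x, path)
    y <- read_bed(path)
    expect_identical(y, x)
  }
})

test_that("write_bed handles empty sets and missing scores", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(genomic_interval(character(), integer(), integer()), path)
  expect_identical(readLines(path), character(0))
  write_bed(tibble::tibble(chrom = "chr1", start = 5L, end = 9L,
                           name = "c1", score = NA_real_, strand = "."),
            path)
  expect_identical(readLines(path), "chr1\t5\t9\tc1\t.\t.")
})

test_that("GTF transcripts convert to 0-based half-open and require IDs", {
  gtf <- write_tmp(c(
    "# comment",
    paste("chr1", "src", "transcript", "101", "200", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"),
    paste("chr1", "src", "exon", "101", "150", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t")
  ), ".gtf")
  tx <- read_transcripts(gtf, "gtf_minimal")
  expect_identical(nrow(tx), 1L)  # exon rows are ignored
  expect_identical(tx$start, 100L)
  expect_identical(tx$end, 200L)
  expect_identical(tx$gene_id, "g1")

  gtf <- write_tmp(paste("chr1", "src", "transcript", "1", "50", ".", "+",
                         ".", 'gene_id "g1";', sep = "\t"), ".gtf")
  expect_error(read_transcripts(gtf, "gtf_minimal"), "transcript_id")
})

test_that("duplicate transcript_id errors; BED12 uses first six columns", {
  gtf <- write_tmp(c(
    paste("chr1", "s", "transcript", "1", "50", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "s", "transcript", "60", "90", ".", "-", ".",
          'gene_id "g2"; transcript_id "t1";', sep = "\t")
  ), ".gtf")
  expect_error(read_transcripts(gtf, "gtf_minimal"), "duplicate")

  bed12 <- write_tmp(paste("chr1", "10", "500", "g1|g1.t1", "0", "+",
                           "10", "500", "0", "2", "100,100", "0,390",
                           sep = "\t"), ".bed")
  expect_warning(tx <- read_transcripts(bed12, "bed"), "first six")
  expect_identical(tx$transcript_id, "g1.t1")
  expect_identical(tx$gene_id, "g1")
  expect_identical(tx$end, 500L)
})

test_that("read_pwm parses JASPAR counts into probability columns", {
  jp <- write_tmp(c(">M1 toy", "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]",
                    "T [ 0 0 ]"))
  p <- read_pwm(jp, "jaspar", factor_class = "dll")
  expect_s3_class(p, "pwm")
  expect_identical(p$width, 2L)
  expect_equal(p$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p$matrix[, 2], c(A = 0, C = 1, G = 0, T = 0))
  expect_identical(p$id, "M1")
  expect_identical(p$factor_class, "dll")
})

test_that("read_pwm enforces column sanity and the probability tolerance", {
  jp <- write_tmp(c("A [ 8 0 ]", "C [ 0 0 ]", "G [ 0 0 ]", "T [ 0 0 ]"))
  expect_error(read_pwm(jp, "jaspar"), "zero")
  jp <- write_tmp(c("A [ 8 -1 ]", "C [ 0 8 ]", "G [ 0 0 ]", "T [ 0 0 ]"))
  expect_error(read_pwm(jp, "jaspar"), "non-negative")
  # column sum 0.999999 is within the 1e-6 probability tolerance
  tsv <- write_tmp(c("0.499999\t0.25", "0.5\t0.25", "0\t0.25", "0\t0.25"))
  p <- read_pwm(tsv, "tsv")
  expect_equal(unname(p$matrix[1, 1]), 0.499999)
})

test_that("minimal MEME blocks parse with positions as rows", {
  meme <- write_tmp(c(
    "MEME version 4", "", "ALPHABET= ACGT", "", "MOTIF motif1", "",
    "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 0",
    " 1.0 0.0 0.0 0.0", " 0.0 0.0 0.0 1.0"))
  p <- read_pwm(meme, "meme_minimal")
  expect_identical(p$width, 2L)
  expect_identical(p$id, "motif1")
  expect_equal(unname(p$matrix[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p$matrix[, 2]), c(0, 0, 0, 1))
})

test_that("chromosome-universe mismatches are hard errors naming orphans", {
  x <- genomic_interval(c("chr1", "chrX"), c(0, 5), c(10, 9))
  expect_error(check_chrom_universe(x, c("chr1", "chr2"), "peaks"), "chrX")
  expect_silent(check_chrom_universe(x, c("chr1", "chrX")))
})
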