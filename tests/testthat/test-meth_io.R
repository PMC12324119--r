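test_that("read_bedmethyl parses the standard dialect", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\t.\t30\t+\t30.0\t10\t3",
               "chr1\t200\t201\t.\t5\t+\t100.0\t5\t5"), f)
  cs <- read_bedmethyl(f)
  expect_s3_class(cs, "CallSet")
  expect_equal(nrow(cs$calls), 2L)
  rec <- cs$calls[pos == 100]
  expect_equal(rec$n_meth, 3L)
  expect_equal(rec$n_unmeth, 7L)
  expect_equal(rec$level, 30.0)

  # counts reconstructed from (level, depth) alone when meth_col absent
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t101\t.\t10\t+\t30.0\t10", f2)
  cs2 <- read_bedmethyl(f2, dialect = list(level_col = 7, depth_col = 8))
  expect_equal(cs2$calls$n_meth, 3L)
})

test_that("count reconstruction uses round-half-up", {
  f <- withr::local_tempfile(fileext = ".bed")
  # level 25% of depth 10 = 2.5 reads -> rounds up to 3
  writeLines("chr1\t0\t1\t.\t10\t+\t25.0\t10", f)
  cs <- read_bedmethyl(f, dialect = list(level_col = 7, depth_col = 8))
  expect_equal(cs$calls$n_meth, 3L)
  expect_equal(cs$calls$n_unmeth, 7L)
})

test_that("bedmethyl edge cases: empty file, duplicates, non-CpG spans", {
  f <- withr::local_tempfile(fileext = ".bed")
  file.create(f)
  expect_equal(nrow(read_bedmethyl(f)$calls), 0L)

  writeLines(c("chr1\t100\t101\t.\t10\t+\t50\t10\t5",
               "chr1\t100\t101\t.\t10\t+\t60\t10\t6"), f)
  expect_error(read_bedmethyl(f), "duplicate CpG")

  writeLines(c("chr1\t100\t105\t.\t10\t+\t50\t10\t5",
               "chr1\t200\t201\t.\t10\t+\t50\t10\t5"), f)
  expect_warning(cs <- read_bedmethyl(f), "end != start\\+1")
  expect_equal(cs$calls$pos, 200L)

  writeLines(c("chr1\t100\t101\t.\t10\t+\t50\t10\t5",
               "chr1\tnot_a_number\t201\t.\t10\t+\t50\t10\t5"), f)
  expect_error(read_bedmethyl(f), "malformed line 2")
})

test_that("read_bismark_coverage converts to 0-based and recomputes levels", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t101\t101\t30\t3\t7", f)
  cs <- read_bismark_coverage(f, merge_strands = FALSE)
  expect_equal(cs$calls$pos, 100L)
  expect_equal(cs$calls$n_meth, 3L)
  expect_equal(cs$calls$n_unmeth, 7L)

  # printed level off by >0.5 points: warn, counts win
  writeLines("chr1\t101\t101\t45\t3\t7", f)
  expect_warning(cs <- read_bismark_coverage(f, merge_strands = FALSE),
                 "counts win")
  expect_equal(cs$calls$level, 30)

  # zero-depth record survives ingestion flagged, excluded from mC calls
  writeLines("chr1\t101\t101\t0\t0\t0", f)
  cs <- read_bismark_coverage(f, merge_strands = FALSE)
  expect_equal(cs$calls$depth, 0L)
  expect_true(is.na(cs$calls$level))
  expect_equal(nrow(classify_mc(cs)), 0L)
})

test_that("strand merge sums paired records and conserves reads", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t101\t101\t30\t3\t7",    # forward C at 0-based 100
               "chr1\t102\t102\t10\t1\t9"), f) # reverse C at 101
  cs <- read_bismark_coverage(f, merge_strands = TRUE)
  expect_equal(nrow(cs$calls), 1L)
  expect_equal(cs$calls$pos, 100L)
  expect_equal(cs$calls$n_meth, 4L)
  expect_equal(cs$calls$n_unmeth, 16L)
  expect_equal(cs$calls$level, 20.0)

  # reference-guided merge on a CGCG run: pairs are (0,1) and (2,3)
  genome <- Biostrings::DNAStringSet(c(chr1 = "CGCGAAAA"))
  writeLines(c("chr1\t1\t1\t50\t1\t1", "chr1\t2\t2\t50\t2\t2",
               "chr1\t3\t3\t50\t3\t3", "chr1\t4\t4\t50\t4\t4"), f)
  cs <- read_bismark_coverage(f, merge_strands = TRUE, fasta = genome)
  expect_equal(cs$calls$pos, c(0L, 2L))
  expect_equal(cs$calls$depth, c(6L, 14L))

  # conservation: total depth before == after, on a random two-strand file
  set.seed(1)
  fwd <- sort(sample(seq(0, 5000, 2), 50))
  line1 <- function(p1, m, u) {
    lv <- if (m + u > 0) 100 * m / (m + u) else 0
    sprintf("chr1\t%d\t%d\t%.4f\t%d\t%d", p1, p1, lv, m, u)
  }
  lines <- unlist(lapply(fwd, function(p) {
    c(line1(p + 1, sample(0:9, 1), sample(0:9, 1)),
      line1(p + 2, sample(0:9, 1), sample(0:9, 1)))
  }))
  writeLines(lines, f)
  unmerged <- read_bismark_coverage(f, merge_strands = FALSE)
  merged <- read_bismark_coverage(f, merge_strands = TRUE)
  expect_equal(sum(merged$calls$depth), sum(unmerged$calls$depth))
  expect_equal(nrow(merged$calls), 50L)
})

test_that("write_callset round-trips both dialects", {
  cs <- toy_callset(25)
  for (dia in c("bedmethyl", "bismark_cov")) {
    f <- withr::local_tempfile()
    write_callset(cs, f, dia)
    back <- if (dia == "bedmethyl") read_bedmethyl(
      f, dialect = list(level_col = 7, depth_col = 8, meth_col = 9),
      platform_label = cs$platform_label, genome_id = cs$genome_id)
    else read_bismark_coverage(f, merge_strands = FALSE,
                               platform_label = cs$platform_label,
                               genome_id = cs$genome_id)
    expect_equal(back$calls, cs$calls, info = dia)
  }
  # depth-0 site round-trips as a 0/0 record
  cs0 <- callset(data.frame(chrom = "chr1", pos = 5, n_meth = 0,
                            n_unmeth = 0))
  f <- withr::local_tempfile()
  write_callset(cs0, f, "bismark_cov")
  expect_equal(readLines(f), "chr1\t6\t6\t0\t0\t0")
  # empty CallSet -> empty file
  f2 <- withr::local_tempfile()
  write_callset(callset(data.frame(chrom = character(), pos = integer(),
                                   n_meth = integer(),
                                   n_unmeth = integer())), f2, "bedmethyl")
  expect_equal(length(readLines(f2)), 0L)
})

test_that("callset validates its invariants", {
  expect_error(callset(data.frame(chrom = "chr1", pos = -1, n_meth = 1,
                                  n_unmeth = 1)), "negative position")
  expect_error(callset(data.frame(chrom = "chr1", pos = 1, n_meth = -1,
                                  n_unmeth = 1)), "negative read count")
  cs <- callset(data.frame(chrom = "chr1", pos = c(3, 1),
                           n_meth = c(1, 2), n_unmeth = c(1, 0)))
  expect_equal(cs$calls$pos, c(1L, 3L))  # ordered by (chrom, pos)
  expect_equal(cs$calls$depth, cs$calls$n_meth + cs$calls$n_unmeth)
})
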