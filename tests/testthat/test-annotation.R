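sizes1 <- c(chr1 = 100000L)

test_that("cpg_context geometry: isolated island flanks", {
  cat <- build_cpg_context(gr1("chr1", 10000, 11000), genome_sizes = sizes1)
  shores <- cat$tracks$shore
  expect_equal(IRanges::start(shores) - 1L, c(8000L, 11000L))
  expect_equal(IRanges::end(shores), c(10000L, 13000L))
  shelves <- cat$tracks$shelf
  expect_equal(IRanges::start(shelves) - 1L, c(6000L, 13000L))
  expect_equal(IRanges::end(shelves), c(8000L, 15000L))
  # widths: 2 * 2000 bp of shore and 2 * 2000 bp of shelf per island
  expect_equal(sum(IRanges::width(shores)), 4000)
  expect_equal(sum(IRanges::width(shelves)), 4000)
})

test_that("cpg_context matches the per-base priority oracle", {
  islands0 <- data.frame(start = c(10000, 12000, 30000, 36500),
                         end = c(11000, 12400, 36000, 37000))
  cat <- build_cpg_context(gr1("chr1", islands0$start, islands0$end),
                           genome_sizes = sizes1)
  # the 1 kb gap between islands 3 and 4 must be entirely shore
  gap <- 36000:36499
  expect_true(all(methconcord:::points_in("chr1", gap,
                                          cat$tracks$shore)))
  # probe a stratified sample of positions plus all label borders
  set.seed(11)
  probes <- unique(c(sample(0:99999, 3000),
                     as.vector(outer(c(islands0$start, islands0$end),
                                     -4001:-1999, "+")),
                     0, 99999))
  probes <- probes[probes >= 0 & probes < 100000]
  expect_equal(catalog_label_at(cat, "chr1", probes),
               oracle_cpg_context(probes, islands0))
})

test_that("cpg_context clips islands at chromosome bounds", {
  expect_warning(
    cat <- build_cpg_context(gr1("chr1", c(500, 99000), c(1500, 100500)),
                             genome_sizes = sizes1),
    "clipped")
  expect_equal(IRanges::start(cat$tracks$island)[1L], 501L)
  # left shore truncated at position 0
  expect_equal(IRanges::start(cat$tracks$shore)[1L], 1L)
  # full coverage and disjointness still hold
  tot <- sum(vapply(cat$tracks,
                    function(tr) sum(IRanges::width(tr)), numeric(1)))
  expect_equal(tot, 100000)
})

test_that("gc_density labels every 5-mer tile by 20 * GC count", {
  # exhaustive: all 4^5 tiles concatenated on one chromosome
  tiles <- do.call(expand.grid,
                   rep(list(c("A", "C", "G", "T")), 5))
  tile_seq <- apply(as.matrix(tiles), 1L, paste, collapse = "")
  genome <- Biostrings::DNAStringSet(
    setNames(paste(tile_seq, collapse = ""), "chr1"))
  cat <- build_gc_density(genome)
  gc_count <- vapply(strsplit(tile_seq, ""), function(b)
    sum(b %in% c("C", "G")), integer(1))
  starts0 <- (seq_along(tile_seq) - 1L) * 5L
  got <- catalog_label_at(cat, "chr1", starts0)
  want <- ifelse(gc_count == 0L, NA_character_,
                 as.character(20L * gc_count))
  expect_equal(got, want)
  # all-N tile unlabelled; N counts as non-GC
  g2 <- Biostrings::DNAStringSet(c(chr1 = "NNNNNGCNNNAAAAA"))
  cat2 <- build_gc_density(g2)
  expect_equal(catalog_label_at(cat2, "chr1", c(0L, 5L, 10L)),
               c(NA, "40", NA))
})

test_that("repeat partition resolves overlaps by priority", {
  tandem <- gr1("chr1", 1000, 2000)
  rmsk <- gr1("chr1", c(1500, 3000, 5000), c(2500, 4000, 5800))
  S4Vectors::mcols(rmsk)$repClass <- c("SINE", "LINE", "LTR")
  cat <- build_repeats(tandem, rmsk, sizes1)
  # a base inside both the tandem tract and the SINE is tandem
  expect_equal(catalog_label_at(cat, "chr1", 1700L), "tandem")
  expect_equal(catalog_label_at(cat, "chr1", 2200L), "SINE")
  expect_equal(catalog_label_at(cat, "chr1", 3500L), "LINE")
  # LTR maps to other_repeat
  expect_equal(catalog_label_at(cat, "chr1", 5500L), "other_repeat")
  # per-base oracle on random probes
  set.seed(2)
  probes <- sample(0:99999, 2000)
  want <- oracle_repeats(probes,
                         data.frame(start = 1000, end = 2000),
                         data.frame(start = 3000, end = 4000),
                         data.frame(start = 1500, end = 2500),
                         data.frame(start = 5000, end = 5800))
  expect_equal(catalog_label_at(cat, "chr1", probes), want)
})

test_that("empty repeat input yields a fully non-repetitive genome", {
  cat <- build_repeats(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                       sizes1)
  expect_equal(sum(IRanges::width(cat$tracks$non_repetitive)), 100000)
})

test_that("gene feature set algebra and strand-aware promoters", {
  gtf <- data.table::data.table(
    type = c("gene", "transcript", "exon", "exon", "gene"),
    start0 = c(50000, 50000, 50000, 59000, 70000),
    end0 = c(60000, 60000, 50500, 60000, 75000),
    strand = c("+", "+", "+", "+", "-"))
  gr <- gr1("chr1", gtf$start0, gtf$end0)
  S4Vectors::mcols(gr)$type <- gtf$type
  S4Vectors::mcols(gr)$transcript_id <-
    c(NA, "t1", "t1", "t1", NA)
  GenomicRanges::strand(gr) <- gtf$strand
  cat <- build_gene_features(gr, genome_sizes = sizes1)
  intron <- cat$tracks$intron[1L]
  expect_equal(IRanges::start(intron) - 1L, 50500L)
  expect_equal(IRanges::end(intron), 59000L)
  prom <- cat$tracks$promoter
  # + strand gene: [48000, 50000); - strand gene: [75000, 77000)
  expect_equal(IRanges::start(prom) - 1L, c(48000L, 75000L))
  expect_equal(IRanges::end(prom), c(50000L, 77000L))
  # intergenic is the complement of gene + promoter (no CDS here):
  # brute-force per-base check on probes
  set.seed(3)
  probes <- sample(0:99999, 2000)
  in_gene <- (probes >= 50000 & probes < 60000) |
    (probes >= 70000 & probes < 75000)
  in_prom <- (probes >= 48000 & probes < 50000) |
    (probes >= 75000 & probes < 77000)
  expect_equal(methconcord:::points_in("chr1", probes,
                                       cat$tracks$intergenic),
               !(in_gene | in_prom))
})

test_that("regulatory catalog merges per label and overlays", {
  cat <- build_regulatory(gr1("chr1", c(100, 150), c(200, 400)),
                          gr1("chr1", 180, 300), sizes1)
  expect_equal(length(cat$tracks$open_chromatin), 1L)
  expect_equal(IRanges::width(cat$tracks$open_chromatin), 300L)
  # a base can carry both labels (overlay semantics)
  expect_true(methconcord:::points_in("chr1", 190L,
                                      cat$tracks$open_chromatin))
  expect_true(methconcord:::points_in("chr1", 190L,
                                      cat$tracks$enhancer))
  expect_false(cat$partition)
})

test_that("reference CpG indexing finds forward-strand C positions", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACGTCGA", chr2 = "CGCG"))
  idx <- index_reference_cpgs(genome)
  expect_equal(idx$positions$chr1, c(2L, 5L))
  expect_equal(idx$positions$chr2, c(0L, 2L))
  expect_equal(idx$total, 4L)
})

test_that("partition catalog CpG counts sum to the genome total", {
  genome <- toy_genome(5000)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  cat <- build_cpg_context(gr1("chr1", 1000, 1400), genome_sizes = sizes)
  idx <- index_reference_cpgs(genome, list(cat))
  expect_equal(sum(idx$counts$n_ref_cpg), idx$total)
})

test_that("UCSC readers accept both bin-prefixed and plain layouts", {
  f <- withr::local_tempfile()
  writeLines(c("585\tchr1\t100\t200\tCpG:1\t100\t10\t60\t20\t60\t0.8"), f)
  expect_equal(IRanges::start(read_cpg_islands(f)), 101L)
  writeLines("chr1\t100\t200\tname", f)
  expect_equal(IRanges::start(read_cpg_islands(f)), 101L)
  # rmsk 13-column layout
  writeLines("0\t0\t0\t0\t0\tchr1\t5000\t5800\t0\t+\trep1\tLINE\tL1", f)
  rk <- read_rmsk(f)
  expect_equal(S4Vectors::mcols(rk)$repClass, "LINE")
  expect_equal(IRanges::start(rk) - 1L, 5000L)
})
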