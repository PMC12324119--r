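#' Configuration of the synthetic two-platform methylome
#'
#' The generator states a small, explicit world: a genome with GC-rich CpG
#' islands, low-complexity tandem tracts, AT-rich interspersed elements
#' and stranded multi-exon genes; one shared true methylome with
#' context-dependent Beta-distributed methylation (islands and promoters
#' low, shores intermediate, shelves and gene bodies high); and two
#' observation processes — platform A with unimodal near-symmetric depth
#' peaking around 29x (long-read-like) and platform B with a right-skewed
#' negative-binomial depth concentrated at 4-10x plus site dropout
#' (bisulfite-like). Non-CpG (CHH/CHG) records carry methylation equal to
#' the bisulfite conversion-failure rate (default 2.8%, i.e. ~97.2%
#' conversion efficiency).
#'
#' @param seed Root seed; everything downstream is deterministic given it.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param islands_per_chrom,island_len_range Island count and length range.
#' @param island_gc Island GC fraction (target 0.6, vs 0.4 background).
#' @param tandem_per_chrom,tandem_len_range Tandem-tract count and length.
#' @param line_per_chrom,line_len,sine_per_chrom,sine_len Interspersed
#'   element architecture.
#' @param genes_per_chrom,gene_len_range Gene count and length range.
#' @param reg_per_chrom,reg_len Regulatory intervals per type.
#' @param beta_means Named means of the true methylation Beta distribution
#'   per context label.
#' @param beta_conc Beta concentration (shape1+shape2).
#' @param depth_a_mean,depth_a_sd Platform A depth: discretized
#'   Normal(mean, sd) truncated at 1.
#' @param depth_b_size,depth_b_mu Platform B depth: NegBinomial(size, mu).
#' @param jitter_a,jitter_b Per-platform level jitter (sd, percentage
#'   points on the probability scale).
#' @param offset_b Systematic platform-B level offset in percentage points
#'   (the bisulfite tendency to read slightly higher).
#' @param dropout_b Fraction of CpG sites absent from platform B's calls.
#' @param conversion_failure Bisulfite conversion-failure rate.
#' @param n_chh,n_chg Number of non-CpG context records to emit.
#' @param preset `"default"` or `"paper-like"`; the latter switches on the
#'   +2-point platform-B offset.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 500000L,
                       islands_per_chrom = 8L,
                       island_len_range = c(600L, 1500L),
                       island_gc = 0.60,
                       tandem_per_chrom = 8L,
                       tandem_len_range = c(200L, 600L),
                       line_per_chrom = 6L, line_len = 2000L,
                       sine_per_chrom = 15L, sine_len = 300L,
                       genes_per_chrom = 15L,
                       gene_len_range = c(3000L, 10000L),
                       reg_per_chrom = 10L, reg_len = 500L,
                       beta_means = c(island = 0.10, shore = 0.50,
                                      shelf = 0.85, body = 0.85,
                                      promoter = 0.10, open_sea = 0.80),
                       beta_conc = 10,
                       depth_a_mean = 29, depth_a_sd = 4,
                       depth_b_size = 2, depth_b_mu = 8,
                       jitter_a = 2, jitter_b = 2,
                       offset_b = 0,
                       dropout_b = 0.05,
                       conversion_failure = 0.028,
                       n_chh = 20000L, n_chg = 20000L,
                       preset = c("default", "paper-like")) {
  preset <- match.arg(preset)
  if (preset == "paper-like") {
    offset_b <- 2
    # ~25k CpGs per 600-kb chromosome at the stated composition, i.e.
    # ~50k genome-wide with the default two chromosomes
    if (missing(chrom_len)) chrom_len <- 600000L
  }
  stopifnot(all(beta_means > 0 & beta_means < 1), beta_conc > 0,
            dropout_b >= 0, dropout_b <= 1,
            conversion_failure >= 0, conversion_failure <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "SimConfig")
}

rand_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

tandem_tract <- function(len, motif) {
  substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
}

# scatter features of given widths along [0, chrom_len) without overlap,
# separated by random gaps; returns a data.table(type, start, end)
place_features <- function(widths, types, chrom_len, min_gap = 4500L) {
  stopifnot(length(widths) == length(types))
  ord <- sample(seq_along(widths))
  widths <- widths[ord]; types <- types[ord]
  slack <- chrom_len - sum(widths) - min_gap * (length(widths) + 1L)
  if (slack < 0)
    stop("feature architecture exceeds chromosome length")
  # random extra gap allocation via sorted uniforms
  cuts <- sort(runif(length(widths) + 1L))
  extra <- floor(slack * diff(c(0, cuts)) / max(cuts, 1e-9))
  gaps <- min_gap + extra  # length n+1; the last gap trails the features
  starts <- cumsum(gaps[-length(gaps)]) +
    c(0, cumsum(widths[-length(widths)]))
  data.table::data.table(type = types, start = as.integer(starts),
                         end = as.integer(starts + widths))
}

#' Simulate a reference genome with annotation tables
#'
#' Builds the synthetic chromosomes (GC-rich islands, low-entropy tandem
#' tracts, AT-rich LINE/SINE elements over a 40%-GC background), places
#' stranded multi-exon genes and regulatory intervals, and returns both
#' the in-memory objects and — via [write_sim_genome()] — files that
#' round-trip through the annotation readers.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `SimGenome`: `genome` (`DNAStringSet`),
#'   `genome_sizes`, `islands`, `simple_repeat`, `rmsk` (with `repClass`),
#'   `genes` / `exons` / `cds` (data.tables, 0-based half-open),
#'   `regulatory` (list of two `GRanges`), and the echoed `cfg`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sizes <- setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms)
  motifs <- c("CCG", "CACG", "CA", "TAA")
  seqs <- character(cfg$n_chroms)
  feat_all <- list(); gene_all <- list(); exon_all <- list()
  cds_all <- list(); reg_all <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    widths <- c(
      sample(cfg$island_len_range[1L]:cfg$island_len_range[2L],
             cfg$islands_per_chrom, replace = TRUE),
      sample(cfg$tandem_len_range[1L]:cfg$tandem_len_range[2L],
             cfg$tandem_per_chrom, replace = TRUE),
      rep(cfg$line_len, cfg$line_per_chrom),
      rep(cfg$sine_len, cfg$sine_per_chrom))
    types <- rep(c("island", "tandem", "LINE", "SINE"),
                 c(cfg$islands_per_chrom, cfg$tandem_per_chrom,
                   cfg$line_per_chrom, cfg$sine_per_chrom))
    feats <- place_features(widths, types, cfg$chrom_len)
    feats[, chrom := ch]
    feat_all[[ci]] <- feats
    # assemble the sequence: background between features
    pieces <- character(0)
    cursor <- 0L
    for (fi in seq_len(nrow(feats))) {
      gap <- feats$start[fi] - cursor
      pieces <- c(pieces, rand_dna(gap, 0.40))
      w <- feats$end[fi] - feats$start[fi]
      pieces <- c(pieces, switch(
        feats$type[fi],
        island = rand_dna(w, cfg$island_gc),
        tandem = tandem_tract(w, sample(motifs, 1L)),
        LINE = rand_dna(w, 0.35),
        SINE = rand_dna(w, 0.35)))
      cursor <- feats$end[fi]
    }
    pieces <- c(pieces, rand_dna(cfg$chrom_len - cursor, 0.40))
    seqs[ci] <- paste(pieces, collapse = "")
    # genes: uniform starts away from the edges; random strand; 3 exons
    glen <- sample(cfg$gene_len_range[1L]:cfg$gene_len_range[2L],
                   cfg$genes_per_chrom, replace = TRUE)
    gstart <- sort(sample(3000:(cfg$chrom_len - max(glen) - 3000L),
                          cfg$genes_per_chrom))
    gdt <- data.table::data.table(
      gene_id = sprintf("%s_g%02d", ch, seq_len(cfg$genes_per_chrom)),
      chrom = ch, start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), cfg$genes_per_chrom, replace = TRUE))
    gene_all[[ci]] <- gdt
    ex <- lapply(seq_len(nrow(gdt)), function(g) {
      s <- gdt$start[g]; e <- gdt$end[g]; L <- e - s
      e1 <- round(0.1 * L); i1 <- round(0.45 * L); i2 <- round(0.55 * L)
      data.table::data.table(
        gene_id = gdt$gene_id[g], chrom = ch,
        start = c(s, s + i1, e - e1),
        end = c(s + e1, s + i2, e))
    })
    exon_all[[ci]] <- data.table::rbindlist(ex)
    # CDS: interior 80% of each exon block
    cds_all[[ci]] <- exon_all[[ci]][, .(
      gene_id, chrom,
      start = start + round(0.1 * (end - start)),
      end = end - round(0.1 * (end - start)))]
    # regulatory intervals: uniform placement (overlay; overlap is fine)
    rstart <- sample(0:(cfg$chrom_len - cfg$reg_len), 2L * cfg$reg_per_chrom)
    reg_all[[ci]] <- data.table::data.table(
      type = rep(c("open_chromatin", "enhancer"), each = cfg$reg_per_chrom),
      chrom = ch, start = rstart, end = rstart + cfg$reg_len)
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
  feats <- data.table::rbindlist(feat_all)
  regs <- data.table::rbindlist(reg_all)
  to_gr <- function(dt) gr_from_bed0(dt$chrom, dt$start, dt$end, sizes)
  rmsk_dt <- feats[type %in% c("LINE", "SINE")]
  rmsk <- to_gr(rmsk_dt)
  S4Vectors::mcols(rmsk)$repClass <- rmsk_dt$type
  structure(list(
    genome = genome, genome_sizes = sizes,
    islands = to_gr(feats[type == "island"]),
    simple_repeat = to_gr(feats[type == "tandem"]),
    rmsk = rmsk,
    genes = data.table::rbindlist(gene_all),
    exons = data.table::rbindlist(exon_all),
    cds = data.table::rbindlist(cds_all),
    regulatory = list(
      open_chromatin = to_gr(regs[type == "open_chromatin"]),
      enhancer = to_gr(regs[type == "enhancer"])),
    cfg = cfg), class = "SimGenome")
}

#' Write a simulated genome and its annotation tables to disk
#'
#' Emits files in the layouts the annotation readers consume: a FASTA,
#' UCSC-style cpgIslandExt / simpleRepeat / rmsk table dumps, a GTF of the
#' genes, and regulatory BEDs.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    islands = file.path(dir, "cpgIslandExt.txt"),
    simple_repeat = file.path(dir, "simpleRepeat.txt"),
    rmsk = file.path(dir, "rmsk.txt"),
    gtf = file.path(dir, "genes.gtf"),
    open_chromatin = file.path(dir, "open_chromatin.bed"),
    enhancers = file.path(dir, "enhancers.bed"))
  Biostrings::writeXStringSet(sim$genome, paths$fasta)
  gr0 <- function(gr) data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = IRanges::start(gr) - 1L, end = IRanges::end(gr))
  isl <- gr0(sim$islands)
  data.table::fwrite(data.table::data.table(
    0L, isl$chrom, isl$start, isl$end,
    paste0("CpG:", seq_len(nrow(isl))), isl$end - isl$start,
    0L, 0L, 0, 0, 0), paths$islands, sep = "\t", col.names = FALSE)
  sr <- gr0(sim$simple_repeat)
  data.table::fwrite(data.table::data.table(
    0L, sr$chrom, sr$start, sr$end, 2L,
    (sr$end - sr$start) / 2), paths$simple_repeat,
    sep = "\t", col.names = FALSE)
  rk <- gr0(sim$rmsk)
  data.table::fwrite(data.table::data.table(
    0L, 0L, 0L, 0L, 0L, rk$chrom, rk$start, rk$end, 0L, "+",
    paste0("rep", seq_len(nrow(rk))),
    S4Vectors::mcols(sim$rmsk)$repClass, "family"), paths$rmsk,
    sep = "\t", col.names = FALSE)
  writeLines(format_gtf(sim), paths$gtf)
  bed <- function(gr, p) data.table::fwrite(
    gr0(gr), p, sep = "\t", col.names = FALSE)
  bed(sim$regulatory$open_chromatin, paths$open_chromatin)
  bed(sim$regulatory$enhancer, paths$enhancers)
  paths
}

format_gtf <- function(sim) {
  lines <- character(0)
  for (g in seq_len(nrow(sim$genes))) {
    gd <- sim$genes[g]
    attr_g <- sprintf('gene_id "%s"; gene_type "protein_coding";',
                      gd$gene_id)
    attr_t <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_type "protein_coding";',
      gd$gene_id, gd$gene_id)
    row <- function(type, s0, e0, attrs) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              gd$chrom, type, s0 + 1L, e0, gd$strand, attrs)
    }
    lines <- c(lines, row("gene", gd$start, gd$end, attr_g),
               row("transcript", gd$start, gd$end, attr_t))
    ex <- sim$exons[gene_id == gd$gene_id]
    cd <- sim$cds[gene_id == gd$gene_id]
    for (i in seq_len(nrow(ex)))
      lines <- c(lines, row("exon", ex$start[i], ex$end[i], attr_t))
    for (i in seq_len(nrow(cd)))
      lines <- c(lines, row("CDS", cd$start[i], cd$end[i], attr_t))
  }
  lines
}

#' Simulate paired-platform methylation calls over a simulated genome
#'
#' Each reference CpG receives one true methylation probability drawn from
#' the Beta distribution of its context (priority: island > promoter >
#' shore > shelf > gene body > open sea). Both platforms observe the same
#' truth through independent binomial read sampling at platform-specific
#' depths, with platform-specific level jitter and an optional systematic
#' platform-B offset; platform B additionally drops a fraction of sites
#' and naturally loses zero-depth sites. CHH/CHG records are emitted with
#' methylation equal to the conversion-failure rate.
#'
#' @param sim A [simulate_genome()] result.
#' @param cfg A [sim_config()]; defaults to the one inside `sim`.
#' @return List: `calls_a`, `calls_b` ([callset()]s), `chh`, `chg`
#'   (CallSets of non-CpG records), `truth` (data.table: chrom, pos,
#'   label, theta) and `catalog` (the cpg_context catalog used).
#' @export
simulate_calls <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 1000L)
  catalog <- build_cpg_context(sim$islands, genome_sizes = sim$genome_sizes)
  pos_list <- reference_cpg_positions(sim$genome)
  truth <- data.table::data.table(
    chrom = rep(names(pos_list), lengths(pos_list)),
    pos = unlist(pos_list, use.names = FALSE))
  gene_gr <- gr_from_bed0(sim$genes$chrom, sim$genes$start, sim$genes$end,
                          sim$genome_sizes)
  prom <- promoter_gr(sim$genes, sim$genome_sizes)
  lab <- rep("open_sea", nrow(truth))
  lab[points_in(truth$chrom, truth$pos, gene_gr)] <- "body"
  lab[points_in(truth$chrom, truth$pos, catalog$tracks$shelf)] <- "shelf"
  lab[points_in(truth$chrom, truth$pos, catalog$tracks$shore)] <- "shore"
  lab[points_in(truth$chrom, truth$pos, prom)] <- "promoter"
  lab[points_in(truth$chrom, truth$pos, catalog$tracks$island)] <- "island"
  truth[, label := lab]
  mu <- cfg$beta_means[truth$label]
  truth[, theta := rbeta(.N, mu * cfg$beta_conc, (1 - mu) * cfg$beta_conc)]
  n <- nrow(truth)
  depth_a <- pmax(1L, as.integer(round(rnorm(n, cfg$depth_a_mean,
                                             cfg$depth_a_sd))))
  depth_b <- rnbinom(n, size = cfg$depth_b_size, mu = cfg$depth_b_mu)
  clip01 <- function(x) pmin(1, pmax(0, x))
  th_a <- clip01(truth$theta + rnorm(n, 0, cfg$jitter_a / 100))
  th_b <- clip01(truth$theta + cfg$offset_b / 100 +
                   rnorm(n, 0, cfg$jitter_b / 100))
  truth[, theta_a := th_a]  # per-platform expected level after jitter,
  truth[, theta_b := th_b]  # offset and clipping (recovery oracle)
  k_a <- rbinom(n, depth_a, th_a)
  k_b <- rbinom(n, depth_b, th_b)
  calls_a <- callset(
    data.table::data.table(chrom = truth$chrom, pos = truth$pos,
                           n_meth = k_a, n_unmeth = depth_a - k_a),
    platform_label = "hifi", genome_id = "simgenome")
  keep_b <- depth_b > 0L & runif(n) >= cfg$dropout_b
  calls_b <- callset(
    data.table::data.table(chrom = truth$chrom[keep_b],
                           pos = truth$pos[keep_b],
                           n_meth = k_b[keep_b],
                           n_unmeth = (depth_b - k_b)[keep_b]),
    platform_label = "wgbs", genome_id = "simgenome")
  nonCpG <- function(n_rec, label) {
    d <- pmax(1L, rnbinom(n_rec, size = cfg$depth_b_size,
                          mu = cfg$depth_b_mu))
    k <- rbinom(n_rec, d, cfg$conversion_failure)
    callset(data.table::data.table(
      chrom = sample(names(sim$genome_sizes), n_rec, replace = TRUE),
      pos = seq_len(n_rec),  # synthetic placeholder positions
      n_meth = k, n_unmeth = d - k),
      platform_label = label, genome_id = "simgenome")
  }
  list(calls_a = calls_a, calls_b = calls_b,
       chh = nonCpG(cfg$n_chh, "wgbs_chh"),
       chg = nonCpG(cfg$n_chg, "wgbs_chg"),
       truth = truth, catalog = catalog)
}

# strand-aware promoter intervals from a gene table (0-based half-open)
promoter_gr <- function(genes, genome_sizes, promoter_up = 2000L) {
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, genes$start - promoter_up, genes$end)
  end0 <- ifelse(plus, genes$start, genes$end + promoter_up)
  gr_from_bed0(genes$chrom, pmax(0L, start0), end0, genome_sizes)
}
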