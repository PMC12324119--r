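#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Root seed for every stochastic stage.
#' @param simulate List of [sim_config()] overrides (ignored when `inputs`
#'   is given). The default runs the generator end to end.
#' @param inputs Optional list with ready-made inputs:
#'   `calls_a`, `calls_b` (paths), `format_a`, `format_b`
#'   (`"bedmethyl"`/`"bismark"`), `fasta`, `islands`, `simple_repeat`,
#'   `rmsk`, `gtf`, `open_chromatin`, `enhancers`, optional `variants`
#'   (BED) and `chh` (Bismark-coverage CHH records).
#' @param min_level,alt_level,min_depth mC criteria (defaults 50, 80, 4).
#' @param n_replicates Downsampling replicates (default 1000; scale down
#'   for quick runs).
#' @param flank_bp Metaprofile flank (default 2000).
#' @return A `RunConfig` list.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = list(),
                       inputs = NULL, min_level = 50, alt_level = 80,
                       min_depth = 4L, n_replicates = 1000L,
                       flank_bp = 2000L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 min_level = min_level, alt_level = alt_level,
                 min_depth = as.integer(min_depth),
                 n_replicates = as.integer(n_replicates),
                 flank_bp = as.integer(flank_bp)),
            class = "RunConfig")
}

# gene table (0-based half-open) from a GTF, for metaprofiling
gtf_genes <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  g <- gr[as.character(S4Vectors::mcols(gr)$type) == "gene"]
  data.table::data.table(
    gene_id = as.character(S4Vectors::mcols(g)$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    start = IRanges::start(g) - 1L, end = IRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full concordance pipeline
#'
#' Orchestrates ingest, annotation, mC-set comparison, context statistics,
#' depth-binned concordance, depth-matched downsampling, metagene
#' profiling, sequence entropy and conversion QC, writing every table as
#' TSV plus a machine-readable `summary.json` into `cfg$out_dir`. The run
#' is deterministic given `cfg$seed`; the configuration is echoed into the
#' bundle.
#'
#' @param cfg A [run_config()].
#' @return The report bundle (list), invisibly; side effect: files under
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  crit <- mc_criteria(cfg$min_level, cfg$min_depth)
  crit_alt <- mc_criteria(cfg$alt_level, cfg$min_depth)

  if (is.null(cfg$inputs)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    scfg <- do.call(sim_config, sim_args)
    sim <- stage("simulate", simulate_genome(scfg))
    sim_dir <- file.path(cfg$out_dir, "sim")
    paths <- stage("simulate", write_sim_genome(sim, sim_dir))
    calls <- stage("simulate", simulate_calls(sim, scfg))
    write_callset(calls$calls_a, file.path(sim_dir, "calls_a.bed"),
                  "bedmethyl")
    write_callset(calls$calls_b, file.path(sim_dir, "calls_b.cov"),
                  "bismark_cov")
    inputs <- list(calls_a = file.path(sim_dir, "calls_a.bed"),
                   calls_b = file.path(sim_dir, "calls_b.cov"),
                   format_a = "bedmethyl", format_b = "bismark",
                   fasta = paths$fasta, islands = paths$islands,
                   simple_repeat = paths$simple_repeat, rmsk = paths$rmsk,
                   gtf = paths$gtf,
                   open_chromatin = paths$open_chromatin,
                   enhancers = paths$enhancers)
    chh <- calls$chh
    genes_dt <- sim$genes
  } else {
    inputs <- cfg$inputs
    chh <- if (!is.null(inputs$chh))
      read_bismark_coverage(inputs$chh, merge_strands = FALSE,
                            platform_label = "chh")
    genes_dt <- stage("ingest", gtf_genes(inputs$gtf))
  }

  reader <- function(path, fmt, label) {
    switch(fmt,
           bedmethyl = read_bedmethyl(path, platform_label = label,
                                      genome_id = "run"),
           bismark = read_bismark_coverage(path, merge_strands = FALSE,
                                           platform_label = label,
                                           genome_id = "run"),
           stop("unknown call format '", fmt, "'"))
  }
  cs_a <- stage("ingest", reader(inputs$calls_a, inputs$format_a, "A"))
  cs_b <- stage("ingest", reader(inputs$calls_b, inputs$format_b, "B"))

  genome <- stage("annotate", load_genome(inputs$fasta))
  sizes <- setNames(Biostrings::width(genome), names(genome))
  catalogs <- stage("annotate", list(
    cpg_context = build_cpg_context(read_cpg_islands(inputs$islands),
                                    genome_sizes = sizes),
    gc_density = build_gc_density(genome),
    repeats = build_repeats(read_simple_repeat(inputs$simple_repeat),
                            read_rmsk(inputs$rmsk), sizes),
    gene_features = build_gene_features(inputs$gtf, genome_sizes = sizes),
    regulatory = build_regulatory(read_bed(inputs$open_chromatin),
                                  read_bed(inputs$enhancers), sizes),
    chromosome = build_chromosome_catalog(sizes)))
  index <- stage("annotate", index_reference_cpgs(genome, catalogs))

  variants <- if (!is.null(inputs$variants)) {
    v <- read_bed(inputs$variants)
    data.table::data.table(
      chrom = as.character(GenomeInfoDb::seqnames(v)),
      pos = IRanges::start(v) - 1L)
  }
  report <- stage("compare", decompose_mc_sets(cs_a, cs_b, crit, variants))
  thr <- stage("compare", list(
    a = threshold_consistency(cs_a, crit, crit_alt),
    b = threshold_consistency(cs_b, crit, crit_alt)))

  summaries <- stage("stats", data.table::rbindlist(lapply(
    catalogs, function(cat)
      summarize_context(report, cs_a, cs_b, index, cat))))
  dbc <- stage("stats", depth_binned_concordance(cs_a, cs_b))

  dcfg <- downsample_config(n_replicates = cfg$n_replicates,
                            seed = cfg$seed,
                            min_shared_depth = cfg$min_depth)
  run <- stage("downsample",
               run_depth_matched(cs_a, cs_b, dcfg,
                                 catalog = catalogs$cpg_context))
  rq <- stage("downsample", r_by_depth_level(run))

  profiles <- if (!is.null(genes_dt)) stage("metaprofile", list(
    a = metaprofile(cs_a, genes_dt, cfg$flank_bp, cfg$min_depth),
    b = metaprofile(cs_b, genes_dt, cfg$flank_bp, cfg$min_depth)))

  entropy_cat <- stage("seqstats", local({
    rep_cat <- catalogs$repeats
    inter <- GenomicRanges::reduce(c(rep_cat$tracks$LINE,
                                     rep_cat$tracks$SINE))
    context_catalog("entropy_classes",
                    list(tandem = rep_cat$tracks$tandem,
                         interspersed = inter,
                         non_repetitive = rep_cat$tracks$non_repetitive),
                    partition = FALSE, genome_sizes = sizes)
  }))
  entropy <- stage("seqstats", entropy_by_category(genome, entropy_cat))
  qc <- if (!is.null(chh)) stage("seqstats", conversion_efficiency(chh))

  # ---- write bundle ----
  w <- function(x, f) data.table::fwrite(x, file.path(cfg$out_dir, f),
                                         sep = "\t")
  w(summaries, "context_summaries.tsv")
  w(dbc$bins, "depth_binned_concordance.tsv")
  w(rq, "downsample_r_by_depth.tsv")
  w(run$r_by_label, "downsample_r_by_label.tsv")
  if (!is.null(profiles)) {
    w(profiles$a$bins, "metaprofile_a.tsv")
    w(profiles$b$bins, "metaprofile_b.tsv")
  }
  w(entropy, "entropy_by_category.tsv")
  w(report$explanations, "unique_site_explanations.tsv")
  summary <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    criteria = list(min_level = crit$min_level,
                    alt_level = cfg$alt_level,
                    min_depth = crit$min_depth),
    mc_sets = report$summary[setdiff(names(report$summary),
                                     "explanation_fractions")],
    explanation_fractions = report$summary$explanation_fractions,
    threshold_consistency = thr,
    conversion_qc = if (!is.null(qc))
      list(pct_meth_chh = qc$pct_meth_chh, efficiency = qc$efficiency),
    entropy = as.list(setNames(entropy$mean_H, entropy$category)),
    downsample = list(n_replicates = dcfg$n_replicates,
                      r_overall_median = stats::median(run$r_overall),
                      r_averaged_overall = run$r_averaged$overall))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  bundle <- list(config = cfg, callsets = list(a = cs_a, b = cs_b),
                 catalogs = catalogs, index = index, report = report,
                 threshold = thr, summaries = summaries, depth_binned = dbc,
                 downsample = run, r_by_depth = rq, profiles = profiles,
                 entropy = entropy, conversion = qc, summary = summary)
  invisible(bundle)
}
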