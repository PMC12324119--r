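#' Assign a CpG to a metagene bin
#'
#' Genes are laid out on an oriented axis with 140 bins: 1-20 cover the
#' `flank_bp` upstream of the TSS in fixed `flank_bp/20`-bp steps (bin 20
#' abuts the TSS), 21-120 cover the gene body in 100 relative bins of 1%
#' of the gene's length each, and 121-140 cover the downstream flank. For
#' minus-strand genes the genomic axis is reflected so bin 1 is always the
#' most-upstream position.
#'
#' @param cpg_pos 0-based CpG position(s) (vectorized).
#' @param gene List or one-row data.frame with `start`, `end` (0-based
#'   half-open) and `strand` (`"+"`/`"-"`).
#' @param flank_bp Flank width (default 2000).
#' @return Integer bin index in 1..140, or `NA` outside
#'   `[TSS - flank_bp, TES + flank_bp)`.
#' @export
assign_bin <- function(cpg_pos, gene, flank_bp = 2000L) {
  start <- as.integer(gene$start); end <- as.integer(gene$end)
  if (end <= start) stop("zero-length gene")
  strand <- as.character(gene$strand)
  p <- as.integer(cpg_pos)
  len <- end - start
  step <- flank_bp / 20
  if (strand == "-") {
    # reflect: oriented position measured from the right end
    upstream_off <- p - end          # >=0 when in the upstream flank
    body_off <- (end - 1L) - p       # 0 at the minus-strand TSS
    down_off <- (start - 1L) - p     # >=0 when in the downstream flank
  } else {
    upstream_off <- (start - 1L) - p
    body_off <- p - start
    down_off <- p - end
  }
  bin <- rep(NA_integer_, length(p))
  in_body <- body_off >= 0L & body_off < len
  bin[in_body] <- 21L + pmin(floor(100 * body_off[in_body] / len), 99)
  in_up <- upstream_off >= 0L & upstream_off < flank_bp
  bin[in_up] <- 20L - as.integer(floor(upstream_off[in_up] / step))
  in_down <- down_off >= 0L & down_off < flank_bp
  bin[in_down] <- 121L + as.integer(floor(down_off[in_down] / step))
  as.integer(bin)
}

#' Gene-aligned metagene methylation profile
#'
#' Aggregates a platform's methylation levels into the 140-bin gene-aligned
#' layout of [assign_bin()], averaging over all CpG occurrences across all
#' genes per bin (a CpG inside the flanks of two genes contributes to
#' both). Sites below `min_depth` are excluded. Bins that receive no CpG
#' carry an `NA` mean, never 0.
#'
#' @param cs A [callset()].
#' @param genes data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; all genes are used regardless of length.
#' @param flank_bp Flank width (default 2000).
#' @param min_depth Minimum depth for a CpG to contribute (default 4).
#' @param per_gene_mean If `TRUE`, aggregate as the mean over genes of
#'   per-gene bin means instead of pooling CpG occurrences.
#' @return An object of class `MetaProfile` whose `bins` table has exactly
#'   140 rows: `bin`, `region` (upstream/body/downstream), `mean_level`,
#'   `n_cpg`.
#' @export
metaprofile <- function(cs, genes, flank_bp = 2000L, min_depth = 4L,
                        per_gene_mean = FALSE) {
  stopifnot_callset(cs)
  genes <- data.table::as.data.table(genes)
  if (nrow(genes) == 0L) stop("empty gene list")
  calls <- cs$calls[depth >= min_depth & !is.na(level)]
  hits <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gi <- genes[g]
    sub <- calls[chrom == gi$chrom &
                   pos >= gi$start - flank_bp &
                   pos < gi$end + flank_bp]
    if (nrow(sub) == 0L) next
    b <- assign_bin(sub$pos, gi, flank_bp)
    keep <- !is.na(b)
    if (!any(keep)) next
    hits[[g]] <- data.table::data.table(gene = g, bin = b[keep],
                                        level = sub$level[keep])
  }
  occ <- data.table::rbindlist(hits)
  if (per_gene_mean && nrow(occ)) {
    per_gene <- occ[, .(level = mean(level), n = .N), by = .(gene, bin)]
    agg <- per_gene[, .(mean_level = mean(level), n_cpg = sum(n)),
                    by = bin]
  } else if (nrow(occ)) {
    agg <- occ[, .(mean_level = mean(level), n_cpg = .N), by = bin]
  } else {
    agg <- data.table::data.table(bin = integer(), mean_level = numeric(),
                                  n_cpg = integer())
  }
  bins <- data.table::data.table(bin = 1:140)
  bins[, region := c(rep("upstream", 20), rep("body", 100),
                     rep("downstream", 20))]
  bins <- merge(bins, agg, by = "bin", all.x = TRUE)
  bins[is.na(n_cpg), n_cpg := 0L]
  data.table::setkey(bins, bin)
  structure(list(bins = bins[], flank_bp = flank_bp,
                 n_genes = nrow(genes), platform = cs$platform_label),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf(
    "MetaProfile '%s': 140 bins over %d genes (flank %d bp); %d bins populated\n",
    x$platform, x$n_genes, x$flank_bp, sum(x$bins$n_cpg > 0)))
  invisible(x)
}
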