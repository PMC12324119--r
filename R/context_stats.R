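#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' Standard Pearson r; returns `NA` (never 0) when fewer than two paired
#' observations remain or either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar r in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Per-context concordance summary
#'
#' For every label of a catalog: the reference-normalized mC proportions
#' of both platforms (`n_mc / n_ref_cpg`, the denominator being the number
#' of reference CpGs in that label), the overlap/unique decomposition, the
#' mean methylation level of each platform over *overlap-called* sites
#' (sites covered at `min_depth`+ on both platforms), and the Pearson
#' correlation of the two platforms' levels over those same sites. Means
#' are unweighted per-site averages.
#'
#' @param report An [decompose_mc_sets()] result.
#' @param cs_a,cs_b The two [callset()]s the report was built from.
#' @param index A [index_reference_cpgs()] result covering `catalog`.
#' @param catalog A [context_catalog()].
#' @return data.table with one row per label: `catalog`, `label`,
#'   `n_ref_cpg`, `n_mc_a`, `n_mc_b`, `n_overlap`, `n_unique_a`,
#'   `n_unique_b`, `delta_unique`, `prop_mc_a`, `prop_mc_b`,
#'   `prop_overlap`, `prop_unique_a`, `prop_unique_b`, `delta_prop_unique`,
#'   `mean_level_a`, `mean_level_b`, `pearson_r`, `n_sites_corr`.
#'   Proportions are `NA` (flagged) for labels without reference CpGs;
#'   correlations are `NA` when fewer than two variable sites enter.
#' @export
summarize_context <- function(report, cs_a, cs_b, index, catalog) {
  stopifnot(inherits(report, "MCSetReport"),
            inherits(catalog, "ContextCatalog"))
  min_depth <- report$criteria$min_depth
  shared <- merge(cs_a$calls, cs_b$calls, by = c("chrom", "pos"),
                  suffixes = c("_a", "_b"))
  shared <- shared[depth_a >= min_depth & depth_b >= min_depth]
  cat_name <- catalog$name
  rows <- lapply(names(catalog$tracks), function(lab) {
    tr <- catalog$tracks[[lab]]
    n_ref <- index$counts[catalog == cat_name & label == lab, n_ref_cpg]
    in_lab <- function(dt) {
      if (nrow(dt) == 0L) return(dt[0L])
      dt[points_in(dt$chrom, dt$pos, tr)]
    }
    mca <- in_lab(report$mc_a); mcb <- in_lab(report$mc_b)
    ov <- in_lab(report$overlap)
    ua <- in_lab(report$unique_a); ub <- in_lab(report$unique_b)
    sh <- in_lab(shared)
    n_ref <- if (length(n_ref)) n_ref[1L] else NA_integer_
    prop <- function(n) if (is.na(n_ref) || n_ref == 0L) NA_real_ else n / n_ref
    r <- pearson_r(sh$level_a, sh$level_b)
    data.table::data.table(
      catalog = catalog$name, label = lab, n_ref_cpg = n_ref,
      n_mc_a = nrow(mca), n_mc_b = nrow(mcb), n_overlap = nrow(ov),
      n_unique_a = nrow(ua), n_unique_b = nrow(ub),
      delta_unique = nrow(ua) - nrow(ub),
      prop_mc_a = prop(nrow(mca)), prop_mc_b = prop(nrow(mcb)),
      prop_overlap = prop(nrow(ov)),
      prop_unique_a = prop(nrow(ua)), prop_unique_b = prop(nrow(ub)),
      delta_prop_unique = prop(nrow(ua)) - prop(nrow(ub)),
      mean_level_a = if (nrow(sh)) mean(sh$level_a) else NA_real_,
      mean_level_b = if (nrow(sh)) mean(sh$level_b) else NA_real_,
      pearson_r = r, n_sites_corr = nrow(sh))
  })
  data.table::rbindlist(rows)
}

#' Depth-stratified concordance between two platforms
#'
#' Bins shared CpG sites by read depth and reports the per-bin Pearson
#' correlation of methylation levels plus a 2D histogram of
#' `(level_a, level_b)` per bin. Bins are closed integer ranges labelled
#' "a-b": the first bin is `[edges[1], edges[2]]` and each subsequent bin
#' starts one read above the previous bin's upper edge (edges
#' `c(5, 10, 15)` give bins 5-10 and 11-15); a final `Inf` edge gives an
#' open ">last" bin. With `matched_only`, only sites whose depths agree on
#' both platforms are kept and binned by that shared depth; otherwise
#' sites are binned by platform-B depth.
#'
#' @param cs_a,cs_b [callset()]s on the same genome.
#' @param edges Strictly increasing integer depth edges.
#' @param matched_only Keep only equal-depth sites.
#' @param hist_binwidth Width, in percentage points, of the 2D level
#'   histogram cells (default 2).
#' @return An object of class `DepthBinnedConcordance`: a `bins`
#'   data.table (`bin`, `lo`, `hi`, `n_sites`, `pearson_r`) and a named
#'   list `hist2d` of matrices (rows = platform A level bins, columns =
#'   platform B level bins) whose entries per bin sum to `n_sites`.
#' @export
depth_binned_concordance <- function(cs_a, cs_b, edges = c(5, 10, 15, 20,
                                                           25, 30, 40, 60,
                                                           Inf),
                                     matched_only = TRUE,
                                     hist_binwidth = 2) {
  stopifnot_callset(cs_a); stopifnot_callset(cs_b)
  check_same_genome(cs_a, cs_b)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  shared <- merge(cs_a$calls, cs_b$calls, by = c("chrom", "pos"),
                  suffixes = c("_a", "_b"))
  if (matched_only) {
    shared <- shared[depth_a == depth_b]
    if (nrow(shared) == 0L) {
      warning("no sites with matched depth on both platforms")
    }
    shared[, bin_depth := depth_a]
  } else {
    shared[, bin_depth := depth_b]
  }
  lo <- c(edges[1L], head(edges[-1L], -1L) + 1L)
  hi <- edges[-1L]
  labels <- ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(">", lo - 1L))
  brk <- seq(0, 100, by = hist_binwidth)
  if (tail(brk, 1L) < 100) brk <- c(brk, 100)
  bins <- list(); hists <- list()
  for (i in seq_along(lo)) {
    sub <- shared[bin_depth >= lo[i] & bin_depth <= hi[i] &
                    !is.na(level_a) & !is.na(level_b)]
    r <- if (nrow(sub) >= 2L) pearson_r(sub$level_a, sub$level_b)
         else NA_real_
    bins[[i]] <- data.table::data.table(
      bin = labels[i], lo = lo[i], hi = hi[i],
      n_sites = nrow(sub), pearson_r = r)
    ha <- cut(sub$level_a, brk, include.lowest = TRUE)
    hb <- cut(sub$level_b, brk, include.lowest = TRUE)
    hists[[labels[i]]] <- table(ha, hb)
  }
  structure(list(bins = data.table::rbindlist(bins), hist2d = hists,
                 matched_only = matched_only, edges = edges),
            class = "DepthBinnedConcordance")
}
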