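#' Methylated-CpG classification criteria
#'
#' A CpG is regarded as methylated when its methylation level is at least
#' `min_level` percent AND its read depth is at least `min_depth`. Both
#' thresholds are inclusive. Defaults are level >= 50% at depth >= 4; a
#' stricter 80% level is the conventional alternative cutoff.
#'
#' @param min_level Percent in `[0, 100]`.
#' @param min_depth Reads, at least 1.
#' @return An object of class `MCCriteria`.
#' @export
mc_criteria <- function(min_level = 50, min_depth = 4L) {
  if (min_level < 0 || min_level > 100) stop("min_level must be in [0,100]")
  if (min_depth < 1L) stop("min_depth must be >= 1")
  structure(list(min_level = as.numeric(min_level),
                 min_depth = as.integer(min_depth)),
            class = "MCCriteria")
}

#' Classify methylated CpGs
#'
#' @param cs A [callset()].
#' @param crit An [mc_criteria()].
#' @return A keyed data.table of `(chrom, pos)` for sites with
#'   `level >= min_level` and `depth >= min_depth`. Depth-0 sites (level
#'   undefined) are never included.
#' @export
classify_mc <- function(cs, crit = mc_criteria()) {
  stopifnot_callset(cs)
  mc <- cs$calls[!is.na(level) & level >= crit$min_level &
                   depth >= crit$min_depth, .(chrom, pos)]
  data.table::setkeyv(mc, c("chrom", "pos"))
  mc
}

#' Decompose two platforms' methylated-CpG sets
#'
#' Computes the overlap and the platform-unique mC sets, and explains each
#' unique site by inspecting the *other* platform's call at that position.
#' Categories are exclusive and assigned in fixed precedence order:
#' \describe{
#'   \item{variant_position}{the site is in the supplied variant mask — a
#'     sequence variant invalidates both depth and level readings;}
#'   \item{low_depth_other}{the other platform has no call there or covers
#'     it below `min_depth`;}
#'   \item{sub_threshold_other}{the other platform calls it at adequate
#'     depth but with level below `min_level`;}
#'   \item{absent_other}{defensive residual (unreachable when the other
#'     platform's calls are internally consistent).}
#' }
#'
#' @param cs_a,cs_b [callset()]s on the same genome.
#' @param crit An [mc_criteria()].
#' @param variants Optional data.frame of `(chrom, pos)` variant positions
#'   (0-based). When absent, variant sites fold into the depth/level
#'   categories.
#' @return An object of class `MCSetReport` with the position sets, the
#'   per-site explanation table, and a summary with both count and
#'   fraction decompositions (fractions over the platform's own mC set and
#'   over the union).
#' @export
decompose_mc_sets <- function(cs_a, cs_b, crit = mc_criteria(),
                              variants = NULL) {
  stopifnot_callset(cs_a); stopifnot_callset(cs_b)
  check_same_genome(cs_a, cs_b)
  mc_a <- classify_mc(cs_a, crit)
  mc_b <- classify_mc(cs_b, crit)
  overlap <- mc_a[mc_b, nomatch = NULL]
  unique_a <- mc_a[!mc_b]
  unique_b <- mc_b[!mc_a]
  vdt <- if (!is.null(variants) && nrow(variants)) {
    v <- data.table::as.data.table(variants)[, .(chrom = as.character(chrom),
                                                 pos = as.integer(pos))]
    data.table::setkeyv(v, c("chrom", "pos"))
    v
  }
  expl_a <- explain_unique(unique_a, cs_b, crit, vdt)
  expl_b <- explain_unique(unique_b, cs_a, crit, vdt)
  explanations <- data.table::rbindlist(list(
    if (nrow(expl_a)) cbind(set = "unique_a", expl_a),
    if (nrow(expl_b)) cbind(set = "unique_b", expl_b)))
  summary <- list(
    n_mc_a = nrow(mc_a), n_mc_b = nrow(mc_b),
    n_overlap = nrow(overlap),
    n_unique_a = nrow(unique_a), n_unique_b = nrow(unique_b),
    delta_unique = nrow(unique_a) - nrow(unique_b),
    n_union = nrow(mc_a) + nrow(mc_b) - nrow(overlap),
    frac_overlap_of_a = safe_div(nrow(overlap), nrow(mc_a)),
    frac_overlap_of_b = safe_div(nrow(overlap), nrow(mc_b)),
    frac_overlap_of_union = safe_div(
      nrow(overlap), nrow(mc_a) + nrow(mc_b) - nrow(overlap)),
    explanation_fractions = list(
      unique_a = category_fractions(expl_a),
      unique_b = category_fractions(expl_b)))
  structure(list(mc_a = mc_a, mc_b = mc_b, overlap = overlap,
                 unique_a = unique_a, unique_b = unique_b,
                 explanations = explanations, criteria = crit,
                 summary = summary),
            class = "MCSetReport")
}

explain_unique <- function(uniq, cs_other, crit, vdt) {
  if (nrow(uniq) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  category = character()))
  other <- cs_other$calls[uniq, on = c("chrom", "pos")]
  cat <- rep("absent_other", nrow(uniq))
  present <- !is.na(other$depth)
  low <- !present | (present & other$depth < crit$min_depth)
  sub <- present & other$depth >= crit$min_depth &
    !is.na(other$level) & other$level < crit$min_level
  cat[sub] <- "sub_threshold_other"
  cat[low] <- "low_depth_other"
  if (!is.null(vdt)) {
    isvar <- !is.na(vdt[uniq, on = c("chrom", "pos"), which = TRUE])
    cat[isvar] <- "variant_position"
  }
  data.table::data.table(chrom = uniq$chrom, pos = uniq$pos, category = cat)
}

category_fractions <- function(expl) {
  cats <- c("variant_position", "low_depth_other", "sub_threshold_other",
            "absent_other")
  if (nrow(expl) == 0L) return(setNames(rep(NA_real_, length(cats)), cats))
  tab <- table(factor(expl$category, levels = cats))
  setNames(as.numeric(tab) / nrow(expl), cats)
}

#' @export
print.MCSetReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "MCSetReport (level >= %g%%, depth >= %d)\n  mC A: %d  mC B: %d  overlap: %d\n  unique A: %d  unique B: %d  (delta %d)\n",
    x$criteria$min_level, x$criteria$min_depth,
    s$n_mc_a, s$n_mc_b, s$n_overlap, s$n_unique_a, s$n_unique_b,
    s$delta_unique))
  invisible(x)
}

#' Cross-threshold mC consistency
#'
#' For a stricter level criterion nested in a looser one, reports the
#' fraction of strict-threshold mCs also called under the loose threshold
#' (1 by construction when only `min_level` differs) and the retained
#' fraction `|mc(strict)| / |mc(loose)|` — the quantity behind statements
#' like "over 80% of mCs at the 80% cutoff overlap those at 50%".
#'
#' @param cs A [callset()].
#' @param crit_low,crit_high Loose and strict [mc_criteria()];
#'   `crit_high$min_level` must be >= `crit_low$min_level`.
#' @return List with `overlap_fraction`, `retained_fraction`, `n_low`,
#'   `n_high`. `overlap_fraction` is `NA` (flagged) when the strict set is
#'   empty.
#' @export
threshold_consistency <- function(cs, crit_low = mc_criteria(50, 4),
                                  crit_high = mc_criteria(80, 4)) {
  if (crit_high$min_level < crit_low$min_level)
    stop("crit_high$min_level must be >= crit_low$min_level")
  mc_low <- classify_mc(cs, crit_low)
  mc_high <- classify_mc(cs, crit_high)
  n_both <- nrow(mc_high[mc_low, nomatch = NULL])
  list(overlap_fraction = safe_div(n_both, nrow(mc_high)),
       retained_fraction = safe_div(nrow(mc_high), nrow(mc_low)),
       n_low = nrow(mc_low), n_high = nrow(mc_high))
}

safe_div <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
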