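#' Configuration for depth-matched downsampling
#'
#' @param n_replicates Number of independent resampling rounds
#'   (default 1000).
#' @param seed Integer seed; the whole run is reproducible byte-for-byte
#'   given the seed.
#' @param min_shared_depth Minimum depth both platforms must reach at a
#'   site for it to enter the matched analysis (default 4).
#' @param mode `"per_replicate_r"` computes one Pearson r per replicate per
#'   stratum (a distribution of r over replicates); `"averaged_levels"`
#'   averages each site's resampled level over replicates and computes one
#'   r per stratum from the averaged levels. Both summaries are always
#'   returned; `mode` only selects which one downstream reports highlight.
#' @param replace Sample reads with replacement (binomial) instead of the
#'   default without-replacement (hypergeometric) draw. Without
#'   replacement, a site already at the target depth keeps its counts
#'   exactly.
#' @return An object of class `DownsampleConfig`.
#' @export
downsample_config <- function(n_replicates = 1000L, seed = 1L,
                              min_shared_depth = 4L,
                              mode = c("per_replicate_r", "averaged_levels"),
                              replace = FALSE) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 min_shared_depth = as.integer(min_shared_depth),
                 mode = match.arg(mode), replace = isTRUE(replace)),
            class = "DownsampleConfig")
}

#' Downsample one site's reads to a target depth
#'
#' Draws the number of methylated reads retained when `target` reads are
#' sampled without replacement from the site's observed reads:
#' `k_meth ~ Hypergeometric(N = n_meth + n_unmeth, K = n_meth, n = target)`
#' (with replacement: `Binomial(target, n_meth / N)`). Vectorized over
#' sites.
#'
#' @param n_meth,n_unmeth Observed read counts (vectors).
#' @param target Target depth per site; must not exceed the observed depth
#'   in without-replacement mode.
#' @param replace Sample with replacement.
#' @return Integer vector `k_meth`; `k_unmeth` is `target - k_meth`.
#' @export
downsample_site <- function(n_meth, n_unmeth, target, replace = FALSE) {
  n <- max(length(n_meth), length(n_unmeth), length(target))
  n_meth <- rep_len(as.integer(n_meth), n)
  n_unmeth <- rep_len(as.integer(n_unmeth), n)
  target <- rep_len(as.integer(target), n)
  depth <- n_meth + n_unmeth
  if (!replace && any(target > depth))
    stop("target depth exceeds observed depth at ",
         sum(target > depth), " site(s)")
  if (replace) {
    rbinom(n, size = target, prob = ifelse(depth > 0, n_meth / depth, 0))
  } else {
    rhyper(n, m = n_meth, n = n_unmeth, k = target)
  }
}

#' Run site-level depth-matched downsampling
#'
#' At every CpG site shared between the platforms (both depths >=
#' `min_shared_depth`), both platforms' reads are independently resampled
#' down to the matched depth `d = min(depth_a, depth_b)`; the procedure is
#' repeated for `n_replicates` rounds. The two platforms use independent
#' draws — there is no stream coupling between them. Concordance is then
#' summarized per replicate (Pearson r genome-wide, per catalog label, per
#' matched depth `d`, and per pre-matching platform-A depth) and, in
#' parallel, from the per-site mean resampled level across replicates.
#'
#' @param cs_a,cs_b [callset()]s on the same genome.
#' @param cfg A [downsample_config()].
#' @param catalog Optional [context_catalog()] for per-label strata (for
#'   overlay catalogs a site contributes to every label covering it).
#' @return An object of class `DownsampleRun`: `sites` (per-site table with
#'   matched depth `d` and mean resampled levels), `r_overall` (one r per
#'   replicate), `r_by_depth` / `r_by_adepth` / `r_by_label` (data.tables
#'   with one r per stratum per replicate), `r_averaged` (one r per
#'   stratum from replicate-averaged levels) and the echoed `config`.
#' @export
run_depth_matched <- function(cs_a, cs_b, cfg = downsample_config(),
                              catalog = NULL) {
  stopifnot_callset(cs_a); stopifnot_callset(cs_b)
  check_same_genome(cs_a, cs_b)
  shared <- merge(cs_a$calls, cs_b$calls, by = c("chrom", "pos"),
                  suffixes = c("_a", "_b"))
  shared <- shared[depth_a >= cfg$min_shared_depth &
                     depth_b >= cfg$min_shared_depth]
  if (nrow(shared) == 0L) stop("no shared sites at min_shared_depth")
  shared[, d := pmin(depth_a, depth_b)]
  data.table::setkeyv(shared, c("chrom", "pos"))
  n_sites <- nrow(shared)
  labels_of <- NULL
  if (!is.null(catalog)) {
    labels_of <- lapply(names(catalog$tracks), function(lab) {
      which(points_in(shared$chrom, shared$pos, catalog$tracks[[lab]]))
    })
    names(labels_of) <- names(catalog$tracks)
  }
  by_d <- split(seq_len(n_sites), shared$d)
  by_ad <- split(seq_len(n_sites), shared$depth_a)

  set.seed(cfg$seed)
  sum_la <- numeric(n_sites); sum_lb <- numeric(n_sites)
  r_overall <- numeric(cfg$n_replicates)
  r_by_depth <- vector("list", cfg$n_replicates)
  r_by_adepth <- vector("list", cfg$n_replicates)
  r_by_label <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    k_a <- downsample_site(shared$n_meth_a, shared$n_unmeth_a, shared$d,
                           replace = cfg$replace)
    k_b <- downsample_site(shared$n_meth_b, shared$n_unmeth_b, shared$d,
                           replace = cfg$replace)
    la <- 100 * k_a / shared$d
    lb <- 100 * k_b / shared$d
    sum_la <- sum_la + la; sum_lb <- sum_lb + lb
    r_overall[rep_i] <- pearson_r(la, lb)
    r_by_depth[[rep_i]] <- strata_r(by_d, la, lb, rep_i, "depth")
    r_by_adepth[[rep_i]] <- strata_r(by_ad, la, lb, rep_i, "depth")
    if (!is.null(labels_of))
      r_by_label[[rep_i]] <- strata_r(labels_of, la, lb, rep_i, "label")
  }
  sites <- shared[, .(chrom, pos, depth_a, depth_b, d)]
  sites[, mean_level_a := sum_la / cfg$n_replicates]
  sites[, mean_level_b := sum_lb / cfg$n_replicates]
  averaged <- averaged_r(sites, by_d, by_ad, labels_of)
  structure(list(sites = sites,
                 r_overall = r_overall,
                 r_by_depth = data.table::rbindlist(r_by_depth),
                 r_by_adepth = data.table::rbindlist(r_by_adepth),
                 r_by_label = data.table::rbindlist(r_by_label),
                 r_averaged = averaged,
                 config = cfg),
            class = "DownsampleRun")
}

strata_r <- function(groups, la, lb, rep_i, key) {
  out <- data.table::data.table(
    stratum = names(groups),
    replicate = rep_i,
    n_sites = lengths(groups),
    r = vapply(groups, function(idx) pearson_r(la[idx], lb[idx]),
               numeric(1)))
  data.table::setnames(out, "stratum", key)
  out
}

averaged_r <- function(sites, by_d, by_ad, labels_of) {
  one <- function(groups, key) {
    dt <- data.table::data.table(
      stratum = names(groups), n_sites = lengths(groups),
      r = vapply(groups, function(idx) {
        pearson_r(sites$mean_level_a[idx], sites$mean_level_b[idx])
      }, numeric(1)))
    data.table::setnames(dt, "stratum", key)
    dt
  }
  list(overall = pearson_r(sites$mean_level_a, sites$mean_level_b),
       by_depth = one(by_d, "depth"),
       by_adepth = one(by_ad, "depth"),
       by_label = if (!is.null(labels_of)) one(labels_of, "label"))
}

#' Replicate-wise r quantiles per matched depth level
#'
#' @param run A [run_depth_matched()] result.
#' @param min_sites Depth levels with fewer sites than this are excluded
#'   (their r is dominated by sampling noise; default 50).
#' @param strata `"matched"` (the matched depth d) or `"platform_a"`
#'   (pre-matching platform-A depth).
#' @return data.table: `depth`, `n_sites`, and the min/q1/median/q3/max of
#'   r across replicates.
#' @export
r_by_depth_level <- function(run, min_sites = 50L,
                             strata = c("matched", "platform_a")) {
  stopifnot(inherits(run, "DownsampleRun"))
  strata <- match.arg(strata)
  tab <- if (strata == "matched") run$r_by_depth else run$r_by_adepth
  tab <- tab[n_sites >= min_sites & !is.na(r)]
  out <- tab[, .(n_sites = n_sites[1L],
                 r_min = min(r),
                 r_q1 = as.numeric(quantile(r, 0.25)),
                 r_median = as.numeric(quantile(r, 0.5)),
                 r_q3 = as.numeric(quantile(r, 0.75)),
                 r_max = max(r)),
             by = .(depth = as.integer(depth))]
  data.table::setkey(out, depth)
  out[]
}
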