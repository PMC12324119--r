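#' Read a bedMethyl-style methylation call file
#'
#' Parses the BED-derived per-site call format emitted by long-read CpG
#' pipelines (e.g. pileup outputs of pb-CpG-tools): tab-separated, 0-based
#' half-open, one row per CpG, with a methylation-percent column and a
#' coverage column whose indices vary between tool versions and are
#' therefore configurable through `dialect`.
#'
#' When `dialect$meth_col` is given, methylated read counts are taken
#' directly from that column; otherwise they are reconstructed as
#' `round(level * depth / 100)` with round-half-up, which can differ from a
#' printed level by less than 0.5 percentage points.
#'
#' @param path File path (plain or gzip).
#' @param dialect Named list with integer column indices: `level_col`,
#'   `depth_col`, and optionally `meth_col`.
#' @param min_fields Minimum number of tab-separated fields a line must
#'   have; lines with fewer are a parse error naming the line number.
#' @param platform_label,genome_id Passed to [callset()].
#' @return A [callset()] object.
#' @export
read_bedmethyl <- function(path,
                           dialect = list(level_col = 7L, depth_col = 8L,
                                          meth_col = NULL),
                           min_fields = NULL,
                           platform_label = "bedmethyl",
                           genome_id = "genome") {
  level_col <- as.integer(dialect$level_col)
  depth_col <- as.integer(dialect$depth_col)
  meth_col <- if (!is.null(dialect$meth_col)) as.integer(dialect$meth_col)
  if (is.null(min_fields))
    min_fields <- max(3L, level_col, depth_col, meth_col)
  dt <- read_call_table(path)
  if (nrow(dt) == 0L)
    return(callset(empty_calls(), platform_label, genome_id))
  check_min_fields(dt, min_fields, path)
  start0 <- suppressWarnings(as.integer(dt[[2L]]))
  end0 <- suppressWarnings(as.integer(dt[[3L]]))
  level <- suppressWarnings(as.numeric(dt[[level_col]]))
  depth <- suppressWarnings(as.integer(dt[[depth_col]]))
  bad <- which(is.na(start0) | is.na(end0) | is.na(depth))
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path)
  not_cpg <- end0 != start0 + 1L
  if (any(not_cpg)) {
    warning(sum(not_cpg), " record(s) with end != start+1 rejected ",
            "(not single-CpG records)")
    keep <- !not_cpg
    start0 <- start0[keep]; level <- level[keep]
    depth <- depth[keep]; dt <- dt[keep]
  }
  if (!is.null(meth_col)) {
    n_meth <- suppressWarnings(as.integer(dt[[meth_col]]))
    if (anyNA(n_meth)) stop("malformed methylated-count field in ", path)
  } else {
    n_meth <- as.integer(round_half_up(level * depth / 100))
  }
  callset(data.table::data.table(chrom = as.character(dt[[1L]]),
                                 pos = start0,
                                 n_meth = n_meth,
                                 n_unmeth = depth - n_meth),
          platform_label, genome_id)
}

#' Read a Bismark coverage file
#'
#' Format: `chrom  start(1-based)  end  level%  count_meth  count_unmeth`.
#' Positions are converted to the internal 0-based convention. The printed
#' level is checked against the counts; when they disagree by more than 0.5
#' percentage points a warning is issued and the counts win (the stored
#' level is always recomputed from counts).
#'
#' Bisulfite callers report the two strands of a CpG as separate cytosine
#' records: the forward C at position p and the reverse C (a G on the
#' forward strand) at p+1. With `merge_strands = TRUE` these pairs are
#' summed into a single forward-strand CpG record at p, making sites
#' comparable with combined-strand long-read callers. Pairing uses the
#' reference when `fasta` is supplied (a record at q merges into q-1 iff
#' the reference has CG at q-1); otherwise a paired-position heuristic is
#' used (adjacent record positions p, p+1 are merged left-to-right).
#' The merge conserves total read counts.
#'
#' @param path File path (plain or gzip).
#' @param merge_strands Sum reverse-strand records into the forward CpG.
#' @param fasta Optional reference (`DNAStringSet` or FASTA path) used to
#'   identify forward-strand CpG positions for the merge.
#' @param platform_label,genome_id Passed to [callset()].
#' @return A [callset()] object.
#' @export
read_bismark_coverage <- function(path, merge_strands = TRUE, fasta = NULL,
                                  platform_label = "bismark",
                                  genome_id = "genome") {
  dt <- read_call_table(path)
  if (nrow(dt) == 0L)
    return(callset(empty_calls(), platform_label, genome_id))
  check_min_fields(dt, 6L, path)
  pos1 <- suppressWarnings(as.integer(dt[[2L]]))
  level <- suppressWarnings(as.numeric(dt[[4L]]))
  n_meth <- suppressWarnings(as.integer(dt[[5L]]))
  n_unmeth <- suppressWarnings(as.integer(dt[[6L]]))
  bad <- which(is.na(pos1) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path)
  depth <- n_meth + n_unmeth
  recomputed <- ifelse(depth > 0, 100 * n_meth / depth, NA_real_)
  off <- !is.na(level) & !is.na(recomputed) & abs(level - recomputed) > 0.5
  if (any(off))
    warning(sum(off), " record(s) with printed level inconsistent with ",
            "counts by >0.5 points; counts win")
  calls <- data.table::data.table(chrom = as.character(dt[[1L]]),
                                  pos = pos1 - 1L,
                                  n_meth = n_meth, n_unmeth = n_unmeth)
  if (merge_strands)
    calls <- merge_cpg_strands(calls, fasta)
  callset(calls, platform_label, genome_id)
}

# sum reverse-strand cytosine records (at p+1) into the forward CpG at p
merge_cpg_strands <- function(calls, fasta = NULL) {
  data.table::setkeyv(calls, c("chrom", "pos"))
  if (!is.null(fasta)) {
    genome <- load_genome(fasta)
    fwd <- reference_cpg_positions(genome)
    is_fwd <- logical(nrow(calls))
    for (ch in unique(calls$chrom)) {
      idx <- which(calls$chrom == ch)
      is_fwd[idx] <- calls$pos[idx] %in% fwd[[ch]]
    }
    calls[, is_fwd := is_fwd]
    prev <- data.table::data.table(chrom = calls$chrom, pos = calls$pos - 1L)
    prev_is_fwd <- calls[prev, on = c("chrom", "pos"), x.is_fwd]
    merge_into_prev <- !calls$is_fwd & !is.na(prev_is_fwd) & prev_is_fwd
    calls[, is_fwd := NULL]
  } else {
    # heuristic: adjacent positions pair left-to-right (CpG strands are
    # always at distance 1, and two forward CpGs are never adjacent)
    merge_into_prev <- logical(nrow(calls))
    for (idx in split(seq_len(nrow(calls)), calls$chrom)) {
      p <- calls$pos[idx]
      i <- 2L
      while (i <= length(p)) {
        if (p[i] == p[i - 1L] + 1L && !merge_into_prev[idx[i - 1L]]) {
          merge_into_prev[idx[i]] <- TRUE
          i <- i + 2L
        } else i <- i + 1L
      }
    }
  }
  calls[, target := pos]
  calls$target[merge_into_prev] <- calls$pos[merge_into_prev] - 1L
  merged <- calls[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                  by = .(chrom, pos = target)]
  merged
}

#' Write a CallSet to disk
#'
#' Emits either the bedMethyl dialect read back by [read_bedmethyl()] with
#' its default `dialect` (columns: chrom, start, end, name, score, strand,
#' level, depth, n_meth) or the Bismark coverage dialect read back by
#' [read_bismark_coverage()] (`merge_strands = FALSE` round-trips exactly,
#' since written records are already combined-strand). Rows are ordered by
#' (chrom, pos). Reading the written file back yields an identical CallSet.
#'
#' @param cs A [callset()].
#' @param path Output path.
#' @param dialect `"bedmethyl"` or `"bismark_cov"`.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path, dialect = c("bedmethyl", "bismark_cov")) {
  stopifnot_callset(cs)
  dialect <- match.arg(dialect)
  dt <- data.table::copy(cs$calls)
  data.table::setkeyv(dt, c("chrom", "pos"))
  lvl <- ifelse(is.na(dt$level), 0, dt$level)
  out <- switch(dialect,
    bedmethyl = data.table::data.table(
      dt$chrom, dt$pos, dt$pos + 1L, ".", dt$depth, "+",
      sprintf("%.6g", lvl), dt$depth, dt$n_meth),
    bismark_cov = data.table::data.table(
      dt$chrom, dt$pos + 1L, dt$pos + 1L,
      sprintf("%.6g", lvl), dt$n_meth, dt$n_unmeth))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_calls <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         n_meth = integer(), n_unmeth = integer())
}

read_call_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(data.table::data.table())
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE,
                          blank.lines.skip = TRUE)
  dt
}

check_min_fields <- function(dt, min_fields, path) {
  if (ncol(dt) < min_fields)
    stop("malformed line 1 in ", path, ": fewer than ", min_fields,
         " tab-separated fields")
  # fill=TRUE pads short lines in the trailing columns
  last <- dt[[min_fields]]
  short <- which(is.na(last) | !nzchar(trimws(last)))
  if (length(short))
    stop("malformed line ", short[1L], " in ", path,
         ": fewer than ", min_fields, " fields")
  invisible(TRUE)
}
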