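#' CallSet: normalized per-CpG methylation calls for one platform
#'
#' A `CallSet` holds one record per CpG site called on one platform. Sites
#' are addressed by the 0-based position of the C of the CpG dinucleotide on
#' the forward strand, so records from different platforms join exactly.
#' Levels are percents in `[0, 100]`; a site with zero depth carries an `NA`
#' level and is excluded from any thresholded analysis.
#'
#' @param calls A data.frame with columns `chrom`, `pos` (0-based integer),
#'   `n_meth`, `n_unmeth`. `depth` and `level` are derived if absent.
#' @param platform_label Free-text platform name.
#' @param genome_id Identifier of the coordinate system the positions refer
#'   to; two CallSets can only be compared when their `genome_id`s match.
#' @return An object of class `CallSet`.
#' @export
callset <- function(calls, platform_label = "platform", genome_id = "genome") {
  dt <- data.table::as.data.table(calls)
  req <- c("chrom", "pos", "n_meth", "n_unmeth")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("calls lacks columns: ", paste(miss, collapse = ", "))
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_unmeth := as.integer(n_unmeth)]
  if (nrow(dt)) {
    if (any(dt$pos < 0L)) stop("negative position in calls")
    if (any(dt$n_meth < 0L | dt$n_unmeth < 0L)) stop("negative read count")
  }
  dt[, depth := n_meth + n_unmeth]
  dt[, level := meth_level(n_meth, n_unmeth)]
  dt <- dt[, .(chrom, pos, n_meth, n_unmeth, depth, level)]
  data.table::setkeyv(dt, c("chrom", "pos"))
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stop("duplicate CpG: more than one call at the same (chrom, pos)")
  structure(list(platform_label = platform_label,
                 genome_id = genome_id,
                 calls = dt),
            class = "CallSet")
}

#' @export
print.CallSet <- function(x, ...) {
  n0 <- sum(x$calls$depth == 0L)
  cat(sprintf("CallSet '%s' on '%s': %d CpG sites (%d with depth 0)\n",
              x$platform_label, x$genome_id, nrow(x$calls), n0))
  invisible(x)
}

#' @export
length.CallSet <- function(x) nrow(x$calls)

is_callset <- function(x) inherits(x, "CallSet")

stopifnot_callset <- function(x, arg = deparse(substitute(x))) {
  if (!is_callset(x)) stop(arg, " must be a CallSet")
  invisible(x)
}

check_same_genome <- function(a, b) {
  if (!identical(a$genome_id, b$genome_id))
    stop("CallSets refer to different genomes: '", a$genome_id,
         "' vs '", b$genome_id, "'")
  invisible(TRUE)
}
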