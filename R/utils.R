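#' @import data.table
#' @importFrom stats cor quantile rbeta rbinom rhyper rnbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# round-half-up, used when reconstructing counts from (level, depth);
# base round() is round-half-even and would give 2 for 2.5
round_half_up <- function(x) floor(x + 0.5)

#' Compute percent methylation from read counts
#'
#' Returns `100 * n_meth / (n_meth + n_unmeth)`, or `NA` where total depth
#' is zero (an undefined level, deliberately not 0).
#'
#' @param n_meth,n_unmeth Non-negative integer read counts.
#' @return Numeric vector of percent levels in `[0, 100]`, `NA` at depth 0.
#' @export
meth_level <- function(n_meth, n_unmeth) {
  depth <- n_meth + n_unmeth
  ifelse(depth > 0, 100 * n_meth / depth, NA_real_)
}

# named integer vector of chromosome lengths -> validated
as_genome_sizes <- function(genome_sizes) {
  if (is.null(names(genome_sizes)) || any(!nzchar(names(genome_sizes))))
    stop("genome_sizes must be a named vector of chromosome lengths")
  sizes <- as.integer(genome_sizes)
  if (any(is.na(sizes)) || any(sizes <= 0L))
    stop("genome_sizes must be positive integers")
  names(sizes) <- names(genome_sizes)
  sizes
}

# GRanges covering each whole chromosome
genome_granges <- function(genome_sizes) {
  sizes <- as_genome_sizes(genome_sizes)
  gr <- GenomicRanges::GRanges(
    seqnames = names(sizes),
    ranges = IRanges::IRanges(start = 1L, end = unname(sizes))
  )
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(sizes)
  gr
}

# build a GRanges from 0-based half-open coordinates, clipped to bounds
gr_from_bed0 <- function(chrom, start0, end0, genome_sizes = NULL) {
  if (length(chrom) == 0L)
    return(GenomicRanges::GRanges())
  start1 <- as.integer(start0) + 1L
  end1 <- as.integer(end0)
  keep <- end1 >= start1
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start1[keep], end1[keep]))
  if (!is.null(genome_sizes)) {
    sizes <- as_genome_sizes(genome_sizes)
    unknown <- !(as.character(GenomeInfoDb::seqnames(gr)) %in% names(sizes))
    if (any(unknown))
      stop("intervals on chromosomes absent from genome_sizes: ",
           paste(unique(as.character(GenomeInfoDb::seqnames(gr))[unknown]),
                 collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(sizes)
    clipped <- GenomicRanges::trim(gr)
    if (!identical(IRanges::ranges(clipped), IRanges::ranges(gr)))
      warning("intervals extending past chromosome ends were clipped")
    gr <- clipped
  }
  gr
}

# 0-based point positions -> width-1 GRanges (for membership queries)
points_gr <- function(chrom, pos0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L))
}

# fast "is point in interval set" using overlaps, ignoring strand
points_in <- function(chrom, pos0, gr) {
  if (length(gr) == 0L || length(pos0) == 0L)
    return(logical(length(pos0)))
  IRanges::overlapsAny(points_gr(chrom, pos0), gr, ignore.strand = TRUE)
}
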