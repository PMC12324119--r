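# small in-code fixtures shared across test files

toy_callset <- function(n = 10, seed = 42, platform = "toy",
                        genome_id = "toy_genome") {
  set.seed(seed)
  depth <- sample(1:40, n, replace = TRUE)
  n_meth <- rbinom(n, depth, runif(n))
  callset(data.frame(chrom = "chr1", pos = sort(sample(0:99999, n)),
                     n_meth = n_meth, n_unmeth = depth - n_meth),
          platform_label = platform, genome_id = genome_id)
}

# a deterministic two-chromosome toy genome as DNAStringSet
toy_genome <- function(len = 2000, seed = 7) {
  set.seed(seed)
  mk <- function() paste(sample(c("A", "C", "G", "T"), len,
                               replace = TRUE), collapse = "")
  Biostrings::DNAStringSet(c(chr1 = mk(), chr2 = mk()))
}

gr1 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

# per-base oracle for the island/shore/shelf partition: for each 0-based
# position, edge distance to the nearest island decides the label under
# island > shore > shelf priority
oracle_cpg_context <- function(pos, islands0, flank_shore = 2000,
                               flank_shelf = 4000) {
  vapply(pos, function(p) {
    d <- Inf
    for (i in seq_len(nrow(islands0))) {
      s <- islands0$start[i]; e <- islands0$end[i]
      if (p >= s && p < e) return("island")
      d <- min(d, if (p < s) s - p else p - e + 1L)
    }
    if (d <= flank_shore) "shore"
    else if (d <= flank_shelf) "shelf"
    else "open_sea"
  }, character(1))
}

# per-base oracle for the repeat partition under the stated priority
oracle_repeats <- function(pos, tandem0, line0, sine0, other0) {
  inside <- function(p, iv) {
    nrow(iv) > 0 && any(p >= iv$start & p < iv$end)
  }
  vapply(pos, function(p) {
    if (inside(p, tandem0)) "tandem"
    else if (inside(p, line0)) "LINE"
    else if (inside(p, sine0)) "SINE"
    else if (inside(p, other0)) "other_repeat"
    else "non_repetitive"
  }, character(1))
}

catalog_label_at <- function(catalog, chrom, pos0) {
  labs <- names(catalog$tracks)
  hit <- vapply(labs, function(lab) {
    methconcord:::points_in(chrom, pos0, catalog$tracks[[lab]])
  }, logical(length(pos0)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = length(pos0))
  apply(hit, 1L, function(row) {
    w <- which(row)
    if (length(w) == 1L) labs[w]
    else if (length(w) == 0L) NA_character_
    else paste(labs[w], collapse = "+")
  })
}
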