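#' Shannon entropy of a nucleotide sequence
#'
#' `H = -sum(p_i * log2(p_i))` over the frequencies of A, C, G, T (with
#' `0 * log 0 := 0`). Non-ACGT symbols are excluded from the denominator.
#' H ranges from 0 (homopolymer) to 2 bits (uniform base composition); low
#' values mark repetitive, homogeneous sequence.
#'
#' @param seq A character string or `DNAString`.
#' @return H in bits, or `NA` if the sequence contains no ACGT base.
#' @export
shannon_entropy <- function(seq) {
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  counts <- table(factor(bases, levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  p <- as.numeric(counts) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

# vectorized entropy from a base-count matrix (columns A,C,G,T)
entropy_from_counts <- function(m) {
  n <- rowSums(m)
  p <- m / ifelse(n > 0, n, NA_real_)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[n == 0] <- NA_real_
  h
}

#' Mean sequence entropy of CpG-containing windows per region category
#'
#' Tiles the genome into non-overlapping `window`-bp windows anchored at
#' position 0 of each chromosome, keeps windows containing at least one
#' CpG dinucleotide, computes each window's Shannon entropy, and averages
#' per category. A window counts toward every category whose intervals it
#' overlaps (so a border-straddling window may contribute to two
#' categories). With `placement = "cpg_centered"`, one `window`-bp window
#' is centered on each reference CpG instead.
#'
#' @param fasta Reference: `DNAStringSet` or FASTA path.
#' @param catalog A [context_catalog()] (typically the repeats partition,
#'   with interspersed = LINE+SINE).
#' @param window Window width in bp (default 100).
#' @param placement `"tiled"` or `"cpg_centered"`.
#' @return data.table: `category`, `n_windows`, `mean_H`; categories with
#'   no qualifying window carry `n_windows = 0` and `NA` mean.
#' @export
entropy_by_category <- function(fasta, catalog, window = 100L,
                                placement = c("tiled", "cpg_centered")) {
  placement <- match.arg(placement)
  genome <- load_genome(fasta)
  win_list <- lapply(names(genome), function(ch) {
    len <- Biostrings::width(genome)[names(genome) == ch]
    if (placement == "tiled") {
      n_full <- len %/% window
      if (n_full == 0L) return(NULL)
      tiles <- IRanges::successiveIRanges(rep(window, n_full))
    } else {
      cg <- Biostrings::matchPattern("CG", genome[[ch]])
      if (length(cg) == 0L) return(NULL)
      centers <- IRanges::start(cg)
      starts <- pmax(1L, centers - as.integer(window %/% 2L))
      tiles <- IRanges::IRanges(start = starts, width = window)
      tiles <- IRanges::restrict(tiles, start = 1L, end = len)
    }
    v <- Biostrings::Views(genome[[ch]], tiles)
    has_cpg <- Biostrings::vcountPattern("CG", v) >= 1L
    if (!any(has_cpg)) return(NULL)
    tiles <- tiles[has_cpg]
    v <- v[has_cpg]
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    data.table::data.table(chrom = ch,
                           start = IRanges::start(tiles),
                           end = IRanges::end(tiles),
                           H = entropy_from_counts(counts))
  })
  wins <- data.table::rbindlist(win_list)
  out <- lapply(names(catalog$tracks), function(lab) {
    if (nrow(wins) == 0L)
      return(data.table::data.table(category = lab, n_windows = 0L,
                                    mean_H = NA_real_))
    wgr <- GenomicRanges::GRanges(wins$chrom,
                                  IRanges::IRanges(wins$start, wins$end))
    sel <- IRanges::overlapsAny(wgr, catalog$tracks[[lab]],
                                ignore.strand = TRUE)
    h <- wins$H[sel & !is.na(wins$H)]
    data.table::data.table(category = lab, n_windows = length(h),
                           mean_H = if (length(h)) mean(h) else NA_real_)
  })
  data.table::rbindlist(out)
}

#' Classify a cytosine's sequence context
#'
#' The two bases downstream of the cytosine (on its own strand) decide the
#' context: G at +1 gives CpG; otherwise G at +2 gives CHG; otherwise CHH
#' (H = A, C or T). For the minus strand the reverse complement is read.
#'
#' @param fasta Reference: `DNAStringSet` or FASTA path.
#' @param chrom Chromosome name.
#' @param pos 0-based position of the cytosine.
#' @param strand `"+"` or `"-"`.
#' @return `"CpG"`, `"CHG"`, `"CHH"`, or `NA` when the context is
#'   truncated by the chromosome end.
#' @export
classify_cytosine_context <- function(fasta, chrom, pos, strand = "+") {
  genome <- load_genome(fasta)
  s <- genome[[chrom]]
  len <- length(s)
  base_at <- function(i) {
    # i is 0-based genomic; returns the base read on `strand`
    if (i < 0L || i >= len) return(NA_character_)
    b <- as.character(Biostrings::subseq(s, i + 1L, i + 1L))
    if (strand == "-")
      b <- chartr("ACGT", "TGCA", b)
    b
  }
  dir <- if (strand == "-") -1L else 1L
  if (!identical(base_at(pos), "C"))
    stop("base at position ", pos, " is not C on strand ", strand)
  p1 <- base_at(pos + dir)
  p2 <- base_at(pos + 2L * dir)
  if (is.na(p1)) return(NA_character_)
  if (p1 == "G") return("CpG")
  if (is.na(p2)) return(NA_character_)
  if (p2 == "G") return("CHG")
  "CHH"
}

#' Bisulfite conversion efficiency from non-CpG methylation
#'
#' Unmethylated cytosines outside CpG context should read as fully
#' converted; residual CHH "methylation" therefore proxies incomplete
#' conversion, and `efficiency = 100 - %CHH methylation`. The percent is
#' read-weighted by default (total methylated reads over total reads,
#' matching how callers summarize context methylation); `per_site = TRUE`
#' averages per-site levels instead.
#'
#' @param chh_calls A [callset()] (or data.frame with `n_meth`,
#'   `n_unmeth`) of CHH-context records.
#' @param cpg_calls,chg_calls Optional companion CallSets, summarized the
#'   same way into `pct_meth_cpg` / `pct_meth_chg`.
#' @param per_site Use the mean of per-site levels instead of the
#'   read-weighted percent.
#' @return An object of class `ConversionQC`: `pct_meth_chh`,
#'   `efficiency` (= 100 - pct_meth_chh, exactly), and optional
#'   `pct_meth_cpg` / `pct_meth_chg`.
#' @export
conversion_efficiency <- function(chh_calls, cpg_calls = NULL,
                                  chg_calls = NULL, per_site = FALSE) {
  pct <- function(x) {
    dt <- if (is_callset(x)) x$calls else data.table::as.data.table(x)
    if (per_site) {
      lv <- meth_level(dt$n_meth, dt$n_unmeth)
      lv <- lv[!is.na(lv)]
      if (!length(lv)) stop("zero total depth in context records")
      mean(lv)
    } else {
      tot <- sum(dt$n_meth) + sum(dt$n_unmeth)
      if (tot == 0) stop("zero total depth in context records")
      100 * sum(dt$n_meth) / tot
    }
  }
  pct_chh <- pct(chh_calls)
  structure(list(
    pct_meth_chh = pct_chh,
    pct_meth_chg = if (!is.null(chg_calls)) pct(chg_calls),
    pct_meth_cpg = if (!is.null(cpg_calls)) pct(cpg_calls),
    efficiency = 100 - pct_chh,
    per_site = per_site), class = "ConversionQC")
}

#' @export
print.ConversionQC <- function(x, ...) {
  cat(sprintf("ConversionQC: %%CHH meth = %.3f -> efficiency = %.3f%%\n",
              x$pct_meth_chh, x$efficiency))
  invisible(x)
}
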