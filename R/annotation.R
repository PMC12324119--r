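#' ContextCatalog: labelled interval sets over a genome
#'
#' A catalog is a named collection of interval tracks (one `GRanges` per
#' label) with declared semantics: a *partition* catalog has pairwise
#' disjoint labels that (except for deliberately unlabelled ground, see
#' [build_gc_density()]) tile the genome; an *overlay* catalog allows a
#' position to carry several labels at once.
#'
#' @param name Catalog id, e.g. `"cpg_context"`.
#' @param tracks Named list of `GRanges`.
#' @param partition Logical: labels mutually exclusive?
#' @param genome_sizes Named vector of chromosome lengths.
#' @return An object of class `ContextCatalog`.
#' @export
context_catalog <- function(name, tracks, partition, genome_sizes) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  sizes <- as_genome_sizes(genome_sizes)
  if (partition) {
    labs <- names(tracks)
    for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
      ov <- GenomicRanges::intersect(tracks[[i]], tracks[[j]],
                                     ignore.strand = TRUE)
      if (sum(IRanges::width(ov)) > 0)
        stop("partition catalog '", name, "': labels '", labs[i], "' and '",
             labs[j], "' overlap")
    }
  }
  structure(list(name = name, tracks = tracks, partition = partition,
                 genome_sizes = sizes),
            class = "ContextCatalog")
}

#' @export
print.ContextCatalog <- function(x, ...) {
  cat(sprintf("ContextCatalog '%s' (%s), %d labels:\n", x$name,
              if (x$partition) "partition" else "overlay",
              length(x$tracks)))
  for (lab in names(x$tracks))
    cat(sprintf("  %-16s %6d intervals, %10.0f bp\n", lab,
                length(x$tracks[[lab]]),
                sum(IRanges::width(x$tracks[[lab]]))))
  invisible(x)
}

# ---- UCSC-style table readers -------------------------------------------

#' Read a UCSC cpgIslandExt-style table
#'
#' Accepts both the raw table dump (leading `bin` column) and a plain
#' `chrom start end ...` BED-like layout; coordinates are 0-based half-open.
#'
#' @param path File path.
#' @return `GRanges` of CpG islands.
#' @export
read_cpg_islands <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  cols <- ucsc_coord_cols(dt)
  gr_from_bed0(dt[[cols[1L]]], as.integer(dt[[cols[2L]]]),
               as.integer(dt[[cols[3L]]]))
}

#' Read a UCSC simpleRepeat-style table (Tandem Repeats Finder output)
#' @param path File path.
#' @return `GRanges` of tandem-repeat tracts.
#' @export
read_simple_repeat <- function(path) read_cpg_islands(path)

#' Read a UCSC rmsk (RepeatMasker) table
#'
#' Uses the standard column layout (`genoName` = column 6, `genoStart` = 7,
#' `genoEnd` = 8, `repClass` = 12); a minimal 4-column
#' `chrom start end repClass` layout is also accepted.
#'
#' @param path File path.
#' @return `GRanges` with a `repClass` metadata column.
#' @export
read_rmsk <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) >= 12L) {
    gr <- gr_from_bed0(dt[[6L]], as.integer(dt[[7L]]), as.integer(dt[[8L]]))
    S4Vectors::mcols(gr)$repClass <- dt[[12L]]
  } else if (ncol(dt) >= 4L) {
    gr <- gr_from_bed0(dt[[1L]], as.integer(dt[[2L]]), as.integer(dt[[3L]]))
    S4Vectors::mcols(gr)$repClass <- dt[[4L]]
  } else stop("rmsk table needs >= 4 columns")
  gr
}

#' Read a BED3+ file
#' @param path File path.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  gr_from_bed0(dt[[1L]], as.integer(dt[[2L]]), as.integer(dt[[3L]]))
}

# does the table have a leading numeric 'bin' column (UCSC dump) or not?
ucsc_coord_cols <- function(dt) {
  first_numeric <- !anyNA(suppressWarnings(as.integer(dt[[1L]])))
  if (first_numeric && ncol(dt) >= 4L) 2:4 else 1:3
}

# ---- catalog builders ----------------------------------------------------

#' Build the CpG island / shore / shelf / open-sea partition
#'
#' Shores are the 0-2 kb flanks of merged islands, shelves the 2-4 kb
#' flanks, open sea the remainder, with the priority order
#' island > shore > shelf applied genome-wide so that colliding flanks of
#' nearby islands resolve deterministically.
#'
#' @param islands `GRanges` of CpG islands (overlapping islands are merged).
#' @param flank_shore Shore width in bp (default 2000).
#' @param flank_shelf_outer Outer edge of the shelf in bp from the island
#'   (default 4000).
#' @param genome_sizes Named chromosome lengths.
#' @return A partition [context_catalog()] named `"cpg_context"` with
#'   labels `island`, `shore`, `shelf`, `open_sea`.
#' @export
build_cpg_context <- function(islands, flank_shore = 2000L,
                              flank_shelf_outer = 4000L, genome_sizes) {
  sizes <- as_genome_sizes(genome_sizes)
  genome <- genome_granges(sizes)
  isl <- GenomicRanges::reduce(set_seqinfo(islands, sizes),
                               ignore.strand = TRUE)
  over_end <- IRanges::end(isl) > GenomeInfoDb::seqlengths(isl)[
    as.character(GenomeInfoDb::seqnames(isl))]
  if (any(IRanges::start(isl) < 1L) || any(over_end)) {
    warning("islands extending past chromosome bounds were clipped")
    isl <- GenomicRanges::trim(isl)
  }
  grow <- function(gr, by) {
    GenomicRanges::trim(suppressWarnings(gr + by))
  }
  shore <- GenomicRanges::setdiff(grow(isl, flank_shore), isl,
                                  ignore.strand = TRUE)
  shelf <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(grow(isl, flank_shelf_outer), isl,
                           ignore.strand = TRUE),
    shore, ignore.strand = TRUE)
  covered <- GenomicRanges::reduce(c(isl, shore, shelf))
  open_sea <- GenomicRanges::setdiff(genome, covered, ignore.strand = TRUE)
  context_catalog("cpg_context",
                  list(island = isl, shore = shore, shelf = shelf,
                       open_sea = open_sea),
                  partition = TRUE, genome_sizes = sizes)
}

#' Build the GC-density partition from a reference sequence
#'
#' The genome is tiled into non-overlapping windows anchored at position 0
#' of each chromosome (default width 5). A tile containing k G/C bases is
#' labelled 20k percent; tiles with zero G/C (including all-N tiles; N
#' counts as non-GC) carry no label — no CpG can occur there, since a
#' CpG's own C already contributes 20%.
#'
#' @param fasta Reference: `DNAStringSet` or FASTA path.
#' @param window Tile width in bp.
#' @return A [context_catalog()] named `"gc_density"` with labels
#'   `"20" ... "100"`; labels are disjoint but do not cover zero-GC ground.
#' @export
build_gc_density <- function(fasta, window = 5L) {
  genome <- load_genome(fasta)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  tracks <- lapply(setNames(1:5, as.character(seq(20, 100, 20))),
                   function(k) GenomicRanges::GRanges())
  per_chrom <- lapply(names(genome), function(ch) {
    seq_len_ch <- sizes[[ch]]
    n_tiles <- seq_len_ch %/% window
    widths <- rep(window, n_tiles)
    if (seq_len_ch %% window) {
      n_tiles <- n_tiles + 1L
      widths <- c(widths, seq_len_ch %% window)
    }
    tiles <- IRanges::successiveIRanges(widths)
    v <- Biostrings::Views(genome[[ch]], tiles)
    gc <- as.integer(Biostrings::letterFrequency(v, letters = "CG"))
    # k G/C bases in a tile -> 20k percent; zero-GC tiles stay unlabelled
    pct <- 20L * gc
    pct[gc == 0L] <- NA_integer_
    list(chrom = ch, tiles = tiles, pct = pct)
  })
  for (lab_k in 1:5) {
    lab <- as.character(20L * lab_k)
    parts <- lapply(per_chrom, function(pc) {
      sel <- which(!is.na(pc$pct) & pc$pct == 20L * lab_k)
      if (!length(sel)) return(NULL)
      r <- IRanges::reduce(pc$tiles[sel])
      data.frame(chrom = pc$chrom, start = IRanges::start(r),
                 end = IRanges::end(r))
    })
    parts <- data.table::rbindlist(parts)
    tracks[[lab]] <- set_seqinfo(
      if (nrow(parts)) GenomicRanges::GRanges(
        parts$chrom, IRanges::IRanges(parts$start, parts$end))
      else GenomicRanges::GRanges(),
      sizes)
  }
  context_catalog("gc_density", tracks, partition = TRUE,
                  genome_sizes = sizes)
}

#' Build the repeat-class partition
#'
#' Tandem repeats come from a simpleRepeat-style track, LINE/SINE from the
#' RepeatMasker `repClass` field (all other classes map to `other_repeat`),
#' and the non-repetitive ground is the genomic complement. Overlaps are
#' resolved by the priority order
#' tandem > LINE > SINE > other_repeat > non_repetitive.
#'
#' @param simple_repeat `GRanges` of tandem repeats.
#' @param rmsk `GRanges` with a `repClass` metadata column.
#' @param genome_sizes Named chromosome lengths.
#' @param priority Character vector giving the resolution order of the
#'   repeat labels (ground label excluded).
#' @return A partition [context_catalog()] named `"repeats"`.
#' @export
build_repeats <- function(simple_repeat, rmsk, genome_sizes,
                          priority = c("tandem", "LINE", "SINE",
                                       "other_repeat")) {
  sizes <- as_genome_sizes(genome_sizes)
  genome <- genome_granges(sizes)
  cls <- if (length(rmsk)) S4Vectors::mcols(rmsk)$repClass else character()
  raw <- list(
    tandem = GenomicRanges::reduce(set_seqinfo(simple_repeat, sizes)),
    LINE = GenomicRanges::reduce(set_seqinfo(rmsk[cls == "LINE"], sizes)),
    SINE = GenomicRanges::reduce(set_seqinfo(rmsk[cls == "SINE"], sizes)),
    other_repeat = GenomicRanges::reduce(
      set_seqinfo(rmsk[!(cls %in% c("LINE", "SINE"))], sizes)))
  stopifnot(setequal(priority, names(raw)))
  tracks <- list()
  taken <- genome[0]
  for (lab in priority) {
    tr <- GenomicRanges::setdiff(raw[[lab]], taken, ignore.strand = TRUE)
    tracks[[lab]] <- tr
    taken <- GenomicRanges::reduce(c(taken, tr))
  }
  tracks$non_repetitive <- GenomicRanges::setdiff(genome, taken,
                                                  ignore.strand = TRUE)
  context_catalog("repeats", tracks, partition = TRUE, genome_sizes = sizes)
}

#' Build the gene-feature overlay catalog from a GTF
#'
#' Labels: `gene`, `exon` (union over transcripts), `intron`
#' (gene minus exon union), `CDS`, `five_prime_UTR`/`three_prime_UTR` (or a
#' single `UTR` when the GTF does not distinguish), `promoter`
#' (`promoter_up` bp upstream of the strand-aware TSS), and `intergenic`
#' (genome minus CDS, promoter and gene). This catalog is an overlay: one
#' position may carry several labels, because each feature is reported and
#' normalized independently downstream.
#'
#' @param gtf Path to a GTF file, or a `GRanges` as returned by
#'   `rtracklayer::import` with a `type` column.
#' @param promoter_up Promoter extent upstream of the TSS, bp.
#' @param genome_sizes Named chromosome lengths.
#' @return An overlay [context_catalog()] named `"gene_features"`.
#' @export
build_gene_features <- function(gtf, promoter_up = 2000L, genome_sizes) {
  sizes <- as_genome_sizes(genome_sizes)
  genome <- genome_granges(sizes)
  gr <- if (is.character(gtf)) rtracklayer::import(gtf, format = "gtf")
        else gtf
  type <- as.character(S4Vectors::mcols(gr)$type)
  genes <- gr[type == "gene"]
  tx <- gr[type == "transcript"]
  if (length(tx)) {
    tx_genes <- S4Vectors::mcols(tx)$transcript_id
    exons_of <- S4Vectors::mcols(gr[type == "exon"])$transcript_id
    no_exons <- setdiff(tx_genes, exons_of)
    if (length(no_exons))
      warning(length(no_exons), " transcript(s) lack exons; skipped")
  }
  flat <- function(sel) {
    GenomicRanges::reduce(set_seqinfo(gr[type %in% sel], sizes),
                          ignore.strand = TRUE)
  }
  gene_u <- flat("gene")
  exon_u <- flat("exon")
  intron <- GenomicRanges::setdiff(gene_u, exon_u, ignore.strand = TRUE)
  promoter <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(set_seqinfo(genes, sizes),
                             upstream = promoter_up, downstream = 0L)))
  promoter <- GenomicRanges::reduce(promoter, ignore.strand = TRUE)
  cds <- flat("CDS")
  intergenic <- GenomicRanges::setdiff(
    genome, GenomicRanges::reduce(c(gene_u, promoter, cds)),
    ignore.strand = TRUE)
  tracks <- list(gene = gene_u, exon = exon_u, intron = intron,
                 CDS = cds, promoter = promoter, intergenic = intergenic)
  if (any(type == "five_prime_utr"))
    tracks$five_prime_UTR <- flat("five_prime_utr")
  if (any(type == "three_prime_utr"))
    tracks$three_prime_UTR <- flat("three_prime_utr")
  if (any(type == "UTR") && is.null(tracks$five_prime_UTR))
    tracks$UTR <- flat("UTR")
  context_catalog("gene_features", tracks, partition = FALSE,
                  genome_sizes = sizes)
}

#' Build the regulatory-element overlay catalog
#'
#' @param open_chromatin `GRanges` (e.g. DNase clusters).
#' @param enhancers `GRanges` (e.g. transcription-factor binding clusters).
#' @param genome_sizes Named chromosome lengths.
#' @return An overlay [context_catalog()] named `"regulatory"`.
#' @export
build_regulatory <- function(open_chromatin, enhancers, genome_sizes) {
  sizes <- as_genome_sizes(genome_sizes)
  context_catalog(
    "regulatory",
    list(open_chromatin = GenomicRanges::reduce(
           set_seqinfo(open_chromatin, sizes), ignore.strand = TRUE),
         enhancer = GenomicRanges::reduce(
           set_seqinfo(enhancers, sizes), ignore.strand = TRUE)),
    partition = FALSE, genome_sizes = sizes)
}

#' Build the per-chromosome partition catalog
#' @param genome_sizes Named chromosome lengths.
#' @return A partition [context_catalog()] named `"chromosome"`, one label
#'   per chromosome.
#' @export
build_chromosome_catalog <- function(genome_sizes) {
  sizes <- as_genome_sizes(genome_sizes)
  genome <- genome_granges(sizes)
  tracks <- lapply(setNames(names(sizes), names(sizes)), function(ch) {
    genome[as.character(GenomeInfoDb::seqnames(genome)) == ch]
  })
  context_catalog("chromosome", tracks, partition = TRUE,
                  genome_sizes = sizes)
}

# ---- reference CpG index -------------------------------------------------

#' Locate and count reference CpG sites per context label
#'
#' Finds every `CG` dinucleotide on the forward strand of the reference and
#' counts, for each label of each supplied catalog, how many CpGs fall in
#' that label. A CpG belongs to a label iff the position of its C lies in
#' the label's intervals (single-point assignment, so partition catalogs
#' never double-count a border CpG). These reference counts are the
#' normalizing denominators for methylated-CpG proportions.
#'
#' @param fasta Reference: `DNAStringSet` or FASTA path.
#' @param catalogs List of [context_catalog()] objects.
#' @return An object of class `ReferenceCpGIndex` with fields `positions`
#'   (named list of 0-based integer vectors per chromosome), `total`,
#'   `counts` (data.table: catalog, label, n_ref_cpg) and `genome_sizes`.
#' @export
index_reference_cpgs <- function(fasta, catalogs = list()) {
  genome <- load_genome(fasta)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  for (cat in catalogs) {
    common <- intersect(names(cat$genome_sizes), names(sizes))
    if (!length(common) ||
        !all(cat$genome_sizes[common] == sizes[common]))
      stop("catalog '", cat$name, "' was built on a different genome")
  }
  positions <- reference_cpg_positions(genome)
  total <- sum(lengths(positions))
  pts <- points_gr(rep(names(positions), lengths(positions)),
                   unlist(positions, use.names = FALSE))
  counts <- data.table::rbindlist(lapply(catalogs, function(cat) {
    data.table::rbindlist(lapply(names(cat$tracks), function(lab) {
      n <- sum(IRanges::overlapsAny(pts, cat$tracks[[lab]],
                                    ignore.strand = TRUE))
      data.table::data.table(catalog = cat$name, label = lab,
                             n_ref_cpg = n)
    }))
  }))
  structure(list(positions = positions, total = total, counts = counts,
                 genome_sizes = sizes),
            class = "ReferenceCpGIndex")
}

# 0-based forward-strand C positions of all CG dinucleotides, per chromosome
reference_cpg_positions <- function(genome) {
  lapply(setNames(names(genome), names(genome)), function(ch) {
    m <- Biostrings::matchPattern("CG", genome[[ch]])
    as.integer(IRanges::start(m)) - 1L
  })
}

load_genome <- function(fasta) {
  if (is.character(fasta)) {
    g <- Biostrings::readDNAStringSet(fasta)
    # FASTA headers may carry descriptions after the id
    names(g) <- sub("\\s.*$", "", names(g))
    g
  } else if (methods::is(fasta, "DNAStringSet")) fasta
  else stop("fasta must be a path or a DNAStringSet")
}

set_seqinfo <- function(gr, sizes) {
  sizes <- as_genome_sizes(sizes)
  GenomeInfoDb::seqlevels(gr) <- union(names(sizes),
                                       GenomeInfoDb::seqlevels(gr))
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  # out-of-bound ranges are detected and reported by the callers that
  # clip; GenomeInfoDb's own warning would just duplicate it
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- unname(sizes))
  gr
}
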