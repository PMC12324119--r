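---
title: "Methods: cross-platform CpG methylation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform CpG methylation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the record model, the context catalogs, the concordance
measures, the depth-matched downsampling procedure, what the synthetic
generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## 1. The record model

A methylation call is a per-site read count pair. For CpG site $i$ on
one platform, $n_{m,i}$ reads support methylation and $n_{u,i}$ support
no methylation; depth $d_i = n_{m,i} + n_{u,i}$ and the methylation
level is

$$\ell_i = 100 \cdot \frac{n_{m,i}}{d_i} \quad (\%),$$

undefined — stored as `NA`, never 0 — when $d_i = 0$. Sites are keyed by
the 0-based position of the C of the CpG dinucleotide on the forward
strand, which makes calls from a BED-native long-read caller and a
1-based bisulfite caller join exactly after normalization.

Two ingestion conventions matter:

* **Count reconstruction.** bedMethyl dialects that print only
  (level, depth) have counts reconstructed as
  $n_m = \lfloor \ell d / 100 + 0.5\rfloor$ (round-half-up, not R's
  round-half-even). The re-derived level can differ from the printed one
  by under 0.5 percentage points; printed levels never override counts.
* **Strand merging.** Bisulfite callers report the two cytosines of a
  CpG separately (forward C at $p$, reverse C at $p+1$); long-read
  callers report one combined-strand record. By default the reverse
  record is summed into the forward one so sites are comparable. The
  merge conserves total reads. Pairing is reference-guided when a FASTA
  is available, otherwise adjacent-position pairing is used (two forward
  CpG C's are never adjacent, so the heuristic is safe except for calls
  at positions absent from both a CpG and a CpG+1 slot, which are kept
  unmerged). Whether the original analyses merged strands is not
  knowable from the upstream tools alone, so the flag is exposed.

## 2. Methylated-CpG classification and set decomposition

A CpG is classified as methylated (an "mC") when $\ell_i \ge 50$ **and**
$d_i \ge 4$, both inclusive; the conventional stricter alternative is
$\ell_i \ge 80$. Raising either threshold can only shrink the set
(tested as a property), and the 80%-set is nested in the 50%-set, so the
cross-threshold "overlap" is identically 1 and the informative quantity
is the retained fraction $|mC_{80}|/|mC_{50}|$.

Given two call sets A and B, the universe for overlap statistics is the
union of called positions. Each site unique to one platform is explained
by inspecting the *other* platform's call there, in fixed precedence:

1. `variant_position` — the site is in a user-supplied variant mask; a
   sequence variant invalidates both the depth and the level readout,
   so it outranks the other categories;
2. `low_depth_other` — no call, or depth below the threshold;
3. `sub_threshold_other` — adequate depth but level below the threshold;
4. `absent_other` — defensive residual (unreachable for internally
   consistent inputs, kept so the partition is total by construction).

Both per-platform overlap fractions and the union-denominator fraction
are reported, since "X% of platform-B mCs are recovered by A" and
"X% of all mCs are shared" answer different questions.

## 3. Context catalogs

Contexts come in two kinds. *Partition* catalogs label every base with
exactly one class; *overlay* catalogs let a base carry several labels
(gene features and regulatory elements are overlays because each feature
is counted and normalized independently).

* **CpG context.** Shores are the 0–2 kb flanks of merged islands,
  shelves the 2–4 kb flanks, open sea the rest. Priority
  island > shore > shelf is applied genome-wide, which also resolves
  collisions between flanks of nearby islands (the tie-break the
  upstream description leaves open; this is the only self-consistent
  reading, and it is what the per-base oracle in the test suite
  encodes).
* **GC density.** Non-overlapping 5-base tiles anchored at position 0;
  a tile with $k$ G/C bases is labelled $20k\%$. N counts as non-GC.
  Zero-GC tiles carry no label: no CpG can occur in one, because the
  CpG's own C already contributes 20%. Tiling (rather than the
  overlapping-window wiggle semantics) was chosen because it yields a
  clean partition; a CpG-centered alternative exists for the entropy
  windows where the same ambiguity recurs.
* **Repeats.** Tandem tracts from a simpleRepeat-style track; LINE and
  SINE from the RepeatMasker class column; every other RepeatMasker
  class becomes `other_repeat`; the complement is `non_repetitive`.
  Priority tandem > LINE > SINE > other ensures "tandem repeat" always
  means the tandem track regardless of RepeatMasker overlap. The order
  is configurable.
* **Gene features.** Exon is the union over transcripts; intron is gene
  minus that union; promoters are the 2000 bp upstream of the
  strand-aware TSS; intergenic is the genome minus (gene ∪ promoter ∪
  CDS). UTR labels are taken from the GTF when present (split or
  unsplit).
* **Chromosome.** One label per chromosome.

A CpG belongs to a context by the position of its C alone — single-point
assignment prevents double counting at context borders. Reference CpG
counts per label (the denominators for normalized mC proportions) come
from locating every `CG` on the forward strand of the reference.

## 4. Concordance measures

Per context label the package reports normalized mC proportions
(count / reference CpGs in the label), the overlap/unique decomposition,
unweighted per-site mean levels over *overlap-called* sites (covered at
depth ≥ 4 on both platforms), and Pearson's $r$ between the two
platforms' levels over the same sites. Correlations from fewer than two
sites or from zero-variance vectors are reported as `NA`, never
coerced to 0. The implementation is verified against a naive two-pass
oracle to $10^{-12}$.

Depth-stratified concordance uses closed integer depth bins labelled
"a–b×" (5–10, 11–15, …, with an open ">x" final bin). By default only
sites whose depths *match* on both platforms are kept and binned by that
shared depth; the alternative bins all shared sites by platform-B depth.
2D level histograms (default 2-point cells) accompany each bin.

## 5. Depth-matched downsampling

Depth itself confounds level comparisons: a 4× site can only take
levels {0, 25, 50, 75, 100}. To remove it, at every shared site with
both depths ≥ 4 both platforms are resampled down to
$d = \min(d_A, d_B)$:

$$k_m \sim \mathrm{Hypergeometric}(N = d, K = n_m, n = d_{\min}),$$

i.e. drawing reads without replacement from the observed read set, so a
site already at the target depth keeps its counts exactly and the
resampled level is unbiased
($E[k_m] = d_{\min} K/N \Rightarrow E[\hat\ell] = \ell$). A
with-replacement (binomial) flag exists for sensitivity analysis. The
two platforms use independent draws — the procedure describes
independent subsampling of both platforms, so no stream coupling is
introduced.

The run is repeated (default 1,000 replicates) and summarized two ways,
because both are standard: the distribution of per-replicate $r$
(genome-wide, per context label, per matched depth, and per pre-matching
platform-A depth — the stratification basis is ambiguous upstream, so
both are emitted, labelled), and a single $r$ per stratum computed from
each site's mean resampled level across replicates. Depth strata with
fewer than 50 sites are excluded from the quantile table by default;
their $r$ is sampling noise.

**Reproducibility contract.** One root seed drives a single sequential
RNG stream over replicates with a fixed site ordering; identical
seed + inputs give byte-identical output (tested). Per-(site, replicate,
platform) substreams were considered for order-independence under
parallel execution and rejected: this implementation has no parallel
path and R's RNG API would make per-draw streams the dominant cost.

## 6. Metagene profile

Each gene contributes 140 bins: 20 fixed 100-bp bins upstream of the
TSS, 100 relative bins of 1% of the gene's length, 20 fixed bins
downstream of the TES, all strand-oriented (bin 1 is always
most-upstream). Body bin indices are
$21 + \min(\lfloor 100(p - \mathrm{start})/L \rfloor, 99)$ on the
oriented axis. Aggregation is the unweighted mean over all CpG
occurrences across genes; per-gene-mean aggregation is available by
flag since either convention is defensible. A CpG inside the flanks of
two genes contributes to both (symmetric, uses all data; flank CpGs
falling inside a neighboring gene are deliberately not filtered).
Bins with no CpG carry `NA`, never 0. Bin assignment is exactly
symmetric under genome reflection (tested).

## 7. Sequence statistics

Shannon entropy $H = -\sum_i p_i \log_2 p_i$ over A/C/G/T frequencies
(0–2 bits; non-ACGT symbols excluded from the denominator;
$0\log 0 := 0$). Entropy is averaged over CpG-containing 100-bp
genome-anchored tiles per repeat category; a tile overlapping a category
border counts toward both categories. A CpG-centered window placement is
available behind a flag, since "windows overlapping those regions"
admits both readings.

Cytosine context is decided by the two downstream bases on the
cytosine's own strand: G at +1 → CpG; else G at +2 → CHG; else CHH
(verified exhaustively over all 16 downstream 2-mers). Bisulfite
conversion efficiency is $100 - \%\mathrm{CHH\ methylation}$, with %CHH
read-weighted (total methylated reads over total reads) — matching how
callers summarize context methylation; a per-site-mean variant exists.
`efficiency + pct_meth_chh == 100` holds exactly.

## 8. The synthetic world

The generator states one explicit world and keeps it fixed:

* **Genome.** Two 500-kb chromosomes of 40%-GC i.i.d. background, with
  GC-rich islands (60% GC target), low-entropy tandem tracts (repeated
  short motifs, most containing a CpG so they enter the entropy
  windows), AT-rich LINE/SINE elements, stranded 3-exon genes, and
  regulatory intervals. The "paper-like" preset uses 600-kb chromosomes
  so the world holds ~50k CpGs.
* **Methylome.** One shared truth: per CpG,
  $\theta \sim \mathrm{Beta}(\mu_c \kappa, (1-\mu_c)\kappa)$ with
  context means $\mu_c$ = island 0.10, promoter 0.10, shore 0.50,
  shelf 0.85, gene body 0.85, open sea 0.80 and concentration
  $\kappa = 10$. These are generator settings chosen to reproduce the
  qualitative context orderings (islands/promoters low, shelves/bodies
  high), not measurements.
* **Observation.** Platform A depth is discretized
  $\mathcal{N}(29, 4)$ truncated at 1 (unimodal, near-symmetric,
  mode 28–30×); platform B depth is NegBinomial(size 2, mean 8)
  (right-skewed, most sites 4–10×), plus 5% site dropout and natural
  loss of zero-depth sites. Each platform observes
  $k \sim \mathrm{Binomial}(d, \theta')$ where $\theta'$ adds
  platform-specific Gaussian jitter (sd 2 points) and, in the
  paper-like preset, a +2-point systematic offset for platform B
  (bisulfite's tendency to read slightly higher). CHH/CHG records carry
  methylation equal to the conversion-failure rate, default 0.028
  (≈97.2% efficiency).

The beta–binomial observation model is the simplest one that produces
depth-dependent concordance — replicate $r$ rising with matched depth —
and that is a modelling choice, not an empirical claim. What the
generator does **not** emulate: read-level artifacts (mapping bias,
PCR duplicates, bisulfite degradation), CpG depletion of real vertebrate
background sequence, variant-induced miscalls, chromosome-scale
heterogeneity, and the extreme (>4000×) coverage tail of real bisulfite
data. A green test therefore establishes that the *pipeline arithmetic*
is right under the stated world, not that any particular genome-wide
number from real data is reproduced; genome-wide correlations from real
studies are explicitly out of reach at this scale.

## 9. Numerical conventions and degenerate inputs

* Levels are percents in [0, 100]; thresholds are inclusive.
* Depth-0 sites: level `NA`, excluded from all thresholded analyses,
  retained by I/O round-trips.
* Undefined correlations and proportions over empty denominators are
  `NA` and flagged, never 0.
* Count reconstruction is round-half-up; all other rounding follows R.
* Islands extending past chromosome ends are clipped with a warning;
  partition invariants (disjointness, coverage) still hold after
  clipping.
* Depth-bin edges are inclusive integer ranges; the first bin includes
  both its edges, subsequent bins start one read above the previous
  upper edge.

## 10. Known limitations

* The per-site explanation table attributes a unique site to the first
  matching category only; a site that is simultaneously a variant and
  low-depth appears as `variant_position`.
* `run_depth_matched` holds one resample of all shared sites in memory
  per replicate; at tens of millions of sites a chunked strategy would
  be needed.
* GTFs without gene records (transcript-only annotations) are not
  synthesized into genes.
* The CLI is a thin front end over the R API; configuration files are
  not parsed — R scripting is the intended composition layer.
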