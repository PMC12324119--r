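# methconcord

Cross-platform concordance analysis of per-CpG DNA methylation calls.

## The problem

5-methylcytosine at CpG dinucleotides can be read out by two very
different technologies: bisulfite sequencing (WGBS), which converts
unmethylated cytosines chemically and infers methylation from sequence
changes, and long-read sequencing (e.g. PacBio HiFi), which detects
methylation directly from polymerase kinetics. Studies that use both need
to know where and why the two readouts agree: per genomic context, per
sequencing depth, and per analysis threshold. `methconcord` implements
that comparison as a reusable, tested pipeline for anyone with per-CpG
call files from two platforms — plus a synthetic two-platform generator
so the entire pipeline runs and is testable without any external data.

## What it computes

For two call sets A and B over a shared CpG universe:

- **mC classification.** A CpG is *methylated* (an mC) when its
  methylation level ≥ 50% and read depth ≥ 4 (both inclusive;
  80% is the standard stricter alternative).
- **Set decomposition.** mC(A) and mC(B) are split into overlap and
  platform-unique sets; each unique site is explained by the other
  platform's call at that position (variant position, depth < 4,
  level < 50%, or absent).
- **Context stratification.** Catalogs built from standard annotation
  files: CpG island / shore (±2 kb) / shelf (2–4 kb) / open sea with
  island > shore > shelf priority; GC density of 5-base tiles
  (20…100%); tandem / LINE / SINE / other / non-repetitive;
  gene features (promoter = TSS−2000 bp, exon, intron, CDS, UTRs,
  intergenic); regulatory elements; chromosomes. mC counts are
  normalized by the number of reference CpGs per context.
- **Concordance.** Pearson r of methylation levels at overlap-called
  sites, per context and per depth bin (closed integer bins 5–10×,
  11–15×, …), with 2D level histograms.
- **Depth-matched downsampling.** At each shared site both platforms'
  reads are resampled without replacement
  (`k ~ Hypergeometric(N, K, d)`) down to the matched depth
  `d = min(depth_A, depth_B)`, over many replicates (default 1,000),
  giving replicate-r distributions per context and per depth level.
- **Metagene profile.** Average methylation in 140 gene-aligned bins
  (20 upstream / 100 relative body bins / 20 downstream, 2 kb flanks).
- **Sequence statistics.** Shannon entropy
  `H = −Σ pᵢ log₂ pᵢ` of CpG-containing 100-bp windows per repeat
  category; cytosine context classification (CpG/CHG/CHH); bisulfite
  conversion efficiency `= 100 − %CHH methylation`.

## Worked example

Run the whole pipeline on the built-in synthetic world (two platforms
observing one simulated methylome; islands hypomethylated, shelves and
gene bodies hypermethylated, HiFi-like depth ~29×, WGBS-like right-skewed
depth):

```r
library(methconcord)
cfg <- run_config(out_dir = "run1", seed = 17, n_replicates = 100)
b <- run_pipeline(cfg)

print(b$report)
#> MCSetReport (level >= 50%, depth >= 4)
#>   mC A: 35649  mC B: 24556  overlap: 23777
#>   unique A: 11872  unique B: 779  (delta 11093)

b$summaries[catalog == "cpg_context",
            .(label, n_ref_cpg, prop_mc_a, prop_mc_b,
              mean_level_a, mean_level_b, pearson_r)]
#>       label n_ref_cpg prop_mc_a prop_mc_b mean_level_a mean_level_b pearson_r
#> 1:   island      1381   0.00434    0.0145         9.71         9.94     0.544
#> 2:    shore      2604   0.48272    0.3760        48.54        48.03     0.623
#> 3:    shelf      2624   0.95770    0.6585        83.01        83.30     0.738
#> 4: open_sea     34771   0.91665    0.6278        77.01        76.96     0.780

print(b$conversion)
#> ConversionQC: %CHH meth = 2.763 -> efficiency = 97.237%

b$entropy
#>          category n_windows   mean_H
#> 1:         tandem        67 1.498010
#> 2:   interspersed       354 1.915814
#> 3: non_repetitive      9542 1.948684

median(b$downsample$r_overall)
#> [1] 0.753
```

Reading the numbers: platform A (long-read-like) calls many more mCs
than B, and nearly all of B's mCs are recovered by A — the unique-A
excess traces back to B's low-coverage sites (see
`run1/unique_site_explanations.tsv`). Islands carry almost no mCs and
~10% mean methylation while shelves sit near 85%, matching the
generator's truth. Tandem-repeat windows have visibly lower sequence
entropy (1.50 bits) than interspersed/non-repetitive sequence (~1.9).
The conversion QC recovers the simulated 2.8% conversion-failure rate as
97.2% efficiency. Every table in the bundle (`context_summaries.tsv`,
`downsample_r_by_depth.tsv`, `metaprofile_*.tsv`, `summary.json`, …) is
written under `out_dir`.

A thin CLI wraps the same functionality:

```sh
Rscript inst/scripts/methconcord.R simulate --seed 17 --out-dir sim/
Rscript inst/scripts/methconcord.R run --seed 17 --out-dir out/
```

## Documentation

`vignettes/methconcord-methods.Rmd` describes the statistical model, the
synthetic world and its limits, numerical conventions, and design
decisions. Function-level documentation lives in the roxygen comments in
`R/`.
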