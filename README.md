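# lrpseq

Genome-wide analysis of occupancy, gene regulation, and DNA bridging for a
bacterial global transcription regulator — built around the
leucine-responsive regulatory protein (Lrp) of *Escherichia coli*.

## The problem

Lrp binds hundreds of chromosomal sites, regulates a large fraction of the
*E. coli* genome, and responds to exogenous leucine; Lrp dimers assemble
into octamers and hexadecamers whose higher-order forms can bridge DNA
sites kilobases apart.  Dissecting such a regulator requires connecting
three layers of evidence: where the protein binds (ChIP-seq against a
knockout control), what that binding does to transcription (RNA-polymerase
ChIP-seq over gene bodies), and how an effector such as leucine reshapes
both.  `lrpseq` is an R package for analysts working with this kind of
paired regulator/RNAP ChIP-seq design across genotypes, media, growth
phases, and a lineage/biological replicate hierarchy.

## What it computes

**Occupancy statistic.** Binned coverage is depth-normalised and converted
per bin to a robust z-scored log-ratio,

    z_i = (r_i − median(r)) / (1.4826 · MAD(r)),   r_i = log2((chip_i + ε)/(input_i + ε)),

then the same statistic from the regulator-knockout (`lrp::scar`) sample is
subtracted bin-by-bin — the knockout-subtracted rz-log-ratio occupancy.

**Peaks and consensus.** A thresholding caller (default ≥ 4 robust-z
units) with gap merging and width filtering; cross-condition consensus
sites (union-merged intervals significant in ≥ 1 sample) with a
sites × samples occupancy matrix, max-normalised rows, Euclidean
average-linkage clustering, Spearman condition correlations, paired
Wilcoxon tests, exact Poisson rate and proportion tests on peak counts.

**Regulation.** TSS overlap with permutation enrichment; per-TU
regulator-dependent RNAP log2 fold changes with a pooled-null permutation
test and BH adjustment; direct-target calling (bound TSS **and**
significant RNAP change); a leucine-modulation score
`(lfc_LIV − lfc_Min) · sign(lfc_Min)`; classification of each direct
target into the six regulation modes (regulator activating/repressing ×
leucine independent/concerted/reciprocal).

**DNA bridging.** Per-peak local counts at 2 kb edge distance with
permutation comparisons between genotypes; circular interpeak-distance
distributions against a 200-shuffle within-region null with smoothed
densities and a pointwise 95% band.

**Bayesian quantification.** Hierarchical normal models (JAGS) for
Western-blot densitometry (posterior levels vs wild type, 95% credible
intervals, `P_diff`), ChIP-qPCR log2 enrichment with Savage–Dickey log10
Bayes-factor tiers (`*` 0.5–1, `**` 1–2, `***` > 2), and ΔΔCq expression
effects.

**Synthetic data.** A generator that plants primary sites, satellite sites
at 1.2–2 kb spacing, genotype-specific leucine responses, regulator-coupled
RNAP effects, and log-normal quantification noise — with a full
ground-truth record, so every stage above is validated by parameter
recovery.

## Worked example

```r
library(lrpseq)

cfg   <- sim_config(seed = 42)             # 1 Mb circular genome, 50 planted sites
ann   <- simulate_annotation(cfg)
truth <- simulate_truth(cfg, ann)

# knockout-subtracted occupancy for wild type in minimal medium, log phase
occ <- simulate_scored_track(cfg, truth, sample_meta("WT", "Min", "Log"))
peaks <- call_peaks(occ)
nrow(peaks)
#> [1] 71

ov <- overlap_tss(peaks, ann$tss)
en <- tss_enrichment(peaks, ann$tss, cfg$genome_length, n_perm = 999, seed = 1)
sprintf("%.1f%% of peaks at a TSS (null %.1f%%), p = %.3f",
        100 * ov$fraction, 100 * mean(en$null), en$p)
#> [1] "33.8% of peaks at a TSS (null 5.6%), p = 0.001"

local_peak_counts(peaks, cfg$genome_length)
#> <bridging_stats> 71 peaks, radius 2000 bp, mean local count 1.59

fit <- fit_western_model(simulate_western(truth, seed = 42),
                         mcmc_config(seed = 42))
subset(fit, phase == "Stat" & medium == "Min",
       select = c(strain, value, ci.lo, ci.hi, P_diff, direction))
#>    strain value ci.lo ci.hi P_diff direction
#> 13  D114E 1.052 0.713 1.447  0.600    higher
#> 14   dC11 0.384 0.266 0.564  1.000     lower
#> 15  L136R 0.689 0.472 0.984  0.979     lower
#> 16     WT 1.000 1.000 1.000     NA      <NA>
```

Reading the output: 71 peaks are called on the synthetic wild-type track;
a third of them sit on annotated TSSs, six times the permutation-null
expectation (p at the attainable floor for 999 permutations).  The mean
local peak count of 1.59 says most wild-type peaks are isolated or have one
close neighbour.  The Western model recovers the planted protein levels:
the dimer-only variant (`dC11`, planted at 0.45× wild type in stationary
phase) is confidently reduced (`P_diff` ≈ 1, direction "lower"), while
D114E (planted 1.3×) trends higher.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lrpseq.R` with subcommands `simulate`, `score`, `callpeaks`, and
`bridging`, each consuming and emitting files only (bedGraph, GFF3, BED6,
TSV, JSON).

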