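---
title: "Methods: occupancy scoring, regulation modes, bridging statistics and Bayesian quantification"
author: "lrpseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy scoring, regulation modes, bridging statistics and Bayesian quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpseq)
```

# The problem

The leucine-responsive regulatory protein (Lrp) is a global transcription
factor of *Escherichia coli* that binds hundreds of chromosomal sites and
regulates a large fraction of the genome in response to exogenous
branched-chain amino acids.  Lrp dimers assemble into octamers and
hexadecamers, and higher-order oligomers can contact two or more DNA sites
kilobases apart ("DNA bridging").  A paired experimental design measures
regulator occupancy (Lrp ChIP-seq) and transcriptional output (RNA
polymerase ChIP-seq) across genotypes (wild type and oligomerisation
variants D114E, L136R, and the dimer-only ΔC11), media (minimal medium,
`Min`, versus the same medium with leucine/isoleucine/valine, `LIV`), growth
phases (`Log`, `Stat`), and a replicate hierarchy of independently
constructed lineages each grown in biological replicate.  A regulator
deletion strain (`lrp::scar`, "scar") provides the zero-binding control.

`lrpseq` implements the analysis chain for such a design, together with a
synthetic-data generator that plants known ground truth so every stage can
be validated by parameter recovery.

# The occupancy statistic

For one sample, binned ChIP and input coverage are depth-normalised to a
common total (`normalize_depth()`, default $10^6$), converted to a per-bin
log ratio

$$r_i = \log_2\frac{c_i + \epsilon}{u_i + \epsilon},$$

with pseudocount $\epsilon = 1$ stabilising empty bins, and robust z-scored:

$$z_i = \frac{r_i - \operatorname{median}(r)}{1.4826\,\operatorname{MAD}(r)}.$$

The constant 1.4826 makes the MAD a consistent estimator of the standard
deviation under normality, so $z$ is on an interpretable SD-like scale while
remaining insensitive to the (sparse, strong) true peaks.  The same
statistic computed on the matched scar sample is subtracted bin-by-bin
(`subtract_scar()`), removing condition-specific artefacts such as
copy-number gradients: the result is the knockout-subtracted rz-log-ratio
occupancy on which everything downstream operates.  Stages are tracked on
the `occupancy_track` object and only advance forward
(`raw → log_ratio → rz → scar_subtracted`), so mis-ordered pipelines fail
loudly.

Bins are 0-based, half-open, fixed width (default 25 bp), and the replicon
is treated as circular throughout (a single bacterial chromosome), which
avoids edge artefacts in window extraction and in the shuffling nulls.

# Peak calling and consensus sites

`call_peaks()` takes maximal runs of bins at or above a threshold (default 4
robust-z units on the scar-subtracted scale), bridges sub-threshold gaps up
to `merge_gap` (default 4 bins) and discards runs narrower than `min_width`
(default 2 bins).  The threshold is deliberately conservative: the statistic
is centred at 0 with unit robust scale genome-wide, so 4 units is far into
the tail, and on knockout tracks the caller returns nothing (verified as a
calibration property).  All three parameters are exposed and logged by the
command-line wrapper.

`consensus_union()` merges the union of peak intervals across all samples at
gap 0 into disjoint consensus sites — each significant in at least one
sample — and fills the sites-by-samples matrix with each sample's mean
subtracted occupancy over each site.  Rows of that matrix are
max-normalised for display (`row_normalize()`; rows with non-positive
maxima are zeroed and flagged rather than sign-flipped), ordered by
agglomerative clustering with Euclidean distance and average linkage
(`cluster_order()`), and compared across conditions by Spearman correlation
(`condition_correlation()`) and the paired Wilcoxon signed-rank test
(`paired_occupancy_test()`; exact for ≤ 25 untied differences, otherwise
the continuity-corrected normal approximation).  Peak-count comparisons
between genotypes use the exact conditional Poisson rate test
(`poisson_rate_test()`, a binomial test on one count given the total) and
the continuity-corrected two-sample proportion test (`proportion_test()`).

# Connecting binding to transcription

A peak overlaps a transcription start site (TSS) when the TSS position lies
in the half-open peak interval.  Enrichment of peaks at promoters is
assessed by a permutation test (`tss_enrichment()`): each peak is re-placed
uniformly at random on the circular replicon with its width preserved, and
the overlap fraction recomputed; the p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, which is
valid (never anti-conservative) at any $n_\text{perm}$.

The transcriptional effect of the regulator at a transcription unit (TU) is
the mean over TU-body bins of the RNAP log$_2$(ChIP/input) statistic in the
regulator-carrying genotype minus the same quantity in the scar strain
(`tu_log2fc()`): a regulator-dependent log$_2$ fold change in RNAP
occupancy, positive for activation.  RNAP occupancy over the gene body is
used as the proxy for transcription.

Significance of those changes (`diff_significance()`) is a permutation
test with one deliberate design choice.  With the study's replicate design
(four regulator replicates versus four scar replicates) a per-TU label
permutation has only $\binom{8}{4} = 70$ distinct relabellings, so per-TU
p-values cannot fall below $2/70 \approx 0.029$ — after
Benjamini–Hochberg adjustment across a hundred TUs nothing could ever reach
$q \le 0.05$.  Because every TU statistic shares the same noise structure,
we studentise the per-TU difference (Welch t) and pool the permutation
null across TUs, a standard device in genomics permutation testing; the
pooled null has $n_\text{perm} \times n_\text{TU}$ draws and supports
genome-scale BH adjustment.  Calibration under the null is part of the test
suite (type-I error at the nominal level within binomial error over
hundreds of seeded trials).

A TU is a **direct target** (`call_direct_targets()`) when a peak overlaps
its TSS *and* its RNAP change is significant ($q \le 0.05$) under at least
one condition — binding without an expression change, or a change without
binding, does not qualify.

## The six regulation modes

Direct targets are classified (`classify_mode()`) along two axes:

* **direction** — activating or repressing, from the sign of the
  significant fold change (minimal medium taking precedence);
* **leucine axis** — *independent* (effect unchanged while bound in both
  media), *concerted* (effect significantly stronger in LIV), *reciprocal*
  (effect significantly weaker or absent in LIV).

The magnitude comparison uses a normal z-test on
$|\mathrm{lfc}_{LIV}| - |\mathrm{lfc}_{Min}|$ with the two standard errors
combined, at level 0.05; loss of TSS binding or loss of significance in LIV
counts as reciprocal (the mirror case as concerted).  Partial-reduction
sites still count as "bound" — binding is binary at the call level and the
magnitude lives in the **leucine-modulation score**

$$s = (\mathrm{lfc}_{LIV} - \mathrm{lfc}_{Min}) \cdot
      \operatorname{sign}(\mathrm{lfc}_{Min}),$$

positive when leucine strengthens the regulator's effect and negative when
it weakens it.  Applied to a generative model in which leucine only removes
or reduces binding, the classifier populates exclusively the two reciprocal
modes — the package-level counterpart of the experimental observation that
a leucine-inhibition-only mechanism suffices.

`tss_pileup()` builds the TSS-centred occupancy matrices used for heat
maps: rows are windows of ±1 kb (default) at bin resolution, reversed for
minus-strand TSSs so transcription always runs toward positive offsets,
with circular wrapping at the origin.

# Bridging statistics

Higher-order oligomers that bridge DNA manifest as clustered peaks.  Two
statistics quantify this:

* **Local peak counts** (`local_peak_counts()`): for each peak, the number
  of peaks within 2 kb (default) nearest-edge distance on the circle.  The
  focal peak counts itself (flag `include_self`), so an isolated peak
  scores 1 and "self plus one neighbour" scores 2, which keeps group means
  directly interpretable.  Genotype comparisons use a two-sided label
  permutation test on the per-peak counts (`local_count_permutation()`).
* **Interpeak distances** (`interpeak_distances()`): centre-to-centre
  distances between circularly consecutive peaks ($n$ peaks give $n$
  distances including the wrap-around gap).  Edge distance suits adjacency;
  centre distance suits spacing periodicity.

The null for the distance distribution (`shuffle_null()`) re-places each
peak uniformly at random — width preserved, overlaps rejected — within its
assigned region, 200 times by default, and reports the pointwise mean and
central 95% band of the smoothed density across shuffles.  Regions default
to fixed-span (10 kb) windows around observed peak clusters
(`cluster_regions()`), so the null preserves *where* clusters are while
destroying the spacing *within* them.  Non-overlap is enforced by rejection
sampling with a retry cap; exactness of the marginal placement distribution
is not claimed.

Densities are Gaussian kernel estimates (`smooth_density()`) with
Scott's-rule bandwidth ($\mathrm{sd}\cdot n^{-1/5}$).  One numerical choice
matters here: the density is evaluated on a bounded grid (0–10 kb by
default), and distances outside the grid range are excluded *before*
bandwidth selection.  The full circular distance set is dominated by
multi-10-kb gaps between clusters; a bandwidth computed from it would be
several kilobases wide and would smooth away precisely the 1.5–2 kb
spacing structure the statistic exists to detect.

# Bayesian quantification models

Three data types share one likelihood family: a normal model on log-scale
responses with one mean per design cell, weakly-informative zero-centred
normal priors on the cell means (scale $2.5\times$ the data SD), a uniform
prior on the residual SD, and — where the design has lineage replicates —
a lineage random intercept.  Sampling is by JAGS (4 chains × 2000
post-warm-up draws by default, seeds fixed per chain); convergence is
monitored by split-$\hat R$ and flagged above 1.01.  The residual-SD prior
has a small positive floor ($0.005\times$ data SD) so that degenerate
noiseless tables (exactly replicated values) remain fittable.

* **Western densitometry** (`fit_western_model()`): response
  $\log(\text{regulator band}/\text{total protein})$ per strain × medium ×
  phase cell with a lineage random intercept.  Reported per cell: the
  posterior mean level relative to wild type in the same medium and phase
  (linear scale), a 95% credible interval, and `P_diff` — the posterior
  probability of a difference versus wild type in the observed direction
  (reported with that direction; by construction $\ge 0.5$).  The scar
  knockout is excluded — it has no band to quantify.
* **ChIP-qPCR** (`fit_chip_qpcr_model()`): per replicate,
  $\Delta C_q = C_q(\mathrm{IP}) - C_q(\mathrm{input})$, minus the mean
  $\Delta C_q$ of two control amplicons, gives a per-replicate log$_2$
  enrichment; the model reports posterior enrichment per strain × amplicon,
  a Savage–Dickey log$_{10}$ Bayes factor against zero enrichment with
  tiers `*` (0.5–1), `**` (1–2), `***` (> 2), and the posterior probability
  of a difference versus the reference strain (`sig.vs.wt`).
* **ΔΔCq expression** (`fit_ddcq_model()`): $\Delta C_q$ against the mean
  of a reference-transcript set, contrasted between mutant and reference
  strain; the sign convention makes positive values mean higher expression
  in the mutant.  The pipeline is exactly linear in log$_2$ fold change.

The Bayes factor (`bayes_factor()`) uses the Savage–Dickey density ratio:
prior density at zero over posterior density at zero, the latter from a
Gaussian kernel density of the MCMC draws.  When the posterior lies so far
from zero that its density there underflows, the log$_{10}$ factor is
capped at ±6 — decisions only require the > 2 tier.  The estimator is
validated in the tests against the closed-form conjugate-normal answer.

# The synthetic-data generator

`sim_config()` + `simulate_truth()` define a synthetic study on a circular
1 Mb replicon (a desk-scale stand-in for the 4.6 Mb chromosome) with 200
TUs and 50 planted primary binding sites, a fraction of them (default 0.4)
placed exactly at TSSs so their TUs become true direct targets.  Each
primary site may carry a shared satellite site offset by 1.2–2 kb (the
spacing band the bridging statistics must detect), and genotypes with
`extra_secondary_rate > 0` (D114E, default rate 1 per primary) gain
genotype-specific satellites.  Each site has a leucine class: *abrogated*
(occupancy scale 0 in LIV) or *reduced* (scale 0.3), assigned 50/50 —
the two classes of leucine response seen at wild-type sites.  The genotype
table encodes the study design: wild type fully leucine-sensitive; L136R
binding slightly stronger (scale 1.2) and leucine-insensitive; D114E
slightly stronger (1.1), leucine-sensitive, satellite-rich; ΔC11 and scar
non-binding.

ChIP tracks are negative-binomial background (mean 50, size 50 — moderate
overdispersion over Poisson, giving a per-bin CV of 0.2 as in
well-sequenced bacterial ChIP input) plus Gaussian enrichment bumps
(SD = peak width/4) of amplitude `snr` × background mean × occupancy
scale.  Replicate noise is multiplicative log-normal per site
(`noise_sd`, default 0.15), and lineages share a small multiplicative
factor, mirroring the lineage/biological replicate hierarchy.  RNAP tracks
place uniform enrichment over TU bodies, shifted by $2^{\text{effect}}$
for planted regulator-dependent effects whose LIV magnitude is the Min
magnitude scaled by the site's residual binding — leucine weakens effects
through binding, and only through binding, which is why the downstream
classifier should (and does) find only reciprocal modes on this model.
Setting `noise_sd = 0` switches the generator into a fully deterministic
noiseless limit (flat background, exact enrichment) used by the
linearity/identity tests.

Quantification tables follow the same logic: Western densities are planted
level × lineage factor × log-normal noise over two bioreps of two lineages;
Cq values are $C_q = \text{base} - \log_2(\text{abundance}) + \text{noise}$
with an IP-fraction cost that cancels in the double difference.

**What the generator does not emulate:** read-level sampling (no FASTQ, no
mapping artefacts), sequence content (no motifs, so no sequence-driven
binding strength), growth dynamics, and any background structure beyond
stationary negative-binomial noise — the background model of real tracks is
not specified by the study and the NB choice is a stand-in.  Passing
recovery tests on this generator therefore validates the *statistical
machinery* (scoring, calling, classification, nulls, models), not the
upstream genomics of any real data set.

# Numerical and reproducibility choices

* Coordinates 0-based half-open everywhere; GFF3 converted at the boundary;
  TSS overlap uses position ∈ [start, end).
* All permutation p-values use the add-one estimator; the smallest
  attainable p is $1/(1+n_\text{perm})$ — e.g. exactly 0.001 at 999
  permutations.
* Every stochastic stage takes an explicit seed; identical configs and
  seeds give identical outputs (tracks byte-identical, MCMC summaries
  reproducible via per-chain RNG seeding).
* Multiple testing by Benjamini–Hochberg; the default `q_cut` is 0.05.
* Reciprocal-overlap fraction for "novel" peaks defaults to 0.25 of both
  peak widths.
* The test suite and acceptance script run the full synthetic study at the
  sizes above (1 Mb genome, 50 sites, 500-trial calibrations, 50-seed
  coverage studies with reduced MCMC chains), chosen so the whole suite
  completes in minutes on a single core.

# Known limitations

The peak caller is a thresholding caller, appropriate for the strongly
z-scored, knockout-subtracted statistic it consumes, not a general-purpose
model-based caller.  The six-mode classifier takes binary binding calls as
given and is only as good as the underlying peak calls at the TSS.  The
bridging null conditions on observed cluster locations; it does not test
*whether* peaks cluster genome-wide (that is what the local-count
comparison is for), only whether spacing within clusters is structured.
The exact-zero residual case in the Bayesian models is handled by a prior
floor rather than a point-mass model.
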