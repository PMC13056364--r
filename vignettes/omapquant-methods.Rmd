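---
title: "Methods and design notes for omapquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for omapquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omapquant)
```

# What the package quantifies

Oligonucleotide-mediated proximity labeling (O-MAP) targets a peroxidase to
a genomic locus via hybridization probes; the enzyme deposits
(desthio)biotin on nearby proteins and chromatin, which are then purified
and read out by imaging, sequencing, or mass spectrometry. Three questions
recur when validating such an experiment, and `omapquant` implements one
quantitative pipeline for each:

1. **Imaging:** does the streptavidin (biotin) signal sit on the FISH
   signal that marks the locus? (`quantify_pair()` and friends)
2. **Sequencing:** is the targeted locus — and any contacting partner locus,
   such as the opposite anchor of a chromatin loop — enriched in the
   pull-down library relative to input? (`enrichment_scores()`,
   `distance_profile()`, `summarize_recovery()`)
3. **Proteomics:** which proteins differ between locus pull-down and
   control conditions? (`protein_tests()`, `call_significant()`)

Every stage can be exercised on seeded synthetic data with known ground
truth (`simulate_puncta_pair()`, `simulate_libraries()`,
`simulate_proteome()`), which is how the package's test suite and
`scripts/acceptance.R` validate it end to end.

# Colocalization scoring

Each channel is preprocessed with a Gaussian blur of standard deviation
$\sigma$ followed by min–max rescaling to $[0,1]$ and a power-law
(gamma) transform $x \mapsto x^\gamma$, then binarized with Otsu's method.
Because neither $\sigma$ nor $\gamma$ is knowable a priori for an arbitrary
micrograph, both are chosen by grid search, independently per image and per
channel: each candidate mask is scored by the percentage of its foreground
pixels whose intensity in the *raw* channel strictly exceeds the raw
channel's 90th percentile, and the highest-scoring mask wins.

With $F$ the FISH foreground and $S$ the streptavidin foreground, the
reported metrics are

- labeling efficiency $= 100\,|F \cap S| / |F|$,
- specificity $= 100\,|F \cap S| / |S|$,
- Jaccard index $= |F \cap S| / |F \cup S|$.

## Numerical choices

Several details of this procedure are underdetermined by its verbal
description; the package fixes them explicitly so results are reproducible:

- **Otsu on arbitrary dtypes.** The image is min–max scaled and quantized
  to 256 gray levels before the between-class-variance search, reproducing
  classic 8-bit behavior for 16-bit and float inputs and making the mask
  invariant to positive affine intensity maps. Criterion ties break toward
  the smallest level.
- **Strict inequalities.** Foreground is strictly greater than the Otsu
  threshold, and a pixel "exceeds" the 90th percentile only if strictly
  greater — one consistent convention at both cuts.
- **Percentile rule.** The 90th percentile uses linear interpolation
  (`stats::quantile` type 7) over all pixels of the raw channel.
- **Scoring against the raw image.** Scoring candidate masks against the
  preprocessed image would let the optimizer reward transforms that inflate
  their own output; the raw channel is the fixed reference instead.
- **Grid defaults.** $\sigma \in \{0.5, 1, 2, 4, 8\}$ px spans sub-spot to
  multi-spot smoothing for typical puncta a few pixels wide;
  $\gamma \in \{0.5, 1, 2, 3, 4\}$ covers contrast expansion and
  compression. Both grids are arguments. Score ties break toward the
  smallest $\sigma$, then the smallest $\gamma$ — the least-processed
  candidate.
- **Degenerate inputs.** A constant (pre)processed image cannot be
  thresholded; such parameter sets are skipped inside the grid search and
  flagged (`is_degenerate()`) elsewhere, rather than aborting a batch.
  Empty masks score 0, and empty-denominator metrics are 0, likewise
  flagged.
- **Whole-image metrics.** No nucleus or ROI segmentation is applied; the
  metrics run over all pixels. Restricting to segmented regions is the
  caller's responsibility if desired.
- **Blur kernel at image edges.** The Gaussian kernel radius is capped at
  the image size so large $\sigma$ remains usable on small crops
  (EBImage's `gblur` otherwise rejects kernels larger than the image).

# Bin-based genomic enrichment

The genome is tiled into fixed windows (100 kb by default; terminal bins
may be short). Reads are assigned to bins by the 0-based midpoint of their
interval, $\lfloor(start+end)/2\rfloor$, so a read straddling a bin edge is
counted exactly once. For each library a pseudocount equal to
`pseudocount_fraction` (default 0.10) times *that library's total read
count* is added to every bin, per-bin fractions are recomputed over the
pseudocounted sums, and the score of bin $b$ is

$$\mathrm{score}(b) =
\frac{\mathrm{frac}_{\mathrm{input}}(b)}{\mathrm{frac}_{\mathrm{pulldown}}(b)}.$$

Two points deserve emphasis:

- **The pseudocount is deliberately large.** Ten percent of the library
  total added to every bin is a strong shrinkage toward 1 — with hundreds
  of bins the pseudocount dwarfs typical per-bin counts, so only strong
  enrichment stands out. This is implemented literally because the rule is
  unambiguous arithmetic; a gentler `pseudocount_mode = "per_bin_mean"`
  (the same fraction of the library's mean per-bin count) is provided and
  clearly labeled as the alternative interpretation.
- **Orientation.** The formula above (`orientation = "as_printed"`) puts
  input in the numerator, so an enriched locus scores *below* 1. Because
  plots and rankings usually want enriched loci high, an `"inverted"`
  orientation returns the per-bin reciprocal, and the orientation used is
  stamped into every profile. `summarize_recovery()` always ranks with
  pull-down enrichment oriented upward, whatever the stored orientation.

Distance profiles report, for every bin, the base-pair distance from the
bin midpoint to the nearest point of the nearest same-chromosome target
region. Bins overlapping a target form the on-target (distance 0) stratum
and are excluded from the $\log_{10}$ axis, since $\log 0$ is undefined;
bins on chromosomes without targets are excluded entirely. Strand is
ignored throughout (DNA-level counting). BED input/output uses 0-based
half-open coordinates via `rtracklayer`; BAM users can convert alignments
to BED upstream (`bedtools bamtobed`), keeping this module free of
alignment tooling.

# Differential proximity proteomics

Intensity matrices (proteins × samples) are column-normalized so every
sample sum equals the mean of the original sums — removing loading
differences while preserving within-sample ratios — and tests run on
$\log_2$ intensities, which stabilizes variance and makes effect sizes
directly interpretable as $\log_2$ fold changes. Per protein, a two-sided
t-test compares the two conditions of the contrast: Welch's variant
(Welch–Satterthwaite degrees of freedom) is the default for pairwise
comparisons; Student's pooled-variance variant is available. P-values are
Benjamini–Hochberg adjusted per contrast across all tested proteins, and
the significance gate is strict on both sides:
$|\log_2 FC| > 1$ and $q < 0.05$ by default, with $q < 0.1$ the
conventional relaxed screen.

Handling of imperfect data is explicit: zero intensities are floored at
the smallest nonzero value of the matrix before $\log_2$ (count recorded),
proteins with fewer than two quantified replicates in either condition are
skipped and listed in the `skipped` attribute, and zero-variance proteins
with equal means get $p = 1$ (and $p = 0$ with infinite $t$ when the means
differ — only reachable with noiseless synthetic data). Batch correction
is out of scope; an externally corrected matrix can be passed directly
with `normalize = FALSE`.

A calibration note: with four replicates per group, Welch's test is
slightly conservative (its true size at the 0.05 level is about 0.042
under equal-variance normal noise, because the Satterthwaite degrees of
freedom are estimated). The test suite therefore checks p-value
calibration with the Student variant, whose size is exact under the
generator's noise model, and separately checks that the Welch rate does
not exceed nominal. On real data with unequal variances Welch is the safer
default, which is why it remains the package default.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed and the tests run against them.

**Puncta pairs.** Spots are isotropic 2-D Gaussians (default
$\sigma = 1.5$ px, amplitude 1) on a constant background (0.1) with
additive Gaussian noise (sd 0.05, clipped at zero; a Poisson photon mode
is available behind `noise_model = "poisson"`). A fraction of streptavidin
spots share FISH centers exactly; the rest are placed independently, with
all centers kept at least $5\sigma$ apart so planted overlap is
unambiguous and ground-truth discs (radius $2\sigma$) never touch. These
sizes emulate diffraction-limited puncta at typical confocal sampling;
they do not model PSF structure, 3-D stacks, spectral bleed-through, or
camera-specific noise, so passing tests demonstrate correctness of the
quantification, not robustness to every real-world artifact.

**Read libraries.** Input reads are multinomial over bins with uniform
probability; pull-down probability is the uniform background times
`fold_enrichment` at target bins and times
$1 + f_p (fe - 1) e^{-d/\lambda}$ around partner bins, with $d$ the
distance to the nearest partner-bin midpoint, $\lambda$ the decay length
(two bins by default), and $f_p$ = `partner_peak_fraction` = 0.75. The
sub-unity partner peak encodes that partner loci are recovered indirectly
— through the chromatin contact rather than by direct probe hybridization
— and keeps "the directly targeted bin ranks first genome-wide" a
well-posed expectation; only the monotone decay of partner signal is
relied on downstream. Depths of $10^5$ reads over a few hundred 100-kb
bins keep simulations fast while giving per-bin counts (~200) large enough
for rank statistics to be stable.

**Proteomes.** $\log_2$ intensities are baseline (uniform 6–14) plus the
planted condition effect plus Gaussian replicate noise (sd 0.25 by
default, a typical replicate CV for multiplexed quantification); planted
effects of $|\log_2 FC| = 2$ in both directions emulate clear
locus-specific enrichment. The default validation fixture plants 50
effects among 1000 proteins with 4 vs 4 replicates.

All generators take an explicit seed and use R's default generator via
`withr::with_seed`, so identical arguments give bit-identical output
without disturbing the caller's RNG stream.

# Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` use: 200 random images up to
32×32 for the exhaustive Otsu cross-check; 500 random mask pairs for the
metric algebra; 20 puncta images against full grid re-evaluation; 10 seeds
× 5 overlap levels on 96×96 images for monotone Jaccard recovery; 20
seeded library simulations (500 bins, depth $10^5$, fold 10) for planted
locus recovery; 1000 random p-vectors against brute-force
Benjamini–Hochberg; and 2000-protein null plus 20 seeded planted-effect
proteomes for calibration and power. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick to run.

# Known limitations

- The colocalization stage is 2-D and mask-based; it does not count spots,
  compute Pearson/Manders coefficients, or handle 3-D stacks.
- The enrichment stage starts from read intervals; alignment, duplicate
  marking, and track smoothing live upstream. No peak calling or Hi-C
  contact modeling is attempted.
- The differential stage tests one contrast at a time with per-contrast
  BH; it does not roll peptides up to proteins, model batch effects, or
  compute interaction-network scores.
- Synthetic fixtures demonstrate correctness of the implemented
  procedures under their stated models; they are not evidence about any
  particular real dataset.
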