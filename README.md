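# omapquant

Quantification pipelines for validating locus-specific proximity labeling
(DNA O-MAP): experiments in which hybridization probes recruit a
peroxidase to a chosen genomic locus so that nearby proteins and chromatin
are biotinylated, purified, and read out by imaging, sequencing, or
quantitative mass spectrometry. `omapquant` answers the three validation
questions such experiments raise, each with a self-contained, tested
pipeline:

- **Colocalization (imaging).** Does the streptavidin/biotin stain land on
  the FISH signal marking the locus? Each channel is preprocessed with a
  Gaussian blur (σ) and power-law transform (γ) chosen by per-channel grid
  search, binarized with Otsu's method, and each candidate mask is scored
  by the percentage of its foreground pixels exceeding the raw image's
  90th intensity percentile. With foregrounds *F* (FISH) and *S*
  (streptavidin) the pipeline reports labeling efficiency
  100·|F∩S|/|F|, specificity 100·|F∩S|/|S|, and the Jaccard index
  |F∩S|/|F∪S|.
- **Genomic enrichment (sequencing).** Is the targeted locus — and any
  contacting partner locus, e.g. the opposite anchor of a chromatin
  loop — enriched in pull-down vs input? The genome is tiled into 100 kb
  windows, reads are assigned to bins by interval midpoint, a pseudocount
  of 10% of each library's total reads is added to every bin, and each
  bin is scored by the ratio of pseudocounted read fractions,
  score(b) = frac_input(b) / frac_pulldown(b)
  (with an `inverted` orientation so enriched loci can rank high),
  plus log-distance profiles around the target regions and genome-wide
  rank summaries.
- **Differential proteomics (mass spec).** Which proteins differ between
  pull-down and control? Column normalization for total protein, per-protein
  two-sided t-tests on log2 intensities (Welch by default),
  Benjamini–Hochberg q-values, and strict significance gates
  (|log2FC| > 1 and q < 0.05 by default).

Because the raw data behind such experiments is large and external, the
package ships seeded synthetic-data generators with known ground truth —
punctate two-channel images with a controlled colocalized fraction,
input/pull-down read libraries with planted fold enrichment and
distance-decaying partner signal, and replicate intensity matrices with
planted log2 effects — so the entire pipeline is testable end to end on a
laptop. See the methods vignette (`vignettes/omapquant-methods.Rmd`) for
models, parameter defaults, and design rationale.

## Worked example

```r
library(omapquant)

# --- imaging: 12 spots, 75% of streptavidin spots on FISH centers ---
pair <- simulate_puncta_pair(96, 96, n_spots = 12,
                             overlap_fraction = 0.75, seed = 42)
q <- quantify_pair(pair$fish, pair$strep)
q$fish_mask
#> <binary_mask> 96 x 96 px, sigma = 0.5, gamma = 0.5, score = 100.00%, 328 fg px
q$metrics[c("labeling_efficiency", "specificity", "jaccard")]
#> efficiency 71.0%  specificity 68.7%  jaccard 0.537
```

With three-quarters of the streptavidin spots planted on FISH centers,
about 70% of each mask's foreground overlaps the other and the Jaccard
index lands near the planted overlap fraction — at full overlap it rises
above 0.85, at zero overlap it drops to ~0.

```r
# --- sequencing: planted locus + contacting partner on a 50 Mb chromosome ---
sim <- simulate_libraries(c(chr3 = 5e7), bin_size_bp = 1e5,
                          target_bins = 250, partner_bins = 400,
                          fold_enrichment = 10, depth_input = 1e5,
                          depth_pulldown = 1e5, seed = 42)
prof <- enrichment_scores(sim$input, sim$pulldown)
prof
#> <enrichment_profile> 500 bins, orientation as_printed, pseudocount 0.1 x total
#>   score range [0.8563, 1.007], median 1.001
summarize_recovery(prof, 250L, 400L)[c("best_target_rank",
                                       "median_partner_rank",
                                       "median_background_rank")]
#> target rank: 1 | partner median rank: 2 | background median rank: 251.5
```

The as-printed score puts input in the numerator, so the enriched target
bin has the *smallest* score (0.856) while background sits at ~1; the
recovery summary ranks with pull-down enrichment oriented upward, placing
the targeted bin first genome-wide and the partner anchor right behind it.

```r
# --- proteomics: 50 planted effects among 1000 proteins, 4 vs 4 ---
prot <- simulate_proteome(1000, n_affected = 50, seed = 42)
tab <- run_diffprot(prot$intensities, prot$design,
                    contrast = c("pulldown", "control"))
sum(tab$significant)
#> 50
head(tab[order(tab$q_value), c("protein", "log2fc", "q_value")], 3)
#>     protein    log2fc      q_value
#> 967   P0967 -2.154268 2.991939e-05
#> 128   P0128 -2.170640 2.027042e-04
#> 299   P0299  1.957117 2.027042e-04
```

All 50 significant calls at the |log2FC| > 1, q < 0.05 gates are planted
effects (sensitivity 1.0, false-discovery proportion 0.0 at this seed).

A command-line wrapper with `simulate`, `coloc`, `enrich`, `diffprot`,
and `demo` subcommands is installed at `inst/cli/omap-quant.R`; the `demo`
subcommand runs all three stages on generated fixtures and writes a
deterministic JSON/markdown report.

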