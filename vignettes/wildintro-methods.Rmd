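---
title: "Models and methods behind wildintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wildintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wildintro)
```

# Scope

`wildintro` studies how chromosome segments from a wild relative (an
*Aegilops tauschii*-like donor) move into a crop genome (hexaploid-wheat-like
recipient) through one backcross and selfing by single seed descent. It has
three layers:

1. a forward simulator of the crossing scheme, emitting genotypes plus the
   true donor-origin mosaic of every line;
2. a parent-informed identity-by-descent (IBD) segment caller for biallelic
   SNP dosages;
3. the window statistics used to characterise introgression: recombination
   breakpoints and hotspot windows with permutation-overlap enrichment,
   nucleotide diversity, parental sequence divergence (SD), introgression
   frequency (IF) and efficiency, pericentromeric/distal comparisons, and a
   locus-level selection scan.

The numbered scripts under `analysis/` run the layers in order and write
their tables under `results/run/`.

# The simulator

## Genome and recombination map

The default desk-scale genome is 7 chromosomes of 60 Mbp with the
centromere at 40% of the length — a ~10x compression of wheat D-genome
chromosomes that keeps end-to-end runs to seconds while preserving arm
asymmetry. Full-scale lengths can be passed through `chrom_specs()`.

Recombination in large cereal genomes is strongly suppressed around the
centromere. The default map (`default_recomb_map()`) gives each chromosome
1.5 Morgans, splits it between arms in proportion to arm length, and places
90% of each arm's map length in the terminal third of the arm. Crossover
counts per meiosis are Poisson with the map length as mean (no
interference — the simplest defensible model, and interference does not
enter any statistic tested here); positions follow the local intensity by
inverse-CDF sampling.

## Founders and divergence

Each founder is fully inbred (one haplotype). Donor accessions belong to
two lineages differing in divergence from the recipient: *strangulata*
(the direct D-genome progenitor, low divergence) and *tauschii* (high
divergence). Divergence is a single rate per lineage — expected
donor/recipient polymorphic sites per Mbp, placed uniformly at random —
with 70% of a lineage's sites shared by all its accessions and the rest
accession-private. Recipient lines are near-identical, polymorphic at one
tenth of the *strangulata* rate.

The desk defaults are `strangulata = 2.94` and `tauschii = 11.56` sites/Mbp.
These re-express the pericentromeric field calibration (1.47 vs 5.78 SNPs
per 5 Mbp window, a 3.9-fold ratio) at a density that compensates the 10x
genome compression, so each chromosome carries a realistic number of
informative markers per family (roughly 180-700) and segments remain
callable under the default marker-support filters. The lineage *ratio*, the
quantity the recovery tests check, is preserved exactly.

## Pedigree and selection

A family is one recipient x one donor. The F1 carries one recipient and
one donor haplotype per chromosome (the synthetic-octoploid intermediate
is not simulated: the D-genome analyses never use A/B segregation). Each
progeny line descends from an independent backcross plant: BC1 to the
recipient, then `selfing_generations` rounds of single seed descent
(default 2, i.e. BC1F3; the generation count is exposed because field
programmes often advance further before genotyping). Under neutrality the
expected donor *allele* fraction after one backcross is 25% at any
selfing depth, while the expected heterozygous fraction at BC1F3 is
1/2 x (1/2)^2 = 12.5% (one-locus Markov chain: 11/16 recipient-hom, 2/16
het, 3/16 donor-hom).

Selection models the tenacious-glume situation: a line carrying at least
one donor allele at the locus is discarded with probability `s` and the
family resampled to size, by default at the final (phenotyping) generation.
Only single-locus selection is modelled; polygenic or divergence-dependent
selection is out of scope (see "Known limitations").

## Genotyping noise

Dosages (donor-allele counts 0/1/2) are observed through GBS-style noise:
each entry independently missing with `missing_rate` (default 0.2) and,
if observed, flipped to a random other dosage with `genotype_error_rate`
(default 0.005, imputation-grade data being cleaner than raw GBS). Zero
noise reproduces truth exactly — a tested invariant.

# The segment caller

The field workflow inferred IBD with an external phased-haplotype caller.
Here parents are available and phasing is not, so the package substitutes a
parent-informed three-state hidden-path decoder, validated by truth
recovery rather than by matching the external tool:

* **Informative sites**: donor and all recipient parents homozygous,
  non-missing, and different. Heterozygous or missing parent calls make a
  site non-informative for that family.
* **Emission**: observed donor dosage equals the state's dosage with
  probability `1 - epsilon`, otherwise `epsilon/2` on each mismatch;
  missing observations are uninformative.
* **Transition**: over distance `d`, the state is redrawn uniformly with
  probability `1 - exp(-switch_rate * d)`, so the stay probability tends to
  1 as `d -> 0`.
* **Decoding**: Viterbi; segment boundaries at midpoints between flanking
  informative sites (unbiased under uniform crossover placement within the
  marker gap), chromosome ends extended to the informative-site span.
  Donor segments with fewer than `min_markers = 5` sites or shorter than
  `min_length` (0.2 Mbp at desk scale, 1 Mbp at full scale) are relabelled
  recipient. Scores are mean posteriors from the forward-backward pass.

`switch_rate` should approximate the expected breakpoint density: with ~4
effective meioses of a 1.5-Morgan, 60-Mbp chromosome that is
4 x 1.5 / 60e6 = 1e-7 per bp (the desk default); full-scale wheat
chromosomes are ~10x longer, giving ~1e-8. Decoding is exact — on every
instance with up to 12 sites the decoded path attains the exhaustive
enumeration maximum — and robust: an isolated genotyping error costs
~5.3 log units while opening and closing a segment costs ~8, so single
errors do not fragment segments.

On the default desk simulation the caller reaches length-weighted
precision ~0.99 and recall ~0.956, with median boundary error ~1.4x the
median informative-marker spacing. The residual recall loss is structural:
short distal donor tracts falling under the marker-support filters, and
the uncalled chromosome tails outside the informative span.

# Window statistics

* **Donor proportion** divides total donor-segment length by the genome
  size (4.3 Gb for real *Ae. tauschii* data; the simulated genome size at
  desk scale) and **efficiency** divides by the 25% pedigree expectation.
  Heterozygous segments count full length by default, matching the
  length-based field formula; note this makes the call-based proportion an
  overestimate of the allele-dosage fraction while residual heterozygosity
  persists (carrier expectation 31.25% at BC1F3 vs 25% dosage-weighted) — a
  `het_weight` flag selects the dosage-weighted convention.
* **Breakpoints** are allele-phase transitions between consecutive
  non-missing within-family codes after the within-family major/minor
  recode. The recode matters: raw alt-dosages are phase-inverted wherever
  the recipient carries the alt allele, and each such site would fake two
  transitions; with recipient ancestry in the majority (11/16), the major
  allele is almost always the recipient allele, making recoded codes
  phase-consistent. A 0->2 step counts as one transition (one observable
  phase change). Breakpoint scanning is meant for imputation-grade
  genotypes: at GBS noise levels every isolated error fakes two
  transitions (61,598 vs 3,308 transitions on the default desk run).
* **Windows**: breakpoint midpoints are counted in 2 Mbp windows sliding
  by 1 Mbp (each interior midpoint falls in exactly two windows);
  **hotspots** are windows at or above the 95th percentile (linear
  interpolation) of totals over windows with at least one breakpoint —
  computing the percentile over non-zero windows keeps the threshold from
  collapsing under zero inflation. **Overlap enrichment** against a second
  population draws both hotspot-set sizes uniformly without replacement
  from the shared non-zero-window universe, giving the hypergeometric null
  mean `kA * kB / M`.
* **pi** uses the unbiased pairwise estimator on haplotype counts,
  `2 j (2n - j) / (2n (2n - 1))`, smoothed over 10 consecutive defined
  sites advancing by 2. **SD** counts sites with differing non-missing
  parent genotypes per non-overlapping 5 Mbp window (het-vs-hom counts as
  divergent), averaged across a family group's parent pairs.
* **Regions**: each arm's terminal third is distal, the inner two-thirds
  pericentromeric (the per-arm reading of the "2/3" convention; a
  per-chromosome alternative would shift the boundary on asymmetric arms).
  Group comparisons use the Mann-Whitney U test (exact for combined
  n <= 20 without ties), family comparisons the Kruskal-Wallis test — both
  through the standard `stats` implementations.
* **Selection scan**: donor- and recipient-segment counts per 1-kb window
  (tiled; a sub-window step is configurable) across a region; the dip is
  the donor-track minimum, reported at the centre of the minimising run
  because complete selection produces a tied run of zeros.

# What the simulation does and does not show

The generator reproduces the study conditions: the crossing scheme, the
pericentromere-suppressed landscape, two donor lineages with a ~4-fold
divergence contrast, GBS-like sparsity, and single-locus selection. Tests
against it therefore validate the *machinery* — segment recovery,
breakpoint counting, window statistics, permutation calibration — and the
process-level patterns that follow from the design: the U-shaped
introgression frequency (any-overlap window IF rises with local
recombination), its positive correlation with breakpoint density, and
linkage drag (the donor-depleted region around a selected locus widens
~6-fold when the locus sits in the suppressed pericentromere).

It does not reproduce patterns whose cause the model deliberately omits.
The field data's *negative* IF~SD relation is attributed to selection
against divergent donor chromatin (negative multilocus epistasis); under
neutrality truth-level IF is flat in SD, and detection-side effects (denser
markers where divergence is high, hence better segment and double-crossover
recovery) push the measured relation mildly positive. The corresponding
acceptance check is left failing by design rather than met by an
artificial mechanism. Real data also differ in ways the generator ignores:
linkage disequilibrium within lineages, marker ascertainment,
non-uniform site placement, and polygenic phenology selection.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; VCF (1-based) and BED
  convert at the boundary.
* MAF filtering keeps the boundary on both sides (MAF == threshold kept,
  missingness == cap kept), reading "less/greater than ... filtered out"
  literally. Any non-0/1/2 entry counts as missing.
* The decoder errors on non-finite likelihoods (epsilon at 0 or 0.5);
  chromosomes with fewer than 20 informative sites are flagged uncallable
  and yield no calls rather than unstable ones.
* All-tied rank tests return p = 1 with a warning; empty hotspot
  universes return empty sets with a warning.
* Permutation p-values use the add-one estimator `(1 + #{null >= obs}) /
  (n_perm + 1)`. Because the overlap statistic is integer-valued, its test
  is slightly conservative for small sets; the calibration check uses set
  sizes comparable to the field data (hundreds of windows), where the
  nominal level is attainable.
* Determinism: every stochastic entry point takes an explicit seed, and a
  global seed derives per-family seeds by fixed offsets (+1000 per
  family); identical seeds give byte-identical outputs.

# Problem sizes

Default test and analysis runs use the desk genome (7 x 60 Mbp), 6
families x 30 lines (~10,000 segregating sites, 188 samples), 500 lines
for the pedigree expectation, 1,000 decoder-oracle instances, 20 seeds for
the U-shape check, and 1,000-replicate calibrations of the rank tests and
the permutation null. These sizes keep every Monte-Carlo standard error
small relative to its acceptance band while the full suite runs in a few
minutes.

# Known limitations

* Only single-locus, carrier-discard selection; no polygenic or
  divergence-coupled fitness.
* No crossover interference; no structural variation; sites are placed
  uniformly, not by gene density or ascertainment.
* The caller assumes inbred, correctly labelled parents; heterozygous
  parent sites are discarded, not modelled.
* Statistical phasing/imputation is out of scope; the breakpoint scan
  expects imputation-grade input.
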