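# wildintro

Simulation and detection of wild-relative introgression in backcross wheat
populations.

Breeding programmes move chromatin from wild relatives such as *Aegilops
tauschii* into bread wheat by crossing, backcrossing once, and selfing by
single seed descent (BC1F3-style populations). Where the donor segments
land, how long they are, and how much of the donor genome survives depend
on the recombination landscape (crossovers concentrate in distal
chromosome ends; the pericentromeric two-thirds of each arm is strongly
suppressed), on parental sequence divergence, and on phenotypic selection
against wild alleles such as *Tg* (tenacious glume). `wildintro` provides,
for geneticists and breeders working with such populations:

* a **forward simulator** of the crossing scheme — pericentromere-suppressed
  recombination map, two donor lineages (*ssp. strangulata* low divergence,
  *ssp. tauschii* high), GBS-style genotype noise, optional single-locus
  selection — emitting genotypes plus the true donor-origin mosaic of every
  line;
* a **parent-informed IBD segment caller**: at family-informative sites
  (parents homozygous and different) progeny donor-allele dosages are
  decoded through a three-state hidden path (recipient / heterozygous
  donor / homozygous donor) with emission error `epsilon` and
  distance-dependent switching, boundaries at inter-marker midpoints;
* the **population statistics** of introgression studies: donor proportion
  (total donor segment length / genome size x 100) and efficiency
  (proportion / 25% x 100), per-chromosome IBD length summaries,
  recombination breakpoints from allele-phase transitions, 2-Mbp/1-Mbp
  sliding-window breakpoint counts with 95th-percentile hotspot calling and
  permutation-overlap enrichment, sliding-window nucleotide diversity
  (pi, 10 SNPs forward by 2), parental sequence divergence per 5 Mbp
  window, pericentromeric/distal Mann-Whitney comparisons, and a 1-kb
  selection scan around a selected locus.

Coordinates are 0-based half-open internally; VCF/BED I/O converts at the
boundary.

## Worked example

The numbered scripts under `analysis/` run the whole workflow at desk
scale (7 chromosomes x 60 Mbp, 6 families x 30 BC1F3 lines) and write
their tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_genotypes.R
Rscript analysis/03_call_segments.R
Rscript analysis/04_recombination.R
Rscript analysis/05_diversity_divergence.R
Rscript analysis/06_selection_scan.R
```

Output of the run committed to this repository's defaults (seed 1):

```
simulated 180 progeny at 9798 sites; true donor genome fraction: mean 25.5% (range 1.9-68.8%)
retained at MAF >= 0.01, missingness <= 30%: 9767 sites
recovery vs truth: precision 0.992, recall 0.957 (length-weighted), median boundary error 164170 bp
donor proportion per line: 1.69-74.83% (mean 30.78%); efficiency 6.8-299.3%
phase transitions: 3308 on imputation-grade genotypes vs 61598 on raw GBS-noise genotypes
hotspot threshold 48.8 RBP/window; 21 hotspot windows (universe: 406 windows with >= 1 RBP)
breakpoint counts across families: Kruskal-Wallis chi2 = 6.9, p = 0.229
hotspot overlap, fine-structured shared map: 17 observed vs 1.05 expected (16.3-fold, p = 0.000999)
parental SD per 5 Mbp window: strangulata 10.33, tauschii 37.72 (3.7-fold)
if_count distal vs pericentromeric: mean 76.0 vs 61.6, Mann-Whitney p = 5.53e-08
selection at 4.0 Mbp (distal): donor-track dip at 4.03 Mbp; depleted region 6.5 Mbp wide
selection at 30.0 Mbp (pericentromeric): depleted region 46.3 Mbp wide (linkage drag)
```

Reading the numbers: the true donor fraction averages ~25% as the pedigree
predicts, while the call-based proportion (mean 30.8%) uses the
full-length-heterozygous convention and so sits near the 31.25% carrier
expectation. The segment caller recovers the simulated truth at 0.99
precision / 0.96 recall with boundary error comparable to the marker
spacing. Introgression frequency is U-shaped (higher in distal windows,
p = 5.5e-8) and tracks breakpoint density; a fully selected locus carves a
donor-free dip at its true position that widens ~7-fold when the locus
sits in the recombination-suppressed pericentromere. See
`vignettes/wildintro-methods.Rmd` for the models, defaults and
limitations.

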