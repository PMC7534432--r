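# Shared fixture builders. Small genomes keep individual tests fast; the
# cached default desk-scale simulation is shared by the heavier tests.

tiny_specs <- function(n = 2, L = 10e6, cen_frac = 0.4)
  chrom_specs(paste0("chr", seq_len(n), "D"), rep(L, n), rep(L * cen_frac, n))

tiny_sim <- function(seed = 7, n_lines = 6, noise = noise_spec(0, 0),
                     specs = tiny_specs(), sspec = NULL) {
  simulate_population(
    specs = specs,
    fspec = founder_spec(n_recipient_lines = 1,
                         donor_lineage = c("strangulata", "tauschii")),
    pspec = pedigree_spec(n_lines_per_family = n_lines),
    nspec = noise,
    recomb_map = default_recomb_map(specs),
    sspec = sspec, seed = seed)
}

# build a geno object directly from a code matrix (sites x samples)
make_geno <- function(gt, chrom = "chr1D", pos = NULL) {
  gt <- as.matrix(gt)
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 1e5
  if (is.null(colnames(gt))) colnames(gt) <- paste0("S", seq_len(ncol(gt)))
  geno_matrix(gt, data.frame(chrom = chrom, pos = pos,
                             id = paste0("v", seq_len(nrow(gt))),
                             ref = "A", alt = "T"))
}

# family bundle wrapper for hand-built matrices: first column donor parent,
# second recipient parent, rest progeny
make_bundle <- function(gt, chrom = "chr1D", pos = NULL) {
  g <- make_geno(gt, chrom, pos)
  list(geno = g, family = "FAM01",
       progeny = g$samples[-(1:2)],
       recipient_parents = g$samples[2], donor_parent = g$samples[1],
       excluded = FALSE)
}

.sim_cache <- new.env(parent = emptyenv())

# default desk-scale simulation shared across heavy tests
cached_default_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_population(seed = seed)
  .sim_cache[[key]]
}

cached_default_calls <- function(seed = 1) {
  key <- paste0("calls", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_default_sim(seed)
    gf <- filter_variants(sim$geno, 0.01, 0.30)
    .sim_cache[[key]] <- call_segments_all(gf, sim$metadata, min_progeny = 1)
  }
  .sim_cache[[key]]
}
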