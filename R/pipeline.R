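#' Parse a plain-text key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; keys are
#' dot-namespaced by module (e.g. `simulate.n_lines_per_family = 30`).
#' Values are parsed as numbers where possible, `TRUE`/`FALSE` as logicals,
#' comma-separated values as vectors. Unknown keys error.
#'
#' @param path config file path (optional).
#' @param overrides named list applied after the file (flag-style
#'   overrides).
#' @return Named list of configuration values merged over the defaults
#'   ([default_run_config()]).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  apply_kv <- function(cfg, key, value) {
    if (!key %in% names(cfg))
      stop("unknown config key: ", key)
    cfg[[key]] <- value
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[trimws(lines) != ""])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); raw <- trimws(kv[2])
      vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(vals))
      value <- if (!any(is.na(num))) num
      else if (all(vals %in% c("TRUE", "FALSE"))) as.logical(vals)
      else vals
      cfg <- apply_kv(cfg, key, value)
    }
  }
  for (k in names(overrides)) cfg <- apply_kv(cfg, k, overrides[[k]])
  cfg
}

#' Default run configuration (desk scale)
#' @return Named list of all recognised configuration keys.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    scale = "desk",
    simulate.n_chrom = 7,
    simulate.chrom_length_bp = 60e6,
    simulate.centromere_frac = 0.4,
    simulate.morgans_per_chrom = 1.5,
    simulate.distal_share = 0.9,
    simulate.n_recipient_lines = 2,
    simulate.n_strangulata = 3,
    simulate.n_tauschii = 3,
    simulate.divergence_strangulata = 2.94,
    simulate.divergence_tauschii = 11.56,
    simulate.n_lines_per_family = 30,
    simulate.n_backcrosses = 1,
    simulate.selfing_generations = 2,
    simulate.missing_rate = 0.2,
    simulate.genotype_error_rate = 0.005,
    simulate.selection_s = 0,
    simulate.selection_chrom = "chr2D",
    simulate.selection_bp = 4e6,
    filter.maf_min = 0.01,
    filter.max_missing = 0.30,
    segments.epsilon = 0.01,
    segments.switch_rate = 1e-7,
    segments.min_markers = 5,
    segments.min_length = 2e5,
    recomb.window = 2e6,
    recomb.step = 1e6,
    recomb.hotspot_percentile = 95,
    popstats.window = 5e6,
    popstats.pi_window = 10,
    popstats.pi_step = 2)
}

sim_from_config <- function(cfg) {
  specs <- default_chrom_specs(cfg$simulate.n_chrom,
                               cfg$simulate.chrom_length_bp,
                               cfg$simulate.centromere_frac)
  fspec <- founder_spec(
    n_recipient_lines = cfg$simulate.n_recipient_lines,
    donor_lineage = c(rep("strangulata", cfg$simulate.n_strangulata),
                      rep("tauschii", cfg$simulate.n_tauschii)),
    divergence_rate = c(strangulata = cfg$simulate.divergence_strangulata,
                        tauschii = cfg$simulate.divergence_tauschii))
  pspec <- pedigree_spec(cfg$simulate.n_backcrosses,
                         cfg$simulate.selfing_generations,
                         cfg$simulate.n_lines_per_family)
  nspec <- noise_spec(cfg$simulate.missing_rate,
                      cfg$simulate.genotype_error_rate)
  sspec <- if (cfg$simulate.selection_s > 0)
    selection_spec(cfg$simulate.selection_chrom, cfg$simulate.selection_bp,
                   s = cfg$simulate.selection_s) else NULL
  map <- default_recomb_map(specs, cfg$simulate.morgans_per_chrom,
                            cfg$simulate.distal_share)
  simulate_population(specs, fspec, pspec, nspec, map, sspec,
                      seed = as.integer(cfg$seed))
}

#' Run the whole analysis pipeline
#'
#' simulate -> write genotypes/metadata/truth -> filter -> per-family
#' segment calling -> breakpoints, hotspots -> diversity, divergence,
#' window statistics -> selection scan track. All tables are written under
#' `outdir` as TSV (BED/VCF where appropriate) along with a run manifest;
#' the run is deterministic given the seed.
#'
#' @param config path to a key=value config file, or a config list from
#'   [read_run_config()], or `NULL` for defaults.
#' @param outdir output directory (created if needed).
#' @param seed overrides the config seed when non-NULL.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the main in-memory results (`sim`,
#'   `calls`, `breakpoints`, `hotspots`, `wstats`, `manifest`).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL, quiet = FALSE) {
  cfg <- if (is.list(config)) config else read_run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[wildintro] ", ...)
  t0 <- Sys.time()

  say("simulate: ", cfg$simulate.n_strangulata + cfg$simulate.n_tauschii,
      " families x ", cfg$simulate.n_lines_per_family, " lines, seed ",
      cfg$seed)
  sim <- sim_from_config(cfg)
  write_vcf(sim$geno, file.path(outdir, "genotypes.vcf"))
  write_metadata(sim$metadata, file.path(outdir, "metadata.tsv"))
  write_truth_bed(sim$truth, file.path(outdir, "truth.bed"))
  write_chrom_specs(sim$specs, file.path(outdir, "chrom_specs.tsv"))

  say("filter: MAF >= ", cfg$filter.maf_min, ", missingness <= ",
      cfg$filter.max_missing)
  gf <- filter_variants(sim$geno, cfg$filter.maf_min, cfg$filter.max_missing)

  say("segments: calling ", length(unique(sim$metadata$family)), " families")
  calls <- call_segments_all(gf, sim$metadata,
                             epsilon = cfg$segments.epsilon,
                             switch_rate = cfg$segments.switch_rate,
                             min_markers = cfg$segments.min_markers,
                             min_length = cfg$segments.min_length,
                             min_progeny = 1)
  write_segments_bed(calls, file.path(outdir, "segments.bed"))
  genome <- sum(sim$specs$length_bp)
  prop <- donor_proportion(calls, genome)
  eff <- introgression_efficiency(prop)
  utils::write.table(
    data.frame(sample = names(prop), donor_pct = as.numeric(prop),
               efficiency_pct = as.numeric(eff)),
    file.path(outdir, "introgression_proportion.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  say("recomb: breakpoints and hotspots")
  bp <- detect_breakpoints_by_family(gf, sim$metadata)
  write_breakpoints_bed(bp, file.path(outdir, "breakpoints.bed"))
  wrbp <- window_rbp(bp, sim$specs, cfg$recomb.window, cfg$recomb.step)
  hot <- call_hotspots(wrbp, cfg$recomb.hotspot_percentile)
  utils::write.table(wrbp, file.path(outdir, "window_rbp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hot$windows, file.path(outdir, "hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("popstats: diversity, divergence, window statistics")
  prog_ids <- sim$metadata$sample[sim$metadata$role == "progeny"]
  pi_prog <- site_pi(gf, intersect(prog_ids, gf$samples))
  pi_smooth <- sliding_pi(pi_prog, cfg$popstats.pi_window,
                          cfg$popstats.pi_step)
  utils::write.table(pi_smooth, file.path(outdir, "pi_sliding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fam_meta <- unique(sim$metadata[sim$metadata$role != "progeny",
                                  c("sample", "role", "family")])
  fams <- unique(sim$metadata$family)
  pairs <- t(vapply(fams, function(f) {
    c(fam_meta$sample[fam_meta$family == f &
                        fam_meta$role == "recipient_parent"][1],
      fam_meta$sample[fam_meta$family == f &
                        fam_meta$role == "donor_parent"][1])
  }, character(2)))
  wstats <- window_stats(calls, bp, sim$geno, pairs, sim$specs,
                         window = cfg$popstats.window)
  utils::write.table(wstats, file.path(outdir, "window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("tg-scan: selection scan track")
  scan <- tg_region_scan(calls, cfg$simulate.selection_chrom,
                         max(0, cfg$simulate.selection_bp - 10e6),
                         min(cfg$simulate.chrom_length_bp,
                             cfg$simulate.selection_bp + 10e6),
                         window = 1e4)
  utils::write.table(scan$track, file.path(outdir, "tg_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- c(
    paste0("wildintro_version=", as.character(utils::packageVersion("wildintro"))),
    paste0("timestamp=", format(t0, "%Y-%m-%dT%H:%M:%S")),
    paste0("elapsed_s=", round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 1)),
    vapply(names(cfg), function(k)
      paste0(k, "=", paste(cfg[[k]], collapse = ",")), ""))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  say("done")
  invisible(list(sim = sim, calls = calls, breakpoints = bp,
                 hotspots = hot, wstats = wstats, manifest = manifest,
                 config = cfg))
}

#' Generate a small committed-size fixture dataset
#'
#' A miniature population (2 chromosomes x 10 Mbp, 2 families x 6 lines,
#' no genotyping noise) written as plain-text VCF, metadata TSV, truth BED
#' and chromosome-spec TSV -- the deterministic fixture used by regression
#' tests.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return Invisibly, the `sim_population` object behind the fixture.
#' @export
generate_fixtures <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- chrom_specs(c("chr1D", "chr2D"), c(10e6, 10e6), c(4e6, 4e6))
  sim <- simulate_population(
    specs = specs,
    fspec = founder_spec(n_recipient_lines = 1,
                         donor_lineage = c("strangulata", "tauschii")),
    pspec = pedigree_spec(n_lines_per_family = 6),
    nspec = noise_spec(0, 0),
    recomb_map = default_recomb_map(specs),
    seed = seed)
  write_vcf(sim$geno, file.path(dir, "fixture.vcf"))
  write_metadata(sim$metadata, file.path(dir, "fixture_metadata.tsv"))
  write_truth_bed(sim$truth, file.path(dir, "fixture_truth.bed"))
  write_chrom_specs(specs, file.path(dir, "fixture_chrom_specs.tsv"))
  invisible(sim)
}
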