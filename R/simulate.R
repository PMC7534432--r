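#' Founder panel specification
#'
#' Describes the founder side of the crossing design: how many recipient
#' (hexaploid wheat) lines and donor (*Ae. tauschii*) accessions to build,
#' which donor lineage each accession belongs to, and the expected density of
#' sites at which a donor haplotype differs from the recipient consensus.
#'
#' Divergence rates are expressed as expected polymorphic sites per Mbp
#' between a donor haplotype and the recipient genome. The *strangulata*
#' lineage (the direct D-genome donor of bread wheat) must be less diverged
#' than the *tauschii* lineage. The desk-scale defaults re-express the
#' pericentromeric per-5-Mbp field calibration (1.47 vs 5.78 SNPs, a
#' 3.9-fold ratio) at a density that preserves realistic per-chromosome
#' marker counts on a 10x-compressed genome.
#'
#' @param n_recipient_lines number of recipient founder lines.
#' @param donor_lineage character vector, one entry per donor accession,
#'   each `"strangulata"` or `"tauschii"`.
#' @param divergence_rate named numeric vector: expected donor/recipient
#'   polymorphic sites per Mbp for each lineage.
#' @param recipient_poly_rate density of sites polymorphic among recipient
#'   lines (per Mbp); recipients are near-identical.
#' @param lineage_shared_frac fraction of a lineage's divergent sites shared
#'   by all accessions of that lineage (the rest are accession-private).
#' @return A `founder_spec` list.
#' @export
founder_spec <- function(n_recipient_lines = 2,
                         donor_lineage = c("strangulata", "strangulata",
                                           "strangulata", "tauschii",
                                           "tauschii", "tauschii"),
                         divergence_rate = c(strangulata = 2.94,
                                             tauschii = 11.56),
                         recipient_poly_rate = divergence_rate[["strangulata"]] / 10,
                         lineage_shared_frac = 0.7) {
  donor_lineage <- match.arg(donor_lineage, c("strangulata", "tauschii"),
                             several.ok = TRUE)
  if (any(divergence_rate <= 0))
    stop("divergence rates must be > 0: no informative sites are possible ",
         "under zero parental divergence")
  if (!all(c("strangulata", "tauschii") %in% names(divergence_rate)))
    stop("divergence_rate must name both lineages")
  if (divergence_rate[["strangulata"]] >= divergence_rate[["tauschii"]])
    stop("strangulata divergence must be below tauschii divergence")
  stopifnot(n_recipient_lines >= 1, length(donor_lineage) >= 1,
            recipient_poly_rate >= 0,
            lineage_shared_frac >= 0, lineage_shared_frac <= 1)
  structure(list(n_recipient_lines = n_recipient_lines,
                 donor_lineage = donor_lineage,
                 divergence_rate = divergence_rate,
                 recipient_poly_rate = recipient_poly_rate,
                 lineage_shared_frac = lineage_shared_frac),
            class = "founder_spec")
}

#' Pedigree specification
#'
#' The crossing scheme: an F1 between recipient and donor, `n_backcrosses`
#' backcrosses to the recipient, then `selfing_generations` rounds of selfing
#' by single seed descent. The default (one backcross, selfing to F3) gives
#' an expected donor genome fraction of 25% under neutrality.
#'
#' @param n_backcrosses number of backcrosses to the recipient (>= 0).
#' @param selfing_generations selfing rounds after the last backcross
#'   (2 advances BC1F1 to BC1F3).
#' @param n_lines_per_family progeny lines retained per family.
#' @return A `pedigree_spec` list.
#' @export
pedigree_spec <- function(n_backcrosses = 1, selfing_generations = 2,
                          n_lines_per_family = 30) {
  stopifnot(n_backcrosses >= 0, selfing_generations >= 0,
            n_lines_per_family >= 1)
  structure(list(n_backcrosses = n_backcrosses,
                 selfing_generations = selfing_generations,
                 n_lines_per_family = n_lines_per_family),
            class = "pedigree_spec")
}

#' Single-locus selection specification
#'
#' Models phenotypic selection against a dominant donor allele (the
#' tenacious-glume situation): a line carrying at least one donor allele at
#' the locus is discarded with probability `s` at the stated generation, and
#' the family is resampled to keep its size. `s = 0` reproduces neutrality.
#'
#' @param locus_chrom,locus_bp position of the selected locus.
#' @param s selection strength in `[0, 1]`.
#' @param generation_applied `"final"` (after the last selfing, the
#'   phenotyping stage) or `"bc1"` (at the backcross plant).
#' @return A `selection_spec` list, or `NULL` if `s = 0` and no locus given.
#' @export
selection_spec <- function(locus_chrom, locus_bp, s = 0,
                           generation_applied = c("final", "bc1")) {
  stopifnot(s >= 0, s <= 1, locus_bp >= 0)
  structure(list(locus_chrom = locus_chrom, locus_bp = locus_bp, s = s,
                 generation_applied = match.arg(generation_applied)),
            class = "selection_spec")
}

#' Genotyping-noise specification
#'
#' Emulates GBS sparsity: every sample-site entry is independently set
#' missing with `missing_rate` and, if observed, flipped to a random other
#' dosage with `genotype_error_rate`. Zero noise leaves genotypes unchanged.
#'
#' @param missing_rate probability an entry is missing, in `[0, 1)`.
#' @param genotype_error_rate probability an observed entry is miscalled,
#'   in `[0, 1)`.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(missing_rate = 0.2, genotype_error_rate = 0.005) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  structure(list(missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate),
            class = "noise_spec")
}

## ---- haplotype mosaics -----------------------------------------------------
## A haplotype on one chromosome is a step function stored as
## list(bp = segment end positions (last == length_bp), lab = founder labels);
## segment i covers [bp[i-1], bp[i]) with bp[0] := 0.

new_hap <- function(length_bp, label) list(bp = length_bp, lab = label)

hap_label_at <- function(hap, pos) {
  hap$lab[findInterval(pos, hap$bp) + 1L]
}

merge_hap_runs <- function(bp, lab) {
  if (length(bp) > 1) {
    keep <- c(lab[-length(lab)] != lab[-1], TRUE)
    bp <- bp[keep]; lab <- lab[keep]
  }
  list(bp = bp, lab = lab)
}

## splice two parental haplotypes at sorted crossover positions
cross_haps <- function(h1, h2, xpos, start_hap) {
  L <- h1$bp[length(h1$bp)]
  if (length(xpos) == 0)
    return(if (start_hap == 1) h1 else h2)
  bounds <- c(sort(xpos), L)
  bp <- numeric(0); lab <- character(0)
  cur <- 0
  src_is_1 <- start_hap == 1
  for (k in seq_along(bounds)) {
    src <- if (src_is_1) h1 else h2
    e <- bounds[k]
    if (e > cur) {
      i1 <- findInterval(cur, src$bp) + 1L
      i2 <- findInterval(e, src$bp, left.open = TRUE) + 1L
      ends <- pmin(src$bp[i1:i2], e)
      bp <- c(bp, ends); lab <- c(lab, src$lab[i1:i2])
      cur <- e
    }
    src_is_1 <- !src_is_1
  }
  keep <- c(bp[-1] > bp[-length(bp)], TRUE)
  if (length(bp) == 1) keep <- TRUE
  merge_hap_runs(bp[keep], lab[keep])
}

## precompute inverse-CDF tables for crossover placement
compile_map <- function(map, specs) {
  validate_recomb_map(map, specs)
  out <- list()
  for (cn in specs$name) {
    m <- map[map$chrom == cn, , drop = FALSE]
    m <- m[order(m$start), ]
    dM <- (m$end - m$start) / 1e6 * m$rate / 100
    out[[cn]] <- list(start = m$start, end = m$end,
                      cumM = c(0, cumsum(dM)), total = sum(dM))
  }
  out
}

## draw crossover positions on one chromosome: count ~ Poisson(Morgans),
## positions by inverse CDF of the piecewise-constant intensity
draw_crossovers <- function(cmap, obligate = FALSE) {
  k <- stats::rpois(1, cmap$total)
  if (obligate && k == 0) k <- 1
  if (k == 0 || cmap$total <= 0) return(numeric(0))
  u <- stats::runif(k, 0, cmap$total)
  seg <- findInterval(u, cmap$cumM, left.open = TRUE)
  seg <- pmax(pmin(seg, length(cmap$start)), 1L)
  frac <- (u - cmap$cumM[seg]) /
    pmax(cmap$cumM[seg + 1] - cmap$cumM[seg], .Machine$double.eps)
  sort(cmap$start[seg] + frac * (cmap$end[seg] - cmap$start[seg]))
}

#' Sample a gamete from a diplotype
#'
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans (no interference); positions are placed proportionally
#' to local map intensity. An obligate-crossover option is off by default.
#'
#' @param parent a diplotype: `list(h1 = , h2 = )`, each a per-chromosome
#'   list of haplotype mosaics as produced by the simulator.
#' @param recomb_map recombination map `data.frame`, or a compiled map from
#'   the internal compiler (used by [advance_pedigree()]).
#' @param specs chromosome specs (required when `recomb_map` is a
#'   `data.frame`).
#' @param obligate force at least one crossover per chromosome.
#' @return `list(hap = per-chromosome mosaic, crossovers = named list of
#'   crossover positions)`.
#' @export
sample_gamete <- function(parent, recomb_map, specs = NULL, obligate = FALSE) {
  cmap <- if (is.data.frame(recomb_map)) {
    stopifnot(!is.null(specs))
    compile_map(recomb_map, specs)
  } else recomb_map
  hap <- list(); xo <- list()
  for (cn in names(parent$h1)) {
    xpos <- draw_crossovers(cmap[[cn]], obligate = obligate)
    start_hap <- sample.int(2L, 1L)
    hap[[cn]] <- cross_haps(parent$h1[[cn]], parent$h2[[cn]], xpos, start_hap)
    xo[[cn]] <- xpos
  }
  list(hap = hap, crossovers = xo)
}

## ---- founders --------------------------------------------------------------

#' Build founder haplotypes and the segregating-site panel
#'
#' Places biallelic sites along the chromosomes (uniformly at random) so that
#' donor haplotypes differ from the recipient consensus at each lineage's
#' divergence rate; a fraction of each lineage's sites is shared by all its
#' accessions, the remainder are accession-private. Recipient lines are
#' near-identical, differing only at a low-density set of
#' recipient-polymorphic sites.
#'
#' @param specs chromosome spec `data.frame`.
#' @param fspec a [founder_spec()].
#' @param seed integer random seed.
#' @return A `founder_panel` list: `sites` (variant table with 0-based `pos`),
#'   `H` (founder x site 0/1 haplotype allele matrix, rows named by founder
#'   id), `founders` (id/role/lineage table), and `specs`.
#' @export
build_founders <- function(specs, fspec = founder_spec(), seed = 1) {
  validate_chrom_specs(specs)
  stopifnot(inherits(fspec, "founder_spec"))
  set.seed(seed)
  rec_ids <- paste0("R", seq_len(fspec$n_recipient_lines))
  don_ids <- paste0("D", seq_along(fspec$donor_lineage))
  founders <- data.frame(
    id = c(rec_ids, don_ids),
    role = c(rep("recipient", length(rec_ids)), rep("donor", length(don_ids))),
    lineage = c(rep(NA_character_, length(rec_ids)), fspec$donor_lineage),
    stringsAsFactors = FALSE)

  site_chrom <- character(0); site_pos <- numeric(0)
  carrier <- list()  # per site: character vector of founder ids carrying alt
  add_sites <- function(chrom, n, L, who) {
    if (n == 0) return()
    pos <- sort(floor(stats::runif(n, 0, L)))
    site_chrom <<- c(site_chrom, rep(chrom, n))
    site_pos <<- c(site_pos, pos)
    carrier <<- c(carrier, rep(list(who), n))
  }
  for (i in seq_len(nrow(specs))) {
    cn <- specs$name[i]; Lmb <- specs$length_bp[i] / 1e6
    for (lin in unique(fspec$donor_lineage)) {
      ids <- don_ids[fspec$donor_lineage == lin]
      rate <- fspec$divergence_rate[[lin]]
      n_shared <- stats::rpois(1, fspec$lineage_shared_frac * rate * Lmb)
      add_sites(cn, n_shared, specs$length_bp[i], ids)
      for (id in ids) {
        n_priv <- stats::rpois(1, (1 - fspec$lineage_shared_frac) * rate * Lmb)
        add_sites(cn, n_priv, specs$length_bp[i], id)
      }
    }
    n_rp <- stats::rpois(1, fspec$recipient_poly_rate * Lmb)
    if (n_rp > 0 && length(rec_ids) > 1) {
      for (k in seq_len(n_rp)) {
        who <- rec_ids[stats::runif(length(rec_ids)) < 0.3]
        if (length(who) == 0) who <- sample(rec_ids, 1)
        add_sites(cn, 1, specs$length_bp[i], who)
      }
    }
  }
  ord <- order(match(site_chrom, specs$name), site_pos)
  site_chrom <- site_chrom[ord]; site_pos <- site_pos[ord]
  carrier <- carrier[ord]
  dup <- duplicated(paste(site_chrom, site_pos))
  site_chrom <- site_chrom[!dup]; site_pos <- site_pos[!dup]
  carrier <- carrier[!dup]

  n_sites <- length(site_pos)
  H <- matrix(0L, nrow = nrow(founders), ncol = n_sites,
              dimnames = list(founders$id, NULL))
  for (j in seq_len(n_sites)) H[carrier[[j]], j] <- 1L
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  sites <- data.frame(chrom = site_chrom, pos = site_pos,
                      id = paste0("S", seq_len(n_sites)),
                      ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  structure(list(sites = sites, H = H, founders = founders, specs = specs),
            class = "founder_panel")
}

founder_diplotype <- function(panel, id) {
  specs <- panel$specs
  h <- lapply(seq_len(nrow(specs)),
              function(i) new_hap(specs$length_bp[i], id))
  names(h) <- specs$name
  list(h1 = h, h2 = h)  # founders are fully inbred
}

## donor-carrier status of an individual at a locus
carries_donor_at <- function(ind, donor_id, chrom, pos) {
  hap_label_at(ind$h1[[chrom]], pos) == donor_id ||
    hap_label_at(ind$h2[[chrom]], pos) == donor_id
}

## ---- pedigree --------------------------------------------------------------

## Simulate one progeny line of one family: F1 -> BC_k -> selfing by SSD.
simulate_line <- function(rec, don, donor_id, cmap, pspec, sspec) {
  f1 <- list(h1 = rec$h1, h2 = don$h1)
  ind <- f1
  for (b in seq_len(pspec$n_backcrosses)) {
    g <- sample_gamete(ind, cmap)
    ind <- list(h1 = g$hap, h2 = rec$h1)
  }
  if (!is.null(sspec) && sspec$s > 0 &&
      sspec$generation_applied == "bc1" &&
      carries_donor_at(ind, donor_id, sspec$locus_chrom, sspec$locus_bp) &&
      stats::runif(1) < sspec$s)
    return(NULL)
  for (g in seq_len(pspec$selfing_generations)) {
    g1 <- sample_gamete(ind, cmap)
    g2 <- sample_gamete(ind, cmap)
    ind <- list(h1 = g1$hap, h2 = g2$hap)
  }
  if (!is.null(sspec) && sspec$s > 0 &&
      sspec$generation_applied == "final" &&
      carries_donor_at(ind, donor_id, sspec$locus_chrom, sspec$locus_bp) &&
      stats::runif(1) < sspec$s)
    return(NULL)
  ind
}

## origin intervals (recipient / donor_het / donor_hom) for one line
line_truth <- function(ind, donor_id, specs) {
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    cn <- specs$name[i]
    h1 <- ind$h1[[cn]]; h2 <- ind$h2[[cn]]
    bp <- sort(unique(c(h1$bp, h2$bp)))
    starts <- c(0, bp[-length(bp)])
    d1 <- hap_label_at(h1, starts) == donor_id
    d2 <- hap_label_at(h2, starts) == donor_id
    state <- c("recipient", "donor_het", "donor_hom")[d1 + d2 + 1L]
    m <- merge_hap_runs(bp, state)
    out[[i]] <- data.frame(chrom = cn,
                           start = c(0, m$bp[-length(m$bp)]),
                           end = m$bp, origin = m$lab,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Advance one family through the pedigree
#'
#' Builds the F1 (one recipient haplotype + one donor haplotype per
#' chromosome, modelling the D-genome contribution of the synthetic
#' octoploid), backcrosses to the recipient, then advances by single seed
#' descent, each progeny line descending from an independent backcross
#' plant. If selection is active, discarded carrier lines are resampled
#' until the family reaches its target size.
#'
#' @param panel a `founder_panel` from [build_founders()].
#' @param recipient_id,donor_id founder ids for this family's parents.
#' @param pspec a [pedigree_spec()].
#' @param recomb_map recombination map `data.frame`.
#' @param sspec optional [selection_spec()] (`NULL` = neutral).
#' @param seed integer random seed.
#' @param max_attempts resampling budget under selection before erroring.
#' @return `list(lines = list of diplotypes, truth = TruthSet data.frame
#'   (line, chrom, start, end, origin; 0-based half-open))`.
#' @export
advance_pedigree <- function(panel, recipient_id, donor_id, pspec,
                             recomb_map, sspec = NULL, seed = 1,
                             max_attempts = 1000L * pspec$n_lines_per_family) {
  stopifnot(inherits(panel, "founder_panel"),
            recipient_id %in% panel$founders$id,
            donor_id %in% panel$founders$id)
  set.seed(seed)
  cmap <- compile_map(recomb_map, panel$specs)
  rec <- founder_diplotype(panel, recipient_id)
  don <- founder_diplotype(panel, donor_id)
  lines <- vector("list", pspec$n_lines_per_family)
  n_done <- 0L; attempts <- 0L
  while (n_done < pspec$n_lines_per_family) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("family ", recipient_id, " x ", donor_id,
           ": no surviving lines within ", max_attempts,
           " attempts under selection (s = ", sspec$s, ")")
    ind <- simulate_line(rec, don, donor_id, cmap, pspec, sspec)
    if (is.null(ind)) next
    n_done <- n_done + 1L
    lines[[n_done]] <- ind
  }
  truth <- do.call(rbind, lapply(seq_along(lines), function(k) {
    t <- line_truth(lines[[k]], donor_id, panel$specs)
    cbind(line = k, t)
  }))
  rownames(truth) <- NULL
  list(lines = lines, truth = truth)
}

#' Donor genome fraction from a TruthSet
#'
#' Fraction of the genome inherited from the donor, computed from true
#' origin intervals. With `het_weight = 0.5` (the default) heterozygous
#' intervals count half, giving the allele-dosage genome fraction whose
#' neutral expectation after one backcross is 25% regardless of further
#' selfing; `het_weight = 1` gives the donor-carrier fraction instead.
#'
#' @param truth TruthSet `data.frame` (line, chrom, start, end, origin).
#' @param specs chromosome spec `data.frame`.
#' @param het_weight weight of `donor_het` intervals.
#' @return Named numeric vector: donor fraction (0-1) per line.
#' @export
truth_donor_fraction <- function(truth, specs, het_weight = 0.5) {
  genome <- sum(specs$length_bp)
  w <- c(recipient = 0, donor_het = het_weight, donor_hom = 1)
  len <- (truth$end - truth$start) * w[truth$origin]
  grp <- if ("sample" %in% names(truth)) truth$sample else truth$line
  out <- tapply(len, grp, sum) / genome
  stats::setNames(as.vector(out), names(out))
}

## ---- genotyping ------------------------------------------------------------

## alt-allele dosage of one line at the panel's sites (no noise)
line_dosage <- function(ind, panel) {
  sites <- panel$sites
  out <- integer(nrow(sites))
  for (cn in unique(sites$chrom)) {
    sel <- which(sites$chrom == cn)
    pos <- sites$pos[sel]
    l1 <- hap_label_at(ind$h1[[cn]], pos)
    l2 <- hap_label_at(ind$h2[[cn]], pos)
    idx <- seq_along(sel)
    a1 <- panel$H[cbind(match(l1, rownames(panel$H)), sel)]
    a2 <- panel$H[cbind(match(l2, rownames(panel$H)), sel)]
    out[sel] <- a1 + a2
  }
  out
}

#' Genotype simulated individuals with GBS-style noise
#'
#' Converts true diplotypes to alt-allele dosages (0/1/2) at the founder
#' panel's sites, then independently sets each entry missing with
#' `missing_rate` and flips observed entries to a random other dosage with
#' `genotype_error_rate`. At family-informative sites (donor and recipient
#' fixed for different alleles) the alt dosage equals the donor-allele
#' dosage.
#'
#' @param individuals named list of diplotypes (names become sample ids);
#'   founder ids are also accepted and genotyped from the panel.
#' @param panel `founder_panel`.
#' @param nspec a [noise_spec()].
#' @param seed integer random seed.
#' @return A [geno_matrix()] (sites x samples).
#' @export
genotype_with_noise <- function(individuals, panel, nspec = noise_spec(),
                                seed = 1) {
  stopifnot(inherits(nspec, "noise_spec"), length(individuals) > 0,
            !is.null(names(individuals)))
  set.seed(seed)
  gt <- vapply(individuals, line_dosage, integer(nrow(panel$sites)),
               panel = panel)
  gt <- matrix(as.integer(gt), nrow = nrow(panel$sites),
               dimnames = list(NULL, names(individuals)))
  n <- length(gt)
  if (nspec$genotype_error_rate > 0) {
    err <- which(stats::runif(n) < nspec$genotype_error_rate)
    if (length(err))
      gt[err] <- (gt[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
  }
  if (nspec$missing_rate > 0)
    gt[stats::runif(n) < nspec$missing_rate] <- NA_integer_
  geno_matrix(gt, panel$sites, colnames(gt))
}

## ---- whole-population convenience -----------------------------------------

#' Simulate a multi-family introgression population
#'
#' End-to-end generator reproducing the study design at desk scale: builds
#' founders, pairs each donor accession with a recipient line (cycled),
#' advances every family through the pedigree, genotypes progeny and parents
#' with noise, and returns the genotype matrix, sample metadata, TruthSet
#' and all inputs. Per-family seeds are derived from `seed` by fixed
#' offsets, so runs are reproducible family by family.
#'
#' @param specs chromosome specs (default [default_chrom_specs()]).
#' @param fspec founder spec (default [founder_spec()]: 2 recipients, 3
#'   *strangulata* + 3 *tauschii* donors).
#' @param pspec pedigree spec (default BC1, selfed to F3, 30 lines/family).
#' @param nspec noise spec (default 20% missing, 0.5% genotype error).
#' @param recomb_map recombination map (default [default_recomb_map()]).
#' @param sspec optional [selection_spec()].
#' @param seed global integer seed.
#' @return A `sim_population` list: `geno` ([geno_matrix()]), `metadata`
#'   (sample/role/family), `truth` (TruthSet with sample ids), `panel`,
#'   `map`, `specs`, and the spec objects used.
#' @export
simulate_population <- function(specs = default_chrom_specs(),
                                fspec = founder_spec(),
                                pspec = pedigree_spec(),
                                nspec = noise_spec(),
                                recomb_map = default_recomb_map(specs),
                                sspec = NULL, seed = 1) {
  panel <- build_founders(specs, fspec, seed = seed)
  don_ids <- panel$founders$id[panel$founders$role == "donor"]
  rec_ids <- panel$founders$id[panel$founders$role == "recipient"]
  individuals <- list(); meta <- list(); truth <- list()
  for (f in seq_along(don_ids)) {
    fam <- sprintf("FAM%02d", f)
    rid <- rec_ids[((f - 1) %% length(rec_ids)) + 1]
    did <- don_ids[f]
    ped <- advance_pedigree(panel, rid, did, pspec, recomb_map,
                            sspec = sspec, seed = seed + 1000L * f)
    ids <- sprintf("%s_L%03d", fam, seq_along(ped$lines))
    names(ped$lines) <- ids
    individuals <- c(individuals, ped$lines)
    t <- ped$truth
    t$sample <- ids[t$line]
    truth[[f]] <- t[, c("sample", "chrom", "start", "end", "origin")]
    meta[[f]] <- data.frame(
      sample = c(ids, rid, did),
      role = c(rep("progeny", length(ids)), "recipient_parent",
               "donor_parent"),
      family = fam, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  # parents appear once per family in metadata but once in the matrix
  parents <- unique(meta$sample[meta$role != "progeny"])
  for (p in parents) individuals[[p]] <- founder_diplotype(panel, p)
  geno <- genotype_with_noise(individuals, panel, nspec, seed = seed + 7L)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(geno = geno, metadata = meta, truth = truth, panel = panel,
                 map = recomb_map, specs = specs, fspec = fspec,
                 pspec = pspec, nspec = nspec, sspec = sspec, seed = seed),
            class = "sim_population")
}

#' Write a TruthSet as BED
#'
#' Four-column BED (0-based half-open) with the origin state in column 4 and
#' the sample id in column 5.
#' @param truth TruthSet `data.frame` with a `sample` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$chrom,
                    start = format(truth$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(truth$end, scientific = FALSE, trim = TRUE),
                    origin = truth$origin, sample = truth$sample)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
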