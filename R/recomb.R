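#' Detect recombination breakpoints from allele-phase transitions
#'
#' For each individual and chromosome, consecutive non-missing 0/1/2 dosage
#' codes are scanned; every change of code emits one breakpoint flanked by
#' the two informative positions (missing codes are skipped, so flanks are
#' the nearest non-missing neighbours). Any change counts as one breakpoint
#' (a 0 -> 2 step is a single observable phase change). Monomorphic sites
#' should be removed within the family first ([remove_monomorphic()]).
#'
#' @param g a `geno` object (one family's polymorphic sites).
#' @param samples samples to scan (default all).
#' @param family optional family label copied to the output.
#' @return BreakpointRecord `data.frame`: sample, chrom, left_pos,
#'   right_pos, midpoint (bp), and family if given. Chromosomes with fewer
#'   than two non-missing codes for a sample yield no records (with one
#'   warning per call).
#' @export
detect_breakpoints <- function(g, samples = g$samples, family = NULL) {
  v <- g$variants
  out <- list()
  thin <- FALSE
  for (cn in unique(v$chrom)) {
    sel <- which(v$chrom == cn)
    pos <- v$pos[sel]
    for (id in samples) {
      codes <- g$gt[sel, id]
      ok <- !is.na(codes)
      if (sum(ok) < 2) { thin <- thin || sum(ok) < 2; next }
      p <- pos[ok]; x <- codes[ok]
      ch <- which(x[-1] != x[-length(x)])
      if (length(ch))
        out[[length(out) + 1]] <- data.frame(
          sample = id, chrom = cn, left_pos = p[ch], right_pos = p[ch + 1],
          midpoint = (p[ch] + p[ch + 1]) / 2, stringsAsFactors = FALSE)
    }
  }
  if (thin) warning("some sample-chromosomes had < 2 non-missing sites")
  if (length(out) == 0)
    res <- data.frame(sample = character(0), chrom = character(0),
                      left_pos = numeric(0), right_pos = numeric(0),
                      midpoint = numeric(0))
  else res <- do.call(rbind, out)
  if (!is.null(family) && nrow(res)) res$family <- family
  rownames(res) <- NULL
  res
}

#' Detect breakpoints family by family
#'
#' The standard within-family recipe behind the breakpoint scan: subset each
#' family's progeny, recode dosages to major/minor polarity within the
#' family ([recode_major_minor()]), drop monomorphic sites, then scan for
#' phase transitions. The recode is essential: at sites where the recipient
#' parent carries the alt allele, raw alt dosages are phase-inverted
#' relative to neighbouring sites and would fake two transitions per site;
#' with recipient ancestry in the majority the major allele is almost
#' always the recipient allele, making recoded dosages phase-consistent.
#'
#' @param g a `geno` object covering several families.
#' @param metadata sample metadata (sample, role, family).
#' @param min_progeny passed to [split_by_family()].
#' @return BreakpointRecord `data.frame` with a `family` column.
#' @export
detect_breakpoints_by_family <- function(g, metadata, min_progeny = 1) {
  bundles <- split_by_family(g, metadata, min_progeny = min_progeny)
  out <- lapply(bundles, function(b) {
    gp <- geno_subset(b$geno, samples = b$progeny)
    gp <- suppressWarnings(remove_monomorphic(recode_major_minor(gp)))
    detect_breakpoints(gp, family = b$family)
  })
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  rownames(res) <- NULL
  res
}

#' Breakpoint counts in sliding windows
#'
#' Counts breakpoints per 2 Mbp window sliding by 1 Mbp (defaults): each
#' breakpoint is assigned to every window containing its midpoint, so an
#' interior midpoint falls in exactly `window/step` windows. Per-family
#' counts are returned when the records carry a `family` column.
#'
#' @param bp BreakpointRecord `data.frame`.
#' @param specs chromosome spec `data.frame`.
#' @param window window size in bp (default 2e6).
#' @param step step size in bp (default 1e6); `window >= step > 0`.
#' @return WindowRBP `data.frame`: chrom, start, end, one `rbp_<family>`
#'   column per family (if present) and `rbp_total`.
#' @export
window_rbp <- function(bp, specs, window = 2e6, step = 1e6) {
  stopifnot(window >= step, step > 0)
  fams <- if ("family" %in% names(bp)) sort(unique(bp$family)) else NULL
  out <- list()
  for (i in seq_len(nrow(specs))) {
    cn <- specs$name[i]; L <- specs$length_bp[i]
    starts <- seq(0, max(0, L - step), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window, L)
    m <- bp$midpoint[bp$chrom == cn]
    count_mid <- function(mid) {
      vapply(seq_along(starts), function(k)
        sum(mid >= starts[k] & mid < ends[k]), 0)
    }
    w <- data.frame(chrom = cn, start = starts, end = ends)
    if (!is.null(fams)) {
      for (f in fams) {
        mf <- bp$midpoint[bp$chrom == cn & bp$family == f]
        w[[paste0("rbp_", f)]] <- count_mid(mf)
      }
      w$rbp_total <- rowSums(w[, paste0("rbp_", fams), drop = FALSE])
    } else {
      w$rbp_total <- count_mid(m)
    }
    out[[cn]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call recombination hotspots at a percentile threshold
#'
#' The threshold is the stated percentile (linear interpolation) of window
#' totals over windows with at least one breakpoint -- zero-inflated empty
#' windows would otherwise drag the threshold down. Windows at or above the
#' threshold are hotspots; ties at the threshold are kept and flagged.
#'
#' @param wrbp WindowRBP `data.frame` from [window_rbp()].
#' @param percentile percentile in (0, 100), default 95.
#' @return `list(windows = hotspot rows of `wrbp`, threshold, tied =
#'   logical, n_universe = number of windows with >= 1 breakpoint)`.
#' @export
call_hotspots <- function(wrbp, percentile = 95) {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(wrbp) < 20) warning("fewer than 20 windows; threshold unstable")
  nz <- wrbp$rbp_total[wrbp$rbp_total >= 1]
  if (length(nz) == 0) {
    warning("all window totals are zero; no hotspots")
    return(list(windows = wrbp[0, ], threshold = NA_real_, tied = FALSE,
                n_universe = 0L))
  }
  thr <- unname(stats::quantile(nz, percentile / 100, type = 7))
  hot <- wrbp[wrbp$rbp_total >= thr, , drop = FALSE]
  list(windows = hot, threshold = thr,
       tied = length(unique(nz)) == 1, n_universe = length(nz))
}

#' Permutation-overlap enrichment of two hotspot sets
#'
#' Given hotspot window sets from two populations and a shared universe of
#' windows (those with at least one breakpoint in the respective population,
#' intersected on coordinates), each permutation replicate draws `|A|` and
#' `|B|` windows uniformly without replacement from the universe and records
#' the intersection size. Fold = observed / null mean; the empirical p-value
#' is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param hotspots_a,hotspots_b character vectors of window keys (e.g.
#'   `"chrom:start"`), subsets of `universe`.
#' @param universe character vector of all eligible window keys.
#' @param n_perm number of permutation replicates.
#' @param seed integer random seed.
#' @return `list(observed, null_mean, null_sd, fold, p_value, n_perm)`.
#' @export
overlap_enrichment <- function(hotspots_a, hotspots_b, universe,
                               n_perm = 1000, seed = 1) {
  hotspots_a <- unique(hotspots_a); hotspots_b <- unique(hotspots_b)
  universe <- unique(universe)
  if (!all(hotspots_a %in% universe) || !all(hotspots_b %in% universe))
    stop("hotspot sets must be subsets of the universe")
  kA <- length(hotspots_a); kB <- length(hotspots_b); M <- length(universe)
  if (M < kA || M < kB) stop("universe smaller than a hotspot set")
  observed <- length(intersect(hotspots_a, hotspots_b))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    a <- sample.int(M, kA); b <- sample.int(M, kB)
    length(intersect(a, b))
  }, 0L)
  nm <- mean(null)
  list(observed = observed, null_mean = nm, null_sd = stats::sd(null),
       fold = if (nm > 0) observed / nm else Inf,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Window key helper
#' @param windows a window `data.frame` with `chrom` and `start`.
#' @return Character vector `"chrom:start"`.
#' @export
window_key <- function(windows) paste0(windows$chrom, ":", windows$start)

#' Across-family test of breakpoint-count distributions
#'
#' Kruskal-Wallis rank-sum test (tie-corrected, chi-square reference) of
#' per-individual breakpoint counts across families. With all values
#' identical the test is degenerate and p = 1 is returned with a warning.
#'
#' @param counts numeric vector of per-individual breakpoint counts.
#' @param family factor/character of family membership, same length.
#' @return An object of class `htest`.
#' @export
family_distribution_test <- function(counts, family) {
  family <- as.factor(family)
  stopifnot(length(counts) == length(family), nlevels(family) >= 2)
  if (length(unique(counts)) == 1) {
    warning("all breakpoint counts identical; degenerate data, p = 1")
    out <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                parameter = c(df = nlevels(family) - 1), p.value = 1,
                method = "Kruskal-Wallis rank sum test (degenerate data)",
                data.name = "counts by family")
    class(out) <- "htest"
    return(out)
  }
  stats::kruskal.test(counts, family)
}

#' Per-individual breakpoint counts
#' @param bp BreakpointRecord `data.frame`.
#' @param samples all sample ids (so zero-count individuals are included).
#' @return Named integer vector of breakpoint counts.
#' @export
breakpoint_counts <- function(bp, samples = unique(bp$sample)) {
  tab <- table(factor(bp$sample, levels = samples))
  stats::setNames(as.integer(tab), samples)
}

#' Write breakpoints as BED
#' @param bp BreakpointRecord `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(bp, path) {
  bed <- data.frame(bp$chrom,
                    format(bp$left_pos, scientific = FALSE, trim = TRUE),
                    format(bp$right_pos, scientific = FALSE, trim = TRUE),
                    bp$sample)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
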