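#' Per-site nucleotide diversity
#'
#' The unbiased pairwise estimator on haplotype counts: with `n` non-missing
#' diploid genotypes and minor-allele count `j` among the `2n` alleles,
#' `pi = 2 j (2n - j) / (2n (2n - 1))` -- the mean number of base
#' differences per site over all pairwise haplotype comparisons. Genotypes
#' contribute both alleles, unphased. Sites with fewer than two non-missing
#' genotypes are undefined (`NA`).
#'
#' @param g a `geno` object.
#' @param samples sample subset (default all).
#' @return `data.frame` (chrom, pos, n, pi).
#' @export
site_pi <- function(g, samples = g$samples) {
  gt <- g$gt[, samples, drop = FALSE]
  n <- rowSums(!is.na(gt))
  j <- rowSums(gt, na.rm = TRUE)
  nn <- 2 * n
  pi <- ifelse(n >= 2, 2 * j * (nn - j) / (nn * (nn - 1)), NA_real_)
  data.frame(chrom = g$variants$chrom, pos = g$variants$pos, n = n, pi = pi)
}

#' Sliding-window average of per-site diversity
#'
#' Averages `window` consecutive defined sites advancing by `step` sites
#' (defaults 10 and 2), per chromosome; each window is anchored at the
#' median position of its sites and partial tail windows are dropped.
#'
#' @param pi_tab output of [site_pi()].
#' @param window number of sites per window.
#' @param step sites to advance between windows.
#' @return `data.frame` (chrom, pos, pi) -- the smoothed track; empty with a
#'   warning for chromosomes with fewer than `window` defined sites.
#' @export
sliding_pi <- function(pi_tab, window = 10, step = 2) {
  stopifnot(window >= 1, step >= 1)
  out <- list()
  short <- FALSE
  for (cn in unique(pi_tab$chrom)) {
    d <- pi_tab[pi_tab$chrom == cn & !is.na(pi_tab$pi), , drop = FALSE]
    d <- d[order(d$pos), ]
    if (nrow(d) < window) { short <- TRUE; next }
    starts <- seq(1, nrow(d) - window + 1, by = step)
    out[[cn]] <- data.frame(
      chrom = cn,
      pos = vapply(starts, function(s)
        stats::median(d$pos[s:(s + window - 1)]), 0),
      pi = vapply(starts, function(s)
        mean(d$pi[s:(s + window - 1)]), 0))
  }
  if (short) warning("chromosome(s) with fewer defined sites than the window")
  if (length(out) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      pi = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed parental sequence divergence
#'
#' Per non-overlapping window (default 5 Mbp), the number of sites at which
#' two parents carry different non-missing genotypes (het-vs-hom counts as
#' divergent). With several parent pairs, per-pair window counts are
#' returned along with their mean (`sd_count`), the group-level sequence
#' divergence.
#'
#' @param g a `geno` object.
#' @param pairs two-column matrix or data.frame of (recipient, donor) sample
#'   ids, one row per parent pair.
#' @param specs chromosome spec `data.frame`.
#' @param window window size in bp.
#' @return `data.frame` (chrom, start, end, one `pair<i>` column per pair,
#'   sd_count = mean across pairs).
#' @export
parental_divergence <- function(g, pairs, specs, window = 5e6) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, window > 0)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    cn <- specs$name[i]
    w <- tile_windows(specs$length_bp[i], window)
    sel <- which(g$variants$chrom == cn)
    pos <- g$variants$pos[sel]
    wi <- findInterval(pos, w$start)
    tab <- data.frame(chrom = cn, start = w$start, end = w$end)
    for (k in seq_len(nrow(pairs))) {
      a <- g$gt[sel, pairs[k, 1]]; b <- g$gt[sel, pairs[k, 2]]
      div <- !is.na(a) & !is.na(b) & a != b
      cnt <- tabulate(wi[div], nbins = nrow(w))
      tab[[paste0("pair", k)]] <- cnt
    }
    pc <- tab[, paste0("pair", seq_len(nrow(pairs))), drop = FALSE]
    tab$sd_count <- rowMeans(pc)
    out[[cn]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group rank comparison (Mann-Whitney U)
#'
#' Two-sided two-sample Wilcoxon rank-sum test with tie correction; exact
#' enumeration when the combined sample size is <= 20 and there are no ties,
#' normal approximation otherwise. All-tied data yield p = 1 with a warning.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param ... passed to [stats::wilcox.test()] (e.g. `alternative`).
#' @return An object of class `htest`.
#' @export
compare_regions <- function(values_a, values_b, ...) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  if (length(unique(c(values_a, values_b))) == 1) {
    warning("all values tied; p = 1")
    out <- list(statistic = c(W = length(values_a) * length(values_b) / 2),
                p.value = 1, method = "Wilcoxon rank sum test (degenerate)",
                data.name = "values_a vs values_b")
    class(out) <- "htest"
    return(out)
  }
  exact <- length(values_a) + length(values_b) <= 20 &&
    !any(duplicated(c(values_a, values_b)))
  suppressWarnings(stats::wilcox.test(values_a, values_b, exact = exact, ...))
}

#' Build a shared 5 Mbp window table of IF, RBP and SD
#'
#' Computes introgression frequency (any-overlap line counts from segment
#' calls), breakpoint totals (midpoint counts) and parental sequence
#' divergence on a common non-overlapping window grid, with the
#' pericentromeric/distal region label of each window midpoint.
#'
#' @param calls SegmentCall `data.frame`.
#' @param bp BreakpointRecord `data.frame`.
#' @param g a `geno` object (for divergence).
#' @param pairs parent pairs, as in [parental_divergence()].
#' @param specs chromosome spec `data.frame`.
#' @param window common window size in bp (default 5e6).
#' @return WindowStatTable `data.frame` (chrom, start, end, if_count,
#'   rbp_total, sd_count, region).
#' @export
window_stats <- function(calls, bp, g, pairs, specs, window = 5e6) {
  iftab <- window_introgression_frequency(calls, specs, window = window)
  rbptab <- window_rbp(bp, specs, window = window, step = window)
  sdtab <- parental_divergence(g, pairs, specs, window = window)
  stopifnot(nrow(iftab) == nrow(rbptab), nrow(iftab) == nrow(sdtab))
  out <- data.frame(chrom = iftab$chrom, start = iftab$start,
                    end = iftab$end, if_count = iftab$if_count,
                    rbp_total = rbptab$rbp_total, sd_count = sdtab$sd_count)
  out$region <- region_of(out$chrom, (out$start + out$end) / 2, specs)
  out
}

#' Rank correlations among introgression, recombination and divergence
#'
#' Spearman correlations (with p-values) among the `if_count`, `rbp_total`
#' and `sd_count` columns of a shared WindowStatTable, overall and within
#' pericentromeric/distal strata.
#'
#' @param wstats WindowStatTable from [window_stats()] (>= 10 windows).
#' @return `list(overall = , by_region = list per region)`, each a
#'   `data.frame` (var1, var2, rho, p_value, n).
#' @export
if_rbp_sd_association <- function(wstats) {
  if (nrow(wstats) < 10) stop("need at least 10 shared windows")
  vars <- c("if_count", "rbp_total", "sd_count")
  stopifnot(all(vars %in% names(wstats)))
  cor_tab <- function(d) {
    cmb <- utils::combn(vars, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      ct <- suppressWarnings(
        stats::cor.test(d[[cmb[1, k]]], d[[cmb[2, k]]], method = "spearman"))
      data.frame(var1 = cmb[1, k], var2 = cmb[2, k],
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(d))
    }))
  }
  by_region <- lapply(split(wstats, wstats$region), function(d)
    if (nrow(d) >= 10) cor_tab(d) else NULL)
  list(overall = cor_tab(wstats), by_region = by_region)
}

#' Principal components of a genotype matrix
#'
#' Mean-imputes missing dosages per site, drops zero-variance sites, centres
#' (optionally scales) and decomposes. A structure sanity check: donor
#' lineages, recipients and progeny should separate on the leading
#' components.
#'
#' @param g a `geno` object with >= 3 samples.
#' @param n_pc number of components to return.
#' @param scale. scale sites to unit variance.
#' @return `list(scores = samples x PCs matrix, var_frac = variance
#'   fractions)`.
#' @export
pca_genotypes <- function(g, n_pc = 10, scale. = FALSE) {
  stopifnot(length(g$samples) >= 3)
  x <- t(g$gt)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0) stop("zero-variance genotype matrix")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_pc, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       var_frac = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}
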