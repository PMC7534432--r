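#' Select family-informative sites
#'
#' A site is informative for a family when the donor parent and every
#' recipient parent are homozygous, non-missing, mutually concordant within
#' the recipients, and the donor differs from the recipients. Heterozygous
#' or missing parent calls make a site non-informative. Chromosomes with
#' fewer than `min_per_chrom` informative sites are flagged uncallable.
#'
#' @param bundle a family bundle from [split_by_family()].
#' @param min_per_chrom minimum informative sites per chromosome (default
#'   20).
#' @return `list(sites, uncallable, density_per_mbp)`: `sites` is a
#'   `data.frame` (chrom, pos, site_idx, donor_code, recipient_code) where
#'   `site_idx` indexes the bundle's variant table; `uncallable` names
#'   flagged chromosomes.
#' @export
select_informative_sites <- function(bundle, min_per_chrom = 20) {
  g <- bundle$geno
  dp <- g$gt[, bundle$donor_parent]
  rp <- g$gt[, bundle$recipient_parents, drop = FALSE]
  rp_hom <- rowSums(is.na(rp) | rp == 1L) == 0 &
    apply(rp, 1, function(x) length(unique(x)) == 1)
  rec_code <- rp[, 1]
  info <- !is.na(dp) & dp != 1L & rp_hom & dp != rec_code
  sites <- data.frame(chrom = g$variants$chrom[info],
                      pos = g$variants$pos[info],
                      site_idx = which(info),
                      donor_code = dp[info],
                      recipient_code = rec_code[info],
                      stringsAsFactors = FALSE)
  tab <- table(sites$chrom)
  uncallable <- union(setdiff(unique(g$variants$chrom), names(tab)),
                      names(tab)[tab < min_per_chrom])
  span <- tapply(sites$pos, sites$chrom, function(p) diff(range(p)))
  dens <- as.numeric(tab[names(span)]) / pmax(span / 1e6, 1e-9)
  list(sites = sites, uncallable = uncallable,
       density_per_mbp = stats::setNames(dens, names(span)))
}

## donor-allele dosage of progeny at informative sites: observed code counts
## alt alleles; where the donor parent is hom-ref (code 0) the donor-allele
## dosage is 2 - code
donor_dosage <- function(codes, donor_code) {
  ifelse(donor_code == 2L, codes, 2L - codes)
}

## ---- 3-state hidden-path decoder ------------------------------------------
## states: 1 = recipient (donor dosage 0), 2 = donor_het (1), 3 = donor_hom (2)

emission_loglik <- function(obs, epsilon) {
  E <- matrix(log(epsilon / 2), nrow = length(obs), ncol = 3)
  ok <- !is.na(obs)
  for (s in 1:3) E[ok & obs == (s - 1L), s] <- log(1 - epsilon)
  E[!ok, ] <- 0
  E
}

## transition: with prob 1 - exp(-switch_rate * d) the state is redrawn
## uniformly over the 3 states, so stay -> 1 as d -> 0
transition_logliks <- function(dist_bp, switch_rate) {
  q <- 1 - exp(-switch_rate * dist_bp)
  list(stay = log(1 - 2 * q / 3), move = log(q / 3))
}

viterbi3 <- function(E, stay, move) {
  n <- nrow(E)
  if (n == 0) return(integer(0))
  delta <- E[1, ] + log(1 / 3)
  psi <- matrix(0L, n, 3)
  for (t in seq_len(n - 1)) {
    cand <- rbind(delta + c(stay[t], move[t], move[t]),
                  delta + c(move[t], stay[t], move[t]),
                  delta + c(move[t], move[t], stay[t]))
    psi[t + 1, ] <- max.col(cand, ties.method = "first")
    delta <- cand[cbind(1:3, psi[t + 1, ])] + E[t + 1, ]
  }
  if (!all(is.finite(delta))) stop("non-finite path likelihood (degenerate epsilon?)")
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in rev(seq_len(n - 1))) path[t] <- psi[t + 1, path[t + 1]]
  path
}

posterior3 <- function(E, stay, move) {
  n <- nrow(E)
  P <- exp(E)
  a <- matrix(0, n, 3); b <- matrix(0, n, 3)
  a[1, ] <- P[1, ] / 3
  a[1, ] <- a[1, ] / sum(a[1, ])
  if (n > 1) for (t in 2:n) {
    s <- exp(stay[t - 1]); m <- exp(move[t - 1])
    Tm <- matrix(m, 3, 3); diag(Tm) <- s
    a[t, ] <- (a[t - 1, ] %*% Tm) * P[t, ]
    a[t, ] <- a[t, ] / sum(a[t, ])
  }
  b[n, ] <- 1
  if (n > 1) for (t in (n - 1):1) {
    s <- exp(stay[t]); m <- exp(move[t])
    Tm <- matrix(m, 3, 3); diag(Tm) <- s
    b[t, ] <- Tm %*% (P[t + 1, ] * b[t + 1, ])
    b[t, ] <- b[t, ] / sum(b[t, ])
  }
  g <- a * b
  g / rowSums(g)
}

## decoded path -> segments with boundaries at midpoints between flanking
## informative sites; the chromosome-end segments extend to the span ends
path_to_segments <- function(path, pos, post) {
  r <- rle(path)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, utils::head(idx_end, -1) + 1L)
  n <- length(pos)
  cuts <- (pos[idx_end[-length(idx_end)]] + pos[idx_start[-1]]) / 2
  starts <- c(pos[1], cuts)
  ends <- c(cuts, pos[n] + 1)
  score <- vapply(seq_along(r$values), function(k) {
    mean(post[cbind(idx_start[k]:idx_end[k], r$values[k])])
  }, 0)
  data.frame(start = starts, end = ends,
             state = c("recipient", "donor_het", "donor_hom")[r$values],
             n_informative = r$lengths, score = score)
}

## relabel short/thin donor segments as recipient, then merge runs
apply_min_filters <- function(seg, min_markers, min_length) {
  demote <- seg$state != "recipient" &
    (seg$n_informative < min_markers | (seg$end - seg$start) < min_length)
  seg$state[demote] <- "recipient"
  if (nrow(seg) > 1) {
    grp <- cumsum(c(TRUE, seg$state[-1] != seg$state[-nrow(seg)]))
    seg <- data.frame(
      start = as.numeric(tapply(seg$start, grp, min)),
      end = as.numeric(tapply(seg$end, grp, max)),
      state = as.character(tapply(seg$state, grp, `[`, 1)),
      n_informative = as.integer(tapply(seg$n_informative, grp, sum)),
      score = as.numeric(
        tapply(seg$score * seg$n_informative, grp, sum) /
          tapply(seg$n_informative, grp, sum)),
      stringsAsFactors = FALSE)
  }
  rownames(seg) <- NULL
  seg
}

#' Call introgression segments from progeny dosages
#'
#' Parent-informed identity-by-descent segment calling: at each family's
#' informative sites, progeny donor-allele dosages are decoded through a
#' three-state hidden path (recipient, heterozygous donor, homozygous donor)
#' with a genotyping-error emission model (`epsilon`) and
#' distance-dependent state switching (`switch_rate` per bp). The most
#' probable path is decoded (Viterbi); adjacent same-state sites merge into
#' segments with boundaries at the midpoints between flanking informative
#' sites. Donor segments supported by fewer than `min_markers` sites or
#' shorter than `min_length` are relabelled recipient.
#'
#' @param bundle family bundle from [split_by_family()].
#' @param info informative sites from [select_informative_sites()].
#' @param epsilon genotyping error probability in `(0, 0.5)`.
#' @param switch_rate state-switch intensity per bp (about the expected
#'   breakpoint density; the desk-scale default 1e-7/bp corresponds to ~4
#'   effective meioses of a 1.5-Morgan, 60-Mbp chromosome; use ~1e-8 for
#'   full-scale wheat chromosomes).
#' @param min_markers minimum informative sites supporting a donor segment.
#' @param min_length minimum donor segment length in bp.
#' @param samples progeny ids to call (default: the bundle's progeny).
#' @return SegmentCall `data.frame`: sample, chrom, start, end (0-based
#'   half-open), state, n_informative, score (mean posterior of the decoded
#'   state). Calls tile each sample's informative-site span.
#' @export
call_segments <- function(bundle, info = select_informative_sites(bundle),
                          epsilon = 0.01, switch_rate = 1e-7,
                          min_markers = 5, min_length = 2e5,
                          samples = bundle$progeny) {
  stopifnot(epsilon > 0, epsilon < 0.5, switch_rate > 0)
  g <- bundle$geno
  sites <- info$sites
  out <- list()
  for (cn in setdiff(unique(sites$chrom), info$uncallable)) {
    s <- sites[sites$chrom == cn, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    tl <- transition_logliks(diff(s$pos), switch_rate)
    for (id in samples) {
      codes <- g$gt[s$site_idx, id]
      d <- donor_dosage(codes, s$donor_code)
      E <- emission_loglik(d, epsilon)
      path <- viterbi3(E, tl$stay, tl$move)
      post <- posterior3(E, tl$stay, tl$move)
      seg <- path_to_segments(path, s$pos, post)
      seg <- apply_min_filters(seg, min_markers, min_length)
      out[[length(out) + 1]] <- cbind(sample = id, chrom = cn, seg,
                                      stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      state = character(0), n_informative = integer(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call segments for every family of a population
#'
#' @param g a `geno` object.
#' @param metadata sample metadata (sample, role, family).
#' @param ... passed to [call_segments()].
#' @param min_progeny passed to [split_by_family()].
#' @return Combined SegmentCall `data.frame` with a `family` column.
#' @export
call_segments_all <- function(g, metadata, ..., min_progeny = 1) {
  bundles <- split_by_family(g, metadata, min_progeny = min_progeny)
  out <- lapply(bundles, function(b) {
    calls <- call_segments(b, ...)
    if (nrow(calls)) calls$family <- b$family
    calls
  })
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  rownames(res) <- NULL
  res
}

## ---- segment statistics ----------------------------------------------------

donor_states <- c("donor_het", "donor_hom")

#' Per-line donor genome proportion
#'
#' Total length of donor segments divided by the genome size, times 100.
#' Heterozygous segments count full length by default (the length-based
#' field formula); `het_weight = 0.5` gives the allele-dosage proportion.
#'
#' @param calls SegmentCall `data.frame`.
#' @param genome_size_bp genome denominator in bp (4.3e9 for the real
#'   *Ae. tauschii* genome; pass the simulated genome size at desk scale).
#' @param het_weight weight of heterozygous donor segments.
#' @return Named numeric vector: percent donor genome per sample (samples
#'   with no donor segment report 0).
#' @export
donor_proportion <- function(calls, genome_size_bp, het_weight = 1) {
  stopifnot(genome_size_bp > 0)
  w <- ifelse(calls$state == "donor_hom", 1,
              ifelse(calls$state == "donor_het", het_weight, 0))
  len <- (calls$end - calls$start) * w
  out <- tapply(len, calls$sample, sum) / genome_size_bp * 100
  out[is.na(out)] <- 0
  stats::setNames(as.vector(out), names(out))
}

#' Introgression efficiency
#'
#' Observed donor proportion as a percentage of the pedigree expectation
#' (25% for BC1F3): `proportion / expected * 100`.
#'
#' @param proportion_pct donor genome proportion(s) in percent.
#' @param expected_pct expected proportion (default 25).
#' @return Efficiency in percent.
#' @export
introgression_efficiency <- function(proportion_pct, expected_pct = 25) {
  stopifnot(expected_pct > 0)
  proportion_pct / expected_pct * 100
}

#' Summarise segment lengths by sharing class
#'
#' Per chromosome and sharing class (line--donor = donor segments,
#' line--recipient = recipient segments), the mean, SD, min and max of
#' segment length expressed as percent of chromosome length, plus a Welch
#' two-sample test comparing the two classes' scaled length distributions.
#'
#' @param calls SegmentCall `data.frame`.
#' @param specs chromosome spec `data.frame`.
#' @return `list(summary = per-chromosome/class data.frame, test = htest or
#'   NULL when a class is empty)`.
#' @export
summarize_ibd_lengths <- function(calls, specs) {
  L <- stats::setNames(specs$length_bp, specs$name)
  cls <- ifelse(calls$state %in% donor_states, "line_donor", "line_recipient")
  pct <- 100 * (calls$end - calls$start) / L[calls$chrom]
  df <- data.frame(chrom = calls$chrom, class = cls, pct = pct)
  agg <- do.call(rbind, lapply(split(df, list(df$chrom, df$class), drop = TRUE),
    function(d) data.frame(chrom = d$chrom[1], class = d$class[1],
                           mean = mean(d$pct), sd = stats::sd(d$pct),
                           min = min(d$pct), max = max(d$pct))))
  rownames(agg) <- NULL
  test <- NULL
  a <- pct[cls == "line_donor"]; b <- pct[cls == "line_recipient"]
  if (length(a) >= 2 && length(b) >= 2)
    test <- stats::t.test(b, a)
  list(summary = agg[order(agg$chrom, agg$class), ], test = test)
}

#' Scaled donor-segment start positions
#'
#' Maps each donor segment start to `100 * start / chromosome_length`,
#' the scale used for cross-chromosome density plots of segment starts.
#'
#' @param calls SegmentCall `data.frame`.
#' @param specs chromosome spec `data.frame`.
#' @return `data.frame` (sample, chrom, start, scaled_start in 0--100).
#' @export
segment_start_density <- function(calls, specs) {
  L <- stats::setNames(specs$length_bp, specs$name)
  d <- calls[calls$state %in% donor_states, , drop = FALSE]
  data.frame(sample = d$sample, chrom = d$chrom, start = d$start,
             scaled_start = 100 * d$start / L[d$chrom],
             row.names = NULL)
}

## non-overlapping windows over one chromosome
tile_windows <- function(L, window) {
  starts <- (seq_len(ceiling(L / window)) - 1) * window
  data.frame(start = starts, end = pmin(starts + window, L))
}

## count intervals overlapping each window of a regular tiling (any overlap)
count_overlaps <- function(starts, ends, win_start0, step, n_win) {
  counts <- numeric(n_win + 1)
  i1 <- pmax(floor((starts - win_start0) / step) + 1, 1)
  i2 <- pmin(ceiling((ends - win_start0) / step), n_win)
  ok <- i1 <= i2 & i2 >= 1 & i1 <= n_win
  for (k in which(ok)) {
    counts[i1[k]] <- counts[i1[k]] + 1
    counts[i2[k] + 1] <- counts[i2[k] + 1] - 1
  }
  cumsum(counts)[seq_len(n_win)]
}

#' Windowed introgression frequency
#'
#' For non-overlapping windows (default 5 Mbp), the number (and fraction) of
#' lines whose donor segments overlap the window by any amount.
#'
#' @param calls SegmentCall `data.frame`.
#' @param specs chromosome spec `data.frame`.
#' @param window window size in bp.
#' @param n_lines denominator for the fraction (default: distinct samples in
#'   `calls`).
#' @return WindowStatTable `data.frame` (chrom, start, end, if_count,
#'   if_frac).
#' @export
window_introgression_frequency <- function(calls, specs, window = 5e6,
                                           n_lines = length(unique(calls$sample))) {
  stopifnot(window > 0)
  d <- calls[calls$state %in% donor_states, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(specs))) {
    cn <- specs$name[i]
    w <- tile_windows(specs$length_bp[i], window)
    dc <- d[d$chrom == cn, , drop = FALSE]
    cnt <- numeric(nrow(w))
    if (nrow(dc)) {
      # count distinct lines per window: merge each line's donor intervals
      per_line <- split(dc, dc$sample)
      for (dl in per_line)
        cnt <- cnt + pmin(count_overlaps(dl$start, dl$end, 0, window,
                                         nrow(w)), 1)
    }
    out[[cn]] <- data.frame(chrom = cn, start = w$start, end = w$end,
                            if_count = cnt, if_frac = cnt / n_lines)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locus-level selection scan in a target region
#'
#' Counts donor-shared and recipient-shared segments overlapping each
#' window (default 1 kb, tiled) of a region, the track pair used to examine
#' selection against a donor allele (the *Tg*-region comparison). The dip is
#' the window minimising the donor track; with ties (e.g. a run of zero
#' counts under complete selection) the centre of the minimising windows is
#' reported.
#'
#' @param calls SegmentCall `data.frame`.
#' @param chrom chromosome name.
#' @param region_start,region_end region bounds in bp (0-based half-open).
#' @param window window size in bp (default 1000).
#' @param step step between window starts (default `window`, i.e. tiled).
#' @return `list(track = data.frame(chrom, start, end, donor_count,
#'   recipient_count), dip_bp = midpoint of the donor-track minimum)`.
#' @export
tg_region_scan <- function(calls, chrom, region_start, region_end,
                           window = 1e3, step = window) {
  stopifnot(region_end > region_start, window > 0, step > 0, step <= window)
  n_win <- ceiling((region_end - region_start) / step)
  starts <- region_start + (seq_len(n_win) - 1) * step
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  don <- cc[cc$state %in% donor_states, , drop = FALSE]
  rec <- cc[cc$state == "recipient", , drop = FALSE]
  count_track <- function(d) {
    if (nrow(d) == 0) return(numeric(n_win))
    if (step == window)
      return(count_overlaps(d$start, d$end, region_start, step, n_win))
    vapply(seq_len(n_win), function(k)
      sum(d$start < starts[k] + window & d$end > starts[k]), 0)
  }
  track <- data.frame(chrom = chrom, start = starts,
                      end = pmin(starts + window, region_end),
                      donor_count = count_track(don),
                      recipient_count = count_track(rec))
  dip <- which(track$donor_count == min(track$donor_count))
  dip <- dip[ceiling(length(dip) / 2)]
  list(track = track, dip_bp = (track$start[dip] + track$end[dip]) / 2)
}

## ---- recovery vs truth -----------------------------------------------------

interval_intersect_len <- function(as, ae, bs, be) {
  if (length(as) == 0 || length(bs) == 0) return(0)
  sum(pmax(0, outer(ae, be, pmin) - outer(as, bs, pmax)))
}

#' Length-weighted recovery of called donor segments against truth
#'
#' Compares donor calls (either donor state) with true donor-origin
#' intervals per sample: precision = intersected length / called length,
#' recall = intersected length / true length, both length-weighted over the
#' whole call set. Boundary error is the distance from each true internal
#' donor boundary to the nearest called donor boundary on the same
#' chromosome and sample.
#'
#' @param calls SegmentCall `data.frame`.
#' @param truth TruthSet `data.frame` with a `sample` column.
#' @return `list(precision, recall, boundary_errors, called_bp, true_bp)`.
#' @export
segment_recovery <- function(calls, truth) {
  dcall <- calls[calls$state %in% donor_states, , drop = FALSE]
  dtrue <- truth[truth$origin %in% donor_states, , drop = FALSE]
  inter <- 0; called_bp <- sum(dcall$end - dcall$start)
  true_bp <- sum(dtrue$end - dtrue$start)
  berr <- numeric(0)
  for (id in unique(truth$sample)) {
    tc <- dtrue[dtrue$sample == id, , drop = FALSE]
    cc <- dcall[dcall$sample == id, , drop = FALSE]
    for (cn in unique(tc$chrom)) {
      t1 <- tc[tc$chrom == cn, , drop = FALSE]
      c1 <- cc[cc$chrom == cn, , drop = FALSE]
      inter <- inter + interval_intersect_len(c1$start, c1$end,
                                              t1$start, t1$end)
      tb <- c(t1$start, t1$end)
      cb <- c(c1$start, c1$end)
      if (length(tb) && length(cb))
        berr <- c(berr, vapply(tb, function(x) min(abs(cb - x)), 0))
    }
  }
  list(precision = if (called_bp > 0) inter / called_bp else NA_real_,
       recall = if (true_bp > 0) inter / true_bp else NA_real_,
       boundary_errors = berr, called_bp = called_bp, true_bp = true_bp)
}

#' Write segment calls as BED
#'
#' 0-based half-open BED: chrom, start, end, name = sample, score =
#' supporting marker count, extra column = state.
#' @param calls SegmentCall `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(calls, path) {
  bed <- data.frame(calls$chrom,
                    format(calls$start, scientific = FALSE, trim = TRUE),
                    format(calls$end, scientific = FALSE, trim = TRUE),
                    calls$sample, calls$n_informative, calls$state)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
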