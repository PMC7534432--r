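# Independent brute-force oracles. These re-derive expected values from
# first principles (exhaustive enumeration, closed forms) and never call the
# code paths they are used to check.

# log-likelihood of one explicit state path under the 3-state decoding model
# (states 1..3 emit donor dosages 0..2; uniform prior; distance-dependent
# uniform-redraw transitions)
oracle_path_loglik <- function(path, obs, pos, epsilon, switch_rate) {
  ll <- log(1 / 3)
  for (t in seq_along(path)) {
    if (!is.na(obs[t]))
      ll <- ll + if (obs[t] == path[t] - 1) log(1 - epsilon) else log(epsilon / 2)
    if (t > 1) {
      q <- 1 - exp(-switch_rate * (pos[t] - pos[t - 1]))
      ll <- ll + if (path[t] == path[t - 1]) log(1 - 2 * q / 3) else log(q / 3)
    }
  }
  ll
}

# exhaustive argmax over all 3^n paths (vectorised over the path matrix so
# n = 12 stays tractable); returns the best log-likelihood
.oracle_path_cache <- new.env(parent = emptyenv())
oracle_all_paths <- function(n) {
  key <- as.character(n)
  if (is.null(.oracle_path_cache[[key]]))
    .oracle_path_cache[[key]] <-
      as.matrix(expand.grid(rep(list(1:3), n), KEEP.OUT.ATTRS = FALSE))
  .oracle_path_cache[[key]]
}

oracle_best_paths <- function(obs, pos, epsilon, switch_rate) {
  n <- length(obs)
  paths <- oracle_all_paths(n)
  ll <- rep(log(1 / 3), nrow(paths))
  for (t in seq_len(n)) {
    if (!is.na(obs[t]))
      ll <- ll + ifelse(paths[, t] - 1 == obs[t], log(1 - epsilon),
                        log(epsilon / 2))
    if (t > 1) {
      q <- 1 - exp(-switch_rate * (pos[t] - pos[t - 1]))
      ll <- ll + ifelse(paths[, t] == paths[, t - 1], log(1 - 2 * q / 3),
                        log(q / 3))
    }
  }
  best <- max(ll)
  list(loglik = best,
       paths = paths[ll >= best - 1e-9, , drop = FALSE])
}

# breakpoint count by explicit pairwise scan of the NA-stripped code vector
oracle_breakpoint_count <- function(codes) {
  x <- codes[!is.na(codes)]
  if (length(x) < 2) return(0L)
  cnt <- 0L
  for (i in seq_len(length(x) - 1)) if (x[i] != x[i + 1]) cnt <- cnt + 1L
  cnt
}

# per-site pi by enumerating all haplotype pairs: expand diploid genotypes
# into alleles and count differing unordered pairs
oracle_site_pi <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) < 2) return(NA_real_)
  hap <- unlist(lapply(g, function(x) switch(as.character(x),
                                             "0" = c(0, 0),
                                             "1" = c(0, 1),
                                             "2" = c(1, 1))))
  diffs <- 0; pairs <- 0
  for (i in seq_len(length(hap) - 1))
    for (j in (i + 1):length(hap)) {
      pairs <- pairs + 1
      if (hap[i] != hap[j]) diffs <- diffs + 1
    }
  diffs / pairs
}

# exact one-locus genotype distribution after n_self selfings starting from
# the BC1 distribution (1/2 recipient hom, 1/2 het): Markov chain enumeration
oracle_bc1_selfed_dist <- function(n_self) {
  p <- c(rr = 0.5, rd = 0.5, dd = 0)
  for (g in seq_len(n_self)) {
    p <- c(rr = p[["rr"]] + p[["rd"]] / 4,
           rd = p[["rd"]] / 2,
           dd = p[["dd"]] + p[["rd"]] / 4)
  }
  p
}
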