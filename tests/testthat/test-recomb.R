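test_that("phase-transition breakpoints match hand-worked examples", {
  pos <- (1:5) * 1e6 - 1
  g <- make_geno(cbind(a = c(0L, 0L, 2L, 2L, 2L)), pos = pos)
  bp <- detect_breakpoints(g)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$left_pos, pos[2])
  expect_equal(bp$right_pos, pos[3])

  g2 <- make_geno(cbind(a = c(0L, 1L, 2L)))
  expect_equal(nrow(detect_breakpoints(g2)), 2)

  # missing codes are skipped; flanks are nearest non-missing neighbours
  g3 <- make_geno(cbind(a = c(0L, NA, 2L)), pos = c(1e6, 2e6, 3e6))
  bp3 <- detect_breakpoints(g3)
  expect_equal(c(bp3$left_pos, bp3$right_pos), c(1e6, 3e6))
})

test_that("breakpoint counting equals brute force on all short vectors", {
  # exhaustive over all {0,1,2,NA}^4 vectors
  codes <- c(0L, 1L, 2L, NA)
  grid <- expand.grid(codes, codes, codes, codes)
  for (i in seq_len(nrow(grid))) {
    v <- as.integer(grid[i, ])
    g <- make_geno(matrix(v, ncol = 1, dimnames = list(NULL, "a")))
    n <- suppressWarnings(nrow(detect_breakpoints(g)))
    expect_equal(n, oracle_breakpoint_count(v))
  }
})

test_that("breakpoints are invariant under allele-polarity flip", {
  set.seed(3)
  for (i in 1:50) {
    v <- sample(c(0:2, NA), 12, replace = TRUE)
    g <- make_geno(matrix(v, ncol = 1, dimnames = list(NULL, "a")))
    gf <- make_geno(matrix(2L - v, ncol = 1, dimnames = list(NULL, "a")))
    expect_equal(suppressWarnings(nrow(detect_breakpoints(g))),
                 suppressWarnings(nrow(detect_breakpoints(gf))))
  }
})

test_that("sliding-window RBP counts assign midpoints to overlapping windows", {
  specs <- chrom_specs("c1", 5e6, 2e6)
  bp <- data.frame(sample = "a", chrom = "c1",
                   left_pos = c(1.4e6, 2.4e6), right_pos = c(1.6e6, 2.6e6),
                   midpoint = c(1.5e6, 2.5e6))
  w <- window_rbp(bp, specs, window = 2e6, step = 1e6)
  expect_equal(w$rbp_total[w$start == 0], 1)
  expect_equal(w$rbp_total[w$start == 1e6], 2)
  expect_equal(w$rbp_total[w$start == 2e6], 1)
  # no breakpoints -> all zeros
  w0 <- window_rbp(bp[0, ], specs, window = 2e6, step = 1e6)
  expect_true(all(w0$rbp_total == 0))
})

test_that("each interior midpoint contributes to exactly window/step windows", {
  specs <- chrom_specs("c1", 60e6, 24e6)
  set.seed(9)
  mids <- runif(200, 3e6, 57e6)  # interior: away from chromosome ends
  bp <- data.frame(sample = "a", chrom = "c1", left_pos = mids - 1,
                   right_pos = mids + 1, midpoint = mids)
  w <- window_rbp(bp, specs, window = 2e6, step = 1e6)
  expect_equal(sum(w$rbp_total), 2 * length(mids))
})

test_that("the 95th-percentile hotspot threshold interpolates linearly", {
  specs <- chrom_specs("c1", 101e6, 40e6)
  mids <- rep((seq_len(100) - 0.5) * 1e6, times = seq_len(100))
  bp <- data.frame(sample = "a", chrom = "c1", left_pos = mids - 1,
                   right_pos = mids + 1, midpoint = mids)
  w <- window_rbp(bp, specs, window = 1e6, step = 1e6)
  w <- w[seq_len(100), ]  # totals are exactly 1..100
  expect_equal(w$rbp_total, as.numeric(1:100))
  h <- call_hotspots(w)
  expect_equal(h$threshold, 95.05)
  expect_equal(nrow(h$windows), 5)
  # constant totals: everything ties at the threshold
  wc <- w; wc$rbp_total <- 7
  hc <- call_hotspots(wc)
  expect_true(hc$tied)
  expect_equal(nrow(hc$windows), 100)
  # all-zero totals: empty set with a warning
  wz <- w; wz$rbp_total <- 0
  expect_warning(hz <- call_hotspots(wz), "zero")
  expect_equal(nrow(hz$windows), 0)
})

test_that("permutation overlap matches the hypergeometric expectation", {
  universe <- paste0("w", 1:100)
  res <- overlap_enrichment(universe[1:10], universe[11:20], universe,
                            n_perm = 2000, seed = 4)
  # E[overlap] = kA kB / M = 1.0
  se <- res$null_sd / sqrt(res$n_perm)
  expect_lt(abs(res$null_mean - 1.0), 3 * se)
  # identical 5-window sets: analytic null mean 0.25, minimal p
  res2 <- overlap_enrichment(universe[1:5], universe[1:5], universe,
                             n_perm = 1000, seed = 5)
  expect_equal(res2$observed, 5)
  expect_lt(abs(res2$null_mean - 0.25), 3 * res2$null_sd / sqrt(1000))
  expect_equal(res2$p_value, 1 / 1001)
  expect_gt(res2$fold, 10)
  # disjoint sets in a large universe: no enrichment
  res3 <- overlap_enrichment(universe[1:10], universe[51:60], universe,
                             n_perm = 500, seed = 6)
  expect_lt(res3$fold, 1)
  expect_gt(res3$p_value, 0.5)
  expect_error(overlap_enrichment(universe[1:5], "z1", universe), "subset")
  expect_error(overlap_enrichment(universe, universe, universe[1:5]),
               "subset")
})

test_that("the family distribution test is a tie-corrected Kruskal-Wallis", {
  set.seed(8)
  counts <- c(rpois(30, 10), rpois(30, 10))
  fam <- rep(c("f1", "f2"), each = 30)
  kw <- family_distribution_test(counts, fam)
  ref <- stats::kruskal.test(counts, as.factor(fam))
  expect_equal(kw$p.value, ref$p.value)
  # k = 2 agrees with the two-sample rank test through the chi-square map
  mw <- suppressWarnings(stats::wilcox.test(counts[fam == "f1"],
                                            counts[fam == "f2"],
                                            correct = FALSE))
  expect_equal(kw$p.value, mw$p.value, tolerance = 0.02)
  # strong shift is detected
  shifted <- c(rpois(30, 4), rpois(30, 20))
  expect_lt(family_distribution_test(shifted, fam)$p.value, 0.001)
  # degenerate data
  expect_warning(deg <- family_distribution_test(rep(3, 20),
                                                 rep(c("a", "b"), 10)),
                 "identical")
  expect_equal(deg$p.value, 1)
})
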