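# decoder fixtures: bundle columns are (donor parent, recipient parent,
# progeny...); informative sites require homozygous, different parents

test_that("informative-site selection keeps only fixed, differing parents", {
  gt <- cbind(D = c(2L, 1L, 2L, 0L, NA, 2L),
              R = c(0L, 0L, 2L, 2L, 0L, NA),
              p1 = c(0L, 1L, 2L, 1L, 0L, 2L))
  b <- make_bundle(gt)
  info <- select_informative_sites(b, min_per_chrom = 1)
  # kept: site 1 (hom-alt vs hom-ref) and site 4 (hom-ref vs hom-alt)
  expect_equal(info$sites$site_idx, c(1L, 4L))
  expect_equal(info$sites$donor_code, c(2L, 0L))
  # a chromosome below the informative minimum is flagged uncallable
  info20 <- select_informative_sites(b, min_per_chrom = 20)
  expect_equal(info20$uncallable, "chr1D")
  expect_equal(nrow(call_segments(b, info20)), 0)
})

test_that("progeny identical to the recipient yields one recipient segment", {
  n <- 40
  gt <- cbind(D = rep(2L, n), R = rep(0L, n), p1 = rep(0L, n))
  b <- make_bundle(gt)
  calls <- call_segments(b)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "recipient")
  expect_equal(calls$n_informative, n)
  # calls tile the informative-site span
  pos <- b$geno$variants$pos
  expect_equal(calls$start, pos[1])
  expect_equal(calls$end, pos[n] + 1)
})

test_that("an isolated genotyping error does not break a donor block", {
  n <- 30
  p <- rep(2L, n); p[15] <- 0L
  gt <- cbind(D = rep(2L, n), R = rep(0L, n), p1 = p)
  b <- make_bundle(gt)
  calls <- call_segments(b)
  expect_equal(calls$state, "donor_hom")
  expect_equal(nrow(calls), 1)
})

test_that("decoded paths attain the exhaustive-enumeration maximum", {
  set.seed(101)
  eps <- 0.02; sr <- 1e-6
  for (i in 1:60) {
    n <- sample(2:8, 1)
    pos <- sort(sample(1:5e6, n))
    obs <- sample(c(0:2, NA), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.3, 0.2))
    E <- emission_loglik(obs, eps)
    tl <- transition_logliks(diff(pos), sr)
    path <- viterbi3(E, tl$stay, tl$move)
    best <- oracle_best_paths(obs, pos, eps, sr)
    expect_equal(oracle_path_loglik(path, obs, pos, eps, sr), best$loglik,
                 tolerance = 1e-9)
  }
})

test_that("calls are invariant to adding non-informative sites", {
  sim <- tiny_sim(seed = 8, n_lines = 6)
  b <- split_by_family(sim$geno, sim$metadata, min_progeny = 1)[[2]]
  calls1 <- call_segments(b)
  # add sites where both parents share the same genotype (non-informative)
  nadd <- 60
  extra_gt <- matrix(1L, nrow = nadd, ncol = ncol(b$geno$gt),
                     dimnames = list(NULL, colnames(b$geno$gt)))
  extra_v <- data.frame(chrom = "chr1D",
                        pos = seq(1.05e6, 9.5e6, length.out = nadd),
                        id = paste0("x", seq_len(nadd)), ref = "A", alt = "T")
  g2 <- geno_matrix(rbind(b$geno$gt, extra_gt),
                    rbind(b$geno$variants, extra_v))
  b2 <- b; b2$geno <- g2
  calls2 <- call_segments(b2)
  expect_equal(calls1, calls2)
})

test_that("per-line calls tile the informative-site span", {
  sim <- tiny_sim(seed = 12, n_lines = 6, noise = noise_spec(0.2, 0.01))
  b <- split_by_family(sim$geno, sim$metadata, min_progeny = 1)[[2]]
  info <- select_informative_sites(b, min_per_chrom = 5)
  calls <- call_segments(b, info)
  for (id in b$progeny) for (cn in unique(calls$chrom)) {
    cc <- calls[calls$sample == id & calls$chrom == cn, ]
    cc <- cc[order(cc$start), ]
    span <- range(info$sites$pos[info$sites$chrom == cn])
    expect_equal(cc$start[1], span[1])
    expect_equal(cc$end[nrow(cc)], span[2] + 1)
    if (nrow(cc) > 1)
      expect_true(all(cc$start[-1] == cc$end[-nrow(cc)]))
  }
})

test_that("donor proportion and efficiency follow the stated formulas", {
  calls <- data.frame(sample = c("a", "a", "b"), chrom = "c1",
                      start = c(0, 5e6, 0), end = c(2e6, 6e6, 1e6),
                      state = c("donor_hom", "donor_het", "recipient"),
                      n_informative = 10L, score = 1)
  p <- donor_proportion(calls, genome_size_bp = 12e6)
  expect_equal(unname(p[c("a", "b")]), c(25, 0))
  expect_equal(unname(donor_proportion(calls, 12e6, het_weight = 0.5)["a"]),
               (2e6 + 0.5e6) / 12e6 * 100)
  # a fully donor_hom line is 100%
  full <- data.frame(sample = "z", chrom = "c1", start = 0, end = 420e6,
                     state = "donor_hom", n_informative = 10L, score = 1)
  expect_equal(unname(donor_proportion(full, 420e6)), 100)
  expect_equal(introgression_efficiency(25), 100)
  expect_equal(introgression_efficiency(0.05), 0.2)
  expect_equal(introgression_efficiency(12.5), 50)
})

test_that("segment length summaries scale by chromosome length", {
  specs <- chrom_specs("c1", 300e6, 120e6)
  calls <- data.frame(sample = "a", chrom = "c1", start = 0, end = 30e6,
                      state = "donor_hom", n_informative = 10L, score = 1)
  s <- summarize_ibd_lengths(calls, specs)
  expect_equal(s$summary$mean, 10)
  expect_equal(s$summary$min, 10)
  expect_equal(s$summary$max, 10)
  expect_null(s$test)  # one class only
})

test_that("the sharing-class location test is calibrated and powered", {
  specs <- chrom_specs("c1", 100e6, 40e6)
  mk <- function(lens, state) data.frame(
    sample = "a", chrom = "c1", start = 0, end = lens, state = state,
    n_informative = 10L, score = 1)
  set.seed(5)
  # null calibration: both classes drawn from the same distribution
  pvals <- vapply(1:400, function(i) {
    calls <- rbind(mk(rexp(20, 1e-7), "donor_hom"),
                   mk(rexp(20, 1e-7), "recipient"))
    summarize_ibd_lengths(calls, specs)$test$p.value
  }, 0)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  # power: recipient segments 6x longer
  rej <- vapply(1:100, function(i) {
    calls <- rbind(mk(rexp(30, 1e-7), "donor_hom"),
                   mk(rexp(30, 1e-7 / 6), "recipient"))
    summarize_ibd_lengths(calls, specs)$test$p.value < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("scaled start positions land in [0, 100]", {
  specs <- chrom_specs("c1", 200e6, 80e6)
  calls <- data.frame(sample = c("a", "a"), chrom = "c1",
                      start = c(0, 100e6), end = c(10e6, 110e6),
                      state = "donor_hom", n_informative = 5L, score = 1)
  d <- segment_start_density(calls, specs)
  expect_equal(d$scaled_start, c(0, 50))
  calls2 <- cached_default_calls(1)
  d2 <- segment_start_density(calls2, cached_default_sim(1)$specs)
  expect_true(all(d2$scaled_start >= 0 & d2$scaled_start <= 100))
})

test_that("window introgression frequency uses any-overlap counting", {
  specs <- chrom_specs("c1", 20e6, 8e6)
  calls <- data.frame(sample = "a", chrom = "c1", start = 0, end = 10e6,
                      state = "donor_het", n_informative = 5L, score = 1)
  w <- window_introgression_frequency(calls, specs, window = 5e6)
  expect_equal(w$if_count, c(1, 1, 0, 0))
  # 1-bp touch still counts
  calls$end <- 10e6 + 1
  w2 <- window_introgression_frequency(calls, specs, window = 5e6)
  expect_equal(w2$if_count, c(1, 1, 1, 0))
  # a line's several segments in one window count once
  calls3 <- rbind(calls, transform(calls, start = 1e6, end = 2e6))
  w3 <- window_introgression_frequency(calls3, specs, window = 5e6)
  expect_equal(w3$if_count[1], 1)
})

test_that("the selection scan returns aligned donor/recipient tracks", {
  calls <- data.frame(sample = c("a", "b"), chrom = "c1",
                      start = c(10e3, 0), end = c(20e3, 50e3),
                      state = c("donor_hom", "recipient"),
                      n_informative = 5L, score = 1)
  scan <- tg_region_scan(calls, "c1", 0, 50e3, window = 1e3)
  expect_equal(nrow(scan$track), 50)
  expect_equal(sum(scan$track$donor_count), 10)
  expect_equal(scan$track$recipient_count, rep(1, 50))
  # empty region gives all-zero tracks
  empty <- tg_region_scan(calls, "c1", 60e3, 70e3, window = 1e3)
  expect_true(all(empty$track$donor_count == 0))
  expect_true(all(empty$track$recipient_count == 0))
})
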