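test_that("founder site counts follow the divergence rate", {
  specs <- chrom_specs("c1", 100e6, 40e6)
  fs <- founder_spec(n_recipient_lines = 1,
                     donor_lineage = c("strangulata", "tauschii"),
                     divergence_rate = c(strangulata = 5, tauschii = 10),
                     recipient_poly_rate = 0)
  # informative count for the strangulata family ~ Poisson(5/Mbp * 100 Mbp)
  counts <- vapply(1:400, function(s) {
    p <- build_founders(specs, fs, seed = s)
    sum(p$H["D1", ] == 1)  # sites where donor 1 differs from recipients
  }, 0)
  se <- sqrt(500 / length(counts))
  expect_lt(abs(mean(counts) - 500), 3 * se)
})

test_that("degenerate founder divergence errors", {
  expect_error(founder_spec(divergence_rate = c(strangulata = 0,
                                                tauschii = 0)), "> 0")
  expect_error(founder_spec(divergence_rate = c(strangulata = 5,
                                                tauschii = 5)), "below")
})

test_that("crossover counts are Poisson with the map length as mean", {
  specs <- chrom_specs("c1", 50e6, 20e6)
  map <- data.frame(chrom = "c1", start = 0, end = 50e6, rate = 2)  # 1 Morgan
  expect_equal(unname(map_morgans(map)), 1)
  panel <- build_founders(specs, founder_spec(n_recipient_lines = 1,
    donor_lineage = "tauschii",
    divergence_rate = c(strangulata = 1, tauschii = 2)), seed = 1)
  f1 <- list(h1 = founder_diplotype(panel, "R1")$h1,
             h2 = founder_diplotype(panel, "D1")$h1)
  set.seed(42)
  n <- vapply(1:10000, function(i)
    length(sample_gamete(f1, map, specs)$crossovers$c1), 0)
  expect_lt(abs(mean(n) - 1), 3 * sqrt(1 / 10000))
  # goodness of fit to Poisson(1)
  kmax <- 5
  obs <- tabulate(pmin(n, kmax) + 1, nbins = kmax + 1)
  p <- dpois(0:(kmax - 1), 1); p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("crossovers respect the intensity support", {
  specs <- chrom_specs(c("c1", "c2"), c(50e6, 50e6), c(20e6, 20e6))
  map <- data.frame(chrom = c("c1", "c2", "c2"),
                    start = c(0, 0, 10e6), end = c(50e6, 10e6, 50e6),
                    rate = c(0, 5, 0))
  panel <- build_founders(specs, founder_spec(n_recipient_lines = 1,
    donor_lineage = "tauschii",
    divergence_rate = c(strangulata = 1, tauschii = 2)), seed = 1)
  f1 <- list(h1 = founder_diplotype(panel, "R1")$h1,
             h2 = founder_diplotype(panel, "D1")$h1)
  set.seed(1)
  for (i in 1:50) {
    g <- sample_gamete(f1, map, specs)
    expect_length(g$crossovers$c1, 0)
    expect_length(g$hap$c1$lab, 1)          # pure parental haplotype
    # all crossovers fall where the intensity is concentrated
    expect_true(all(g$crossovers$c2 >= 0 & g$crossovers$c2 < 10e6))
  }
})

test_that("truth intervals tile every chromosome for every line", {
  sim <- tiny_sim(seed = 5, n_lines = 8)
  for (id in unique(sim$truth$sample)) {
    for (cn in sim$specs$name) {
      t <- sim$truth[sim$truth$sample == id & sim$truth$chrom == cn, ]
      t <- t[order(t$start), ]
      expect_equal(t$start[1], 0)
      expect_equal(t$end[nrow(t)],
                   sim$specs$length_bp[sim$specs$name == cn])
      expect_true(all(t$start[-1] == t$end[-nrow(t)]))
    }
  }
})

test_that("neutral BC1F3 genotype distribution matches exact enumeration", {
  # exact one-locus chain: BC1 (1/2 het) selfed twice
  p <- oracle_bc1_selfed_dist(2)
  expect_equal(unname(p), c(11 / 16, 2 / 16, 3 / 16))
  sim <- cached_default_sim(1)
  fr <- truth_donor_fraction(sim$truth, sim$specs, het_weight = 0.5)
  n <- length(fr)
  # dosage-weighted donor fraction has expectation 1/4
  expect_lt(abs(mean(fr) - 0.25), 3 * sd(fr) / sqrt(n))
  het <- truth_donor_fraction(sim$truth, sim$specs, het_weight = 1) -
    truth_donor_fraction(sim$truth, sim$specs, het_weight = 0)
  expect_lt(abs(mean(het) - p[["rd"]]), 3 * sd(het) / sqrt(n))
})

test_that("selection removes donor carriers at the locus", {
  specs <- tiny_specs()
  freq_at_locus <- function(s, seed = 21) {
    sim <- tiny_sim(seed = seed, n_lines = 40, specs = specs,
                    sspec = if (s > 0)
                      selection_spec("chr1D", 2e6, s = s) else NULL)
    t <- sim$truth[sim$truth$chrom == "chr1D" &
                     sim$truth$start <= 2e6 & sim$truth$end > 2e6, ]
    mean(t$origin != "recipient")
  }
  f <- vapply(c(0, 0.5, 1), freq_at_locus, 0)
  expect_equal(f[3], 0)                    # s = 1: no carriers
  expect_true(f[1] >= f[2] && f[2] >= f[3]) # monotone in s
})

test_that("selection exhausting the resampling budget errors with a diagnostic", {
  specs <- tiny_specs(n = 1)
  map0 <- data.frame(chrom = "chr1D", start = 0, end = 10e6, rate = 1e-9)
  panel <- build_founders(specs, founder_spec(n_recipient_lines = 1,
    donor_lineage = "tauschii",
    divergence_rate = c(strangulata = 1, tauschii = 2)), seed = 1)
  # 5 surviving lines cannot be produced within a 3-attempt budget when
  # roughly half the attempts are discarded as donor carriers
  expect_error(
    advance_pedigree(panel, "R1", "D1", pedigree_spec(n_lines_per_family = 5),
                     map0, selection_spec("chr1D", 5e6, s = 1), seed = 2,
                     max_attempts = 3),
    "surviving")
})

test_that("noise model matches its nominal rates and zero noise is exact", {
  sim0 <- tiny_sim(seed = 9, n_lines = 10, noise = noise_spec(0, 0))
  # zero-noise matrix has no missing entries and dosage domain {0,1,2}
  expect_false(anyNA(sim0$geno$gt))
  expect_true(all(sim0$geno$gt %in% 0:2))
  # informative-site consistency with truth: at sites where donor is fixed
  # alt and recipient fixed ref, dosage must equal the true origin state
  b <- split_by_family(sim0$geno, sim0$metadata, min_progeny = 1)[[2]]
  info <- select_informative_sites(b, min_per_chrom = 1)
  s <- info$sites[1:20, ]
  id <- b$progeny[1]
  tr <- sim0$truth[sim0$truth$sample == id, ]
  for (k in seq_len(nrow(s))) {
    st <- tr$origin[tr$chrom == s$chrom[k] & tr$start <= s$pos[k] &
                      tr$end > s$pos[k]]
    d <- donor_dosage(b$geno$gt[s$site_idx[k], id], s$donor_code[k])
    expect_equal(d, c(recipient = 0L, donor_het = 1L, donor_hom = 2L)[[st]])
  }

  simn <- tiny_sim(seed = 9, n_lines = 10, noise = noise_spec(0.3, 0.01))
  n_entries <- length(simn$geno$gt)
  miss <- mean(is.na(simn$geno$gt))
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / n_entries))
  # same seed => same underlying truth; mismatch rate on observed entries
  obs <- !is.na(simn$geno$gt)
  err <- mean(simn$geno$gt[obs] != sim0$geno$gt[obs])
  expect_lt(abs(err - 0.01), 3 * sqrt(0.01 * 0.99 / sum(obs)))
})

test_that("identical seeds give byte-identical populations", {
  a <- tiny_sim(seed = 13, noise = noise_spec(0.2, 0.01))
  b <- tiny_sim(seed = 13, noise = noise_spec(0.2, 0.01))
  expect_identical(serialize(a$geno, NULL), serialize(b$geno, NULL))
  expect_identical(a$truth, b$truth)
})
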