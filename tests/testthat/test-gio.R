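toy_vcf <- function() system.file("extdata", "toy.vcf", package = "wildintro")

test_that("handcrafted VCF reads with expected codes, skipping multiallelics", {
  expect_warning(g <- read_vcf(toy_vcf()), "non-biallelic")
  expect_equal(dim(g), c(5L, 3L))           # 6 records, 1 multiallelic
  expect_equal(g$samples, c("P1", "P2", "P3"))
  expect_equal(g$variants$pos, c(100, 204, 309, 49, 98))  # 0-based
  expect_equal(unname(g$gt[g$variants$id == "s1", ]), c(0L, 1L, 2L))
  expect_equal(unname(g$gt[g$variants$id == "s3", ]), c(2L, NA, 1L))
  expect_equal(unname(g$gt[g$variants$id == "s6", ]), c(2L, 0L, NA))
})

test_that("VCF write -> read round-trips dosages and positions exactly", {
  sim <- tiny_sim(seed = 3, noise = noise_spec(0.2, 0.01))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$geno, path)
  g2 <- read_vcf(path)
  expect_identical(g2$gt, sim$geno$gt)
  expect_equal(g2$variants$pos, sim$geno$variants$pos)
  expect_equal(g2$variants$ref, sim$geno$variants$ref)
})

test_that("MAF/missingness filtering honours the stated boundaries", {
  # site 1: monomorphic (MAF 0) -> removed at maf_min = 0.05
  # site 2: 1 het among 10 (MAF 1/20 = 0.05) -> retained (boundary keeps)
  # site 3: missing 4/10 -> removed at max_missing = 0.30
  # site 4: missing 3/10 (= 0.30) -> retained (boundary keeps)
  gt <- rbind(rep(0L, 10),
              c(1L, rep(0L, 9)),
              c(rep(NA, 4), 1L, 1L, rep(0L, 4)),
              c(rep(NA, 3), 1L, 1L, rep(0L, 5)))
  g <- make_geno(gt)
  f <- filter_variants(g, maf_min = 0.05, max_missing = 0.30)
  expect_equal(f$variants$id, c("v2", "v4"))
})

test_that("filtering is idempotent and invariant to site/sample order", {
  sim <- tiny_sim(seed = 4, noise = noise_spec(0.25, 0.01))
  f1 <- filter_variants(sim$geno, 0.05, 0.3)
  f2 <- filter_variants(f1, 0.05, 0.3)
  expect_identical(f1$gt, f2$gt)
  # permute samples and sites
  g <- sim$geno
  sp <- sample(ncol(g$gt))
  gp <- geno_matrix(g$gt[, sp], g$variants, g$samples[sp])
  fp <- filter_variants(gp, 0.05, 0.3)
  expect_identical(sort(fp$variants$id), sort(f1$variants$id))
})

test_that("monomorphic removal counts distinct non-missing codes", {
  gt <- rbind(c(2L, 2L, 2L),      # dropped
              c(0L, 2L, 0L),      # kept
              c(0L, NA, 0L),      # dropped: one distinct non-missing code
              c(NA, NA, NA))      # dropped
  g <- make_geno(gt)
  m <- remove_monomorphic(g)
  expect_equal(m$variants$id, "v2")
  expect_warning(remove_monomorphic(make_geno(rbind(c(1L, 1L)))), "monomorphic")
})

test_that("position harmonization keeps, swaps and drops correctly", {
  v <- data.frame(chrom = "c1", pos = c(10, 20, 30),
                  id = paste0("t", 1:3), ref = c("A", "C", "G"),
                  alt = c("T", "G", "A"))
  tgt <- geno_matrix(rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L)), v,
                     c("a", "b"))
  # panel: same site 1; site 2 with ref/alt swapped; site 3 incompatible
  vp <- data.frame(chrom = "c1", pos = c(10, 20, 30),
                   id = paste0("p", 1:3), ref = c("A", "G", "G"),
                   alt = c("T", "C", "C"))
  pan <- geno_matrix(rbind(c(0L, 1L), c(0L, 2L), c(1L, 1L)), vp,
                     c("x", "y"))
  h <- harmonize_positions(tgt, pan)
  expect_equal(unname(h$report["kept"]), 2)
  expect_equal(unname(h$report["swapped"]), 1)
  expect_equal(nrow(h$target$gt), 2)
  # swapped site's panel dosages flipped 0 <-> 2
  expect_equal(unname(h$panel$gt[h$panel$variants$pos == 20, ]), c(2L, 0L))
  # identical tables: all kept, none swapped
  h2 <- harmonize_positions(tgt, tgt)
  expect_equal(unname(h2$report[c("kept", "swapped")]), c(3, 0))
  # disjoint positions error
  vq <- vp; vq$pos <- vq$pos + 1000
  expect_error(harmonize_positions(tgt, geno_matrix(pan$gt, vq, pan$samples)),
               "no shared")
})

test_that("family splitting bundles progeny with parents and flags small families", {
  sim <- tiny_sim(seed = 6, n_lines = 12)
  b <- split_by_family(sim$geno, sim$metadata, min_progeny = 10)
  expect_length(b, 2)
  expect_false(any(vapply(b, `[[`, TRUE, "excluded")))
  expect_true(all(vapply(b, function(x)
    x$donor_parent %in% x$geno$samples, TRUE)))
  # a family dropping below the progeny threshold is flagged, not dropped
  meta9 <- sim$metadata[!(sim$metadata$sample %in%
                            paste0("FAM01_L", sprintf("%03d", 10:12))), ]
  g9 <- geno_subset(sim$geno, samples = meta9$sample[!duplicated(meta9$sample)])
  b9 <- split_by_family(g9, meta9, min_progeny = 10)
  expect_true(b9$FAM01$excluded)
  expect_false(b9$FAM02$excluded)
  # orphan sample errors
  expect_error(split_by_family(sim$geno, sim$metadata[-1, ]), "metadata")
})

test_that("major/minor recoding flips only majority-alt sites", {
  gt <- rbind(c(2L, 2L, 1L), c(0L, 0L, 1L))
  g <- make_geno(gt)
  r <- recode_major_minor(g)
  expect_equal(unname(r$gt[1, ]), c(0L, 0L, 1L))  # flipped
  expect_equal(unname(r$gt[2, ]), c(0L, 0L, 1L))  # untouched
  expect_equal(r$variants$ref[1], "T")            # alleles swapped with it
})
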