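#' Genotype matrix container
#'
#' Sites-by-samples dosage matrix with an aligned variant table. Dosage codes
#' are integers 0/1/2 (`NA` = missing): by default the alt-allele count; after
#' [recode_major_minor()] 0 is the homozygous major allele, 1 heterozygous and
#' 2 homozygous minor. Variant positions are stored 0-based half-open; VCF
#' I/O converts at the boundary.
#'
#' @param gt integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param variants `data.frame` with columns `chrom`, `pos` (0-based), `id`,
#'   `ref`, `alt`; one row per matrix row, sorted by (chrom, pos), biallelic.
#' @param samples character vector of sample ids (one per matrix column).
#' @return An object of class `geno`.
#' @export
geno_matrix <- function(gt, variants, samples = colnames(gt)) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  stopifnot(nrow(gt) == nrow(variants), ncol(gt) == length(samples),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  bad <- !is.na(gt) & !(gt %in% 0:2)
  if (any(bad)) stop("dosage codes must be 0, 1, 2 or NA")
  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, "_", variants$pos)
  if (anyDuplicated(paste(variants$chrom, variants$pos)))
    stop("duplicate (chrom, pos) in variant table")
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_along(ord))) {
    variants <- variants[ord, ]; gt <- gt[ord, , drop = FALSE]
  }
  dimnames(gt) <- list(NULL, samples)
  rownames(variants) <- NULL
  structure(list(gt = gt, variants = variants, samples = samples),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$gt), " sites x ", length(x$samples), " samples; ",
      length(unique(x$variants$chrom)), " chromosome(s); ",
      sprintf("%.1f%%", 100 * mean(is.na(x$gt))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$gt)

#' Subset a genotype matrix
#' @param g a `geno` object.
#' @param sites logical/integer index over sites.
#' @param samples logical/integer/character index over samples.
#' @return A `geno` object.
#' @export
geno_subset <- function(g, sites = NULL, samples = NULL) {
  gt <- g$gt; v <- g$variants
  if (!is.null(sites)) { gt <- gt[sites, , drop = FALSE]; v <- v[sites, , drop = FALSE] }
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  geno_matrix(gt, v, colnames(gt))
}

## ---- VCF I/O ---------------------------------------------------------------

gt_codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) via \pkg{vcfR}, keeps biallelic SNP records only
#' (multiallelic sites are skipped with a warning count) and converts GT
#' calls to alt-allele dosages. Positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF file path.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi))
    warning(sum(multi), " non-biallelic record(s) skipped")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  gt <- matrix(unname(gt_codes[gt_raw]), nrow = nrow(gt_raw),
               dimnames = dimnames(gt_raw))
  variants <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS) - 1,
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  geno_matrix(gt, variants, colnames(gt))
}

#' Write a genotype matrix as a GT-only VCF v4.2
#'
#' Emits plain-text VCF with 1-based positions and a single GT FORMAT field;
#' a write/read round trip reproduces dosages and positions exactly.
#'
#' @param g a `geno` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno"))
  v <- g$variants
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$gt + 1L], nrow = nrow(g$gt))
  gt_str[is.na(g$gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=wildintro",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples), collapse = "\t"))
  body <- paste(v$chrom, format(v$pos + 1, scientific = FALSE, trim = TRUE),
                v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

## ---- filtering and recoding ------------------------------------------------

site_allele_stats <- function(g, samples = g$samples) {
  gt <- g$gt[, samples, drop = FALSE]
  n_obs <- rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  minor <- pmin(alt, 2 * n_obs - alt)
  list(n_obs = n_obs, alt_count = alt, minor_count = minor,
       maf = ifelse(n_obs > 0, minor / (2 * n_obs), NA),
       miss_frac = (ncol(gt) - n_obs) / ncol(gt))
}

#' Filter variants on minor allele frequency and missingness
#'
#' Retains sites with MAF >= `maf_min` and missing fraction <= `max_missing`
#' (both boundaries keep, reading "less/greater than ... filtered out"
#' literally). MAF is computed from allele counts over non-missing genotypes;
#' any non-0/1/2 entry counts as missing. The field presets are reference
#' panel 0.02/0.50, population first pass 0.05/0.30 and D-genome second pass
#' MAF 0.01 only.
#'
#' @param g a `geno` object.
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param max_missing maximum missing fraction in `[0, 1]`.
#' @return Filtered `geno` object (warns if no site survives).
#' @export
filter_variants <- function(g, maf_min = 0.05, max_missing = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  st <- site_allele_stats(g)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$miss_frac <= max_missing
  if (!any(keep)) warning("no sites pass the MAF/missingness filter")
  geno_subset(g, sites = keep)
}

#' Recode dosages to major/minor polarity
#'
#' Flips sites where the alt allele is the major allele so that code 0 is
#' the homozygous major allele, 1 heterozygous and 2 homozygous minor (ref
#' and alt columns are swapped accordingly).
#'
#' @param g a `geno` object.
#' @return Recoded `geno` object.
#' @export
recode_major_minor <- function(g) {
  st <- site_allele_stats(g)
  flip <- !is.na(st$maf) & st$alt_count > st$n_obs  # alt freq > 0.5
  gt <- g$gt
  gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
  v <- g$variants
  tmp <- v$ref[flip]; v$ref[flip] <- v$alt[flip]; v$alt[flip] <- tmp
  geno_matrix(gt, v, g$samples)
}

#' Remove sites monomorphic within a sample subset
#'
#' Drops sites showing a single distinct non-missing dosage code (or none)
#' within the subset, the within-family preparation step for breakpoint
#' scanning.
#'
#' @param g a `geno` object.
#' @param samples sample ids defining the subset (default all).
#' @return `geno` with polymorphic sites only (warns if empty).
#' @export
remove_monomorphic <- function(g, samples = g$samples) {
  stopifnot(length(samples) > 0)
  gt <- g$gt[, samples, drop = FALSE]
  n_distinct <- apply(gt, 1, function(x) length(unique(x[!is.na(x)])))
  keep <- n_distinct >= 2
  if (!any(keep)) warning("all sites are monomorphic in the subset")
  geno_subset(g, sites = keep)
}

#' Harmonize site sets between a target matrix and a reference panel
#'
#' Intersects the two matrices on (chrom, pos), keeping sites with identical
#' ref/alt alleles, or with ref and alt swapped, in which case the panel's
#' dosages are flipped (0 <-> 2) to the target's polarity. Sites present in
#' only one matrix, or with incompatible alleles, are dropped.
#'
#' @param target,panel `geno` objects.
#' @return `list(target = , panel = , report = )` where `report` counts
#'   `kept`, `swapped` and `dropped` sites. Errors on empty intersection.
#' @export
harmonize_positions <- function(target, panel) {
  kt <- paste(target$variants$chrom, target$variants$pos)
  kp <- paste(panel$variants$chrom, panel$variants$pos)
  it <- match(kp, kt)
  common <- which(!is.na(it))
  ti <- it[common]
  same <- target$variants$ref[ti] == panel$variants$ref[common] &
    target$variants$alt[ti] == panel$variants$alt[common]
  swap <- target$variants$ref[ti] == panel$variants$alt[common] &
    target$variants$alt[ti] == panel$variants$ref[common]
  keep <- same | swap
  if (!any(keep)) stop("no shared (chrom, pos) sites with compatible alleles")
  report <- c(kept = sum(keep), swapped = sum(swap),
              dropped = length(kt) + length(kp) - 2 * sum(keep))
  pi_keep <- common[keep]
  ti_keep <- ti[keep]
  pg <- panel$gt[pi_keep, , drop = FALSE]
  flip_rows <- which(swap[keep])
  pg[flip_rows, ] <- 2L - pg[flip_rows, , drop = FALSE]
  pv <- panel$variants[pi_keep, , drop = FALSE]
  pv$ref <- target$variants$ref[ti_keep]
  pv$alt <- target$variants$alt[ti_keep]
  list(target = geno_subset(target, sites = ti_keep),
       panel = geno_matrix(pg, pv, panel$samples),
       report = report)
}

## ---- metadata and family splitting ----------------------------------------

#' Read / write sample metadata TSV (sample, role, family)
#' @param path file path.
#' @return `read_metadata` returns the metadata `data.frame`.
#' @rdname metadata_io
#' @export
read_metadata <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "role", "family") %in% names(m)))
  m
}

#' @param metadata metadata `data.frame`.
#' @rdname metadata_io
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split a genotype matrix into family bundles
#'
#' Each bundle holds the family's progeny plus its parents (parents may be
#' shared across families). Families with fewer than `min_progeny` progeny
#' are flagged excluded but still returned.
#'
#' @param g a `geno` object.
#' @param metadata `data.frame` with columns `sample`, `role`
#'   (`progeny` / `recipient_parent` / `donor_parent` / `reference_panel`),
#'   `family`.
#' @param min_progeny minimum progeny count for a family to be retained
#'   (default 10).
#' @return Named list of bundles: each `list(geno, family, progeny,
#'   recipient_parents, donor_parent, excluded)`.
#' @export
split_by_family <- function(g, metadata, min_progeny = 10) {
  prog <- metadata[metadata$role == "progeny", , drop = FALSE]
  orphan <- setdiff(g$samples, metadata$sample)
  orphan <- orphan[orphan %in% g$samples &
                     !(orphan %in% metadata$sample)]
  missing_meta <- setdiff(g$samples, metadata$sample)
  if (length(missing_meta))
    stop("samples without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  if (any(is.na(prog$family) | prog$family == ""))
    stop("progeny without family assignment")
  fams <- unique(prog$family)
  out <- list()
  for (f in fams) {
    fm <- metadata[metadata$family == f, , drop = FALSE]
    p <- fm$sample[fm$role == "progeny"]
    rp <- unique(fm$sample[fm$role == "recipient_parent"])
    dp <- unique(fm$sample[fm$role == "donor_parent"])
    if (length(rp) < 1 || length(dp) != 1)
      stop("family ", f, " must have >= 1 recipient parent and exactly 1 ",
           "donor parent")
    ids <- intersect(c(p, rp, dp), g$samples)
    out[[f]] <- list(geno = geno_subset(g, samples = ids), family = f,
                     progeny = intersect(p, g$samples),
                     recipient_parents = rp, donor_parent = dp,
                     excluded = length(intersect(p, g$samples)) < min_progeny)
  }
  out
}
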