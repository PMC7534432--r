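#' Chromosome specification table
#'
#' A chromosome spec is a plain `data.frame` with one row per chromosome and
#' columns `name`, `length_bp` and `centromere_bp`. All package coordinates
#' are 0-based, half-open; the centromere is a point position strictly inside
#' the chromosome.
#'
#' @param name character vector of unique chromosome labels.
#' @param length_bp numeric vector of physical lengths in bp.
#' @param centromere_bp numeric vector of centromere midpoints in bp.
#' @return A validated `data.frame` with columns `name`, `length_bp`,
#'   `centromere_bp`.
#' @export
chrom_specs <- function(name, length_bp, centromere_bp) {
  specs <- data.frame(name = as.character(name),
                      length_bp = as.numeric(length_bp),
                      centromere_bp = as.numeric(centromere_bp),
                      stringsAsFactors = FALSE)
  validate_chrom_specs(specs)
  specs
}

validate_chrom_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "length_bp", "centromere_bp") %in% names(specs)))
  if (anyDuplicated(specs$name))
    stop("chromosome names must be unique")
  if (any(specs$length_bp <= 0))
    stop("chromosome lengths must be positive")
  bad <- specs$centromere_bp <= 0 | specs$centromere_bp >= specs$length_bp
  if (any(bad))
    stop("centromere_bp must lie strictly inside (0, length_bp) for: ",
         paste(specs$name[bad], collapse = ", "))
  invisible(specs)
}

#' Default desk-scale genome
#'
#' Seven D-genome-like chromosomes of 60 Mbp each with the centromere at 40%
#' of the chromosome length. This compressed genome keeps whole-pipeline runs
#' fast while preserving the arm asymmetry and pericentromeric geometry of
#' wheat chromosomes; full-scale lengths can be supplied to [chrom_specs()].
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp chromosome length in bp.
#' @param centromere_frac centromere position as a fraction of length.
#' @return A chromosome spec `data.frame`.
#' @export
default_chrom_specs <- function(n_chrom = 7, length_bp = 60e6,
                                centromere_frac = 0.4) {
  chrom_specs(name = paste0("chr", seq_len(n_chrom), "D"),
              length_bp = rep(length_bp, n_chrom),
              centromere_bp = rep(length_bp * centromere_frac, n_chrom))
}

#' Read / write chromosome specs as 3-column TSV
#' @param path file path.
#' @return `read_chrom_specs` returns the spec `data.frame`;
#'   `write_chrom_specs` returns `path` invisibly.
#' @rdname chrom_specs_io
#' @export
read_chrom_specs <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  chrom_specs(x$name, x$length_bp, x$centromere_bp)
}

#' @param specs chromosome spec `data.frame`.
#' @rdname chrom_specs_io
#' @export
write_chrom_specs <- function(specs, path) {
  validate_chrom_specs(specs)
  utils::write.table(specs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Piecewise recombination map
#'
#' A recombination map is a `data.frame` with columns `chrom`, `start`, `end`
#' (bp, 0-based half-open) and `rate` (cM/Mbp). Within each chromosome the
#' intervals must tile `[0, length_bp)` without gaps or overlaps and rates
#' must be non-negative with positive total map length.
#'
#' @param map candidate map `data.frame`.
#' @param specs chromosome spec `data.frame` the map must cover.
#' @return The validated map, invisibly.
#' @export
validate_recomb_map <- function(map, specs) {
  stopifnot(all(c("chrom", "start", "end", "rate") %in% names(map)))
  if (any(map$rate < 0)) stop("recombination rates must be >= 0")
  for (i in seq_len(nrow(specs))) {
    m <- map[map$chrom == specs$name[i], , drop = FALSE]
    if (nrow(m) == 0) stop("map missing chromosome ", specs$name[i])
    m <- m[order(m$start), ]
    if (m$start[1] != 0 || abs(m$end[nrow(m)] - specs$length_bp[i]) > 0.5 ||
        any(m$start[-1] != m$end[-nrow(m)]))
      stop("map intervals must tile [0, length_bp) on ", specs$name[i])
  }
  tot <- map_morgans(map)
  if (!all(is.finite(tot)) || sum(tot) <= 0)
    stop("total map length must be finite and > 0")
  invisible(map)
}

#' Total genetic map length per chromosome
#' @param map recombination map `data.frame` (`rate` in cM/Mbp).
#' @return Named numeric vector of map lengths in Morgans.
#' @export
map_morgans <- function(map) {
  m <- (map$end - map$start) / 1e6 * map$rate / 100
  out <- tapply(m, map$chrom, sum)
  stats::setNames(as.vector(out), names(out))
}

#' Default pericentromere-suppressed recombination map
#'
#' Large cereal chromosomes show a steep recombination gradient along the
#' centromere--telomere axis: crossovers concentrate in the distal chromosome
#' ends while the pericentromeric two-thirds of each arm is strongly
#' suppressed. The default map places `distal_share` (90%) of each arm's map
#' length in the terminal third of the arm, with arm map length proportional
#' to arm physical length and `morgans_per_chrom` total per chromosome.
#'
#' @param specs chromosome spec `data.frame`.
#' @param morgans_per_chrom total map length per chromosome (Morgans).
#' @param distal_share fraction of each arm's map length carried by the
#'   terminal third of the arm.
#' @return A recombination map `data.frame` (chrom, start, end, rate).
#' @export
default_recomb_map <- function(specs, morgans_per_chrom = 1.5,
                               distal_share = 0.9) {
  validate_chrom_specs(specs)
  stopifnot(distal_share >= 0, distal_share <= 1)
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    L <- specs$length_bp[i]
    cen <- specs$centromere_bp[i]
    arms <- list(short = c(0, cen), long = c(cen, L))
    rows <- list()
    for (a in arms) {
      alen <- a[2] - a[1]
      aM <- morgans_per_chrom * alen / L
      # terminal third of the arm is distal; inner two-thirds pericentromeric
      if (identical(a, arms$short)) {
        distal <- c(a[1], a[1] + alen / 3); peri <- c(a[1] + alen / 3, a[2])
      } else {
        peri <- c(a[1], a[2] - alen / 3); distal <- c(a[2] - alen / 3, a[2])
      }
      r_d <- aM * distal_share / ((distal[2] - distal[1]) / 1e6) * 100
      r_p <- aM * (1 - distal_share) / ((peri[2] - peri[1]) / 1e6) * 100
      rows <- c(rows, list(
        data.frame(chrom = specs$name[i], start = distal[1], end = distal[2],
                   rate = r_d),
        data.frame(chrom = specs$name[i], start = peri[1], end = peri[2],
                   rate = r_p)))
    }
    o <- do.call(rbind, rows)
    out[[i]] <- o[order(o$start), ]
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  validate_recomb_map(map, specs)
  map
}

#' Partition chromosomes into pericentromeric and distal regions
#'
#' Each arm is split so that the two-thirds adjacent to the centromere is
#' pericentromeric and the terminal third distal: for centromere `c` and
#' length `L`, the short arm is distal on `[0, c/3)` and pericentromeric on
#' `[c/3, c)`; the long arm pericentromeric on `[c, c + 2(L-c)/3)` and distal
#' on `[c + 2(L-c)/3, L)`.
#'
#' @param specs chromosome spec `data.frame`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `region`
#'   (`"distal"` or `"pericentromeric"`); intervals tile each chromosome.
#' @export
partition_regions <- function(specs) {
  validate_chrom_specs(specs)
  out <- lapply(seq_len(nrow(specs)), function(i) {
    L <- specs$length_bp[i]; cen <- specs$centromere_bp[i]
    data.frame(
      chrom = specs$name[i],
      start = c(0, cen / 3, cen + 2 * (L - cen) / 3),
      end   = c(cen / 3, cen + 2 * (L - cen) / 3, L),
      region = c("distal", "pericentromeric", "distal"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Label positions by chromosome region
#'
#' @param chrom,pos vectors of chromosome names and bp positions.
#' @param specs chromosome spec `data.frame`.
#' @return Character vector `"pericentromeric"`/`"distal"` (NA outside the
#'   genome).
#' @export
region_of <- function(chrom, pos, specs) {
  part <- partition_regions(specs)
  out <- rep(NA_character_, length(pos))
  for (cn in unique(chrom)) {
    p <- part[part$chrom == cn, ]
    sel <- which(chrom == cn)
    idx <- findInterval(pos[sel], p$start)
    ok <- idx >= 1 & idx <= nrow(p) & pos[sel] < p$end[pmax(idx, 1)]
    out[sel[ok]] <- p$region[idx[ok]]
  }
  out
}
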