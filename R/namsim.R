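#' Simulate a genetic map
#'
#' Builds a SNP map with chromosomes of equal genetic length and physical
#' positions drawn uniformly along each chromosome. The genetic position is a
#' linear function of the physical position, so sorting by base pairs sorts by
#' centimorgans as well.
#'
#' @param n_snps Total number of SNPs across the genome.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_cM Genetic length of each chromosome in centimorgans.
#' @param mb_per_cM Physical-to-genetic scale (megabases per centimorgan).
#'   The default of 4 Mb/cM gives barley-like 600 Mb chromosomes at 150 cM.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos_bp`, `pos_cM`,
#'   sorted by chromosome and physical position.
#' @export
#' @examples
#' sim_genetic_map(n_snps = 70, n_chrom = 7, seed = 1)
sim_genetic_map <- function(n_snps = 2000, n_chrom = 7, chrom_length_cM = 150,
                            mb_per_cM = 4, seed = NULL) {
  if (n_snps < 1 || n_chrom < 1) abort("need at least one SNP and one chromosome")
  stopifnot_scalar_seed(seed)
  per_chrom <- rep(n_snps %/% n_chrom, n_chrom) +
    as.integer(seq_len(n_chrom) <= n_snps %% n_chrom)
  len_bp <- chrom_length_cM * mb_per_cM * 1e6
  purrr::map_dfr(seq_len(n_chrom), function(chr) {
    bp <- sort(sample.int(len_bp, per_chrom[chr]))
    tibble::tibble(
      snp_id = sprintf("S%d_%04d", chr, seq_along(bp)),
      chrom = chr,
      pos_bp = bp,
      pos_cM = bp / (mb_per_cM * 1e6)
    )
  })
}

#' Simulate NAM founders
#'
#' Creates the founder haplotypes for a NAM population: a recurrent (elite)
#' parent carrying the reference allele at every SNP and one wild donor per
#' family. Each donor carries the alternative allele at an independent random
#' subset of SNPs.
#'
#' @param n_families Number of donor families (25 for a HEB-25-like design).
#' @param map Genetic map tibble from [sim_genetic_map()].
#' @param donor_polymorphism_rate Probability that a donor carries the
#'   alternative allele at a SNP; in (0, 1].
#' @param seed Optional integer seed.
#'
#' @return An object of class `nam_founders`: a list with `recurrent`
#'   (integer vector of 0s), `donors` (families x SNPs 0/1 matrix) and
#'   `donor_ids`.
#' @export
simulate_founders <- function(n_families, map, donor_polymorphism_rate = 0.5,
                              seed = NULL) {
  if (length(n_families) != 1L || n_families < 1) {
    abort("`n_families` must be a positive integer")
  }
  if (is.null(map) || nrow(map) == 0L) abort("`map` is empty")
  if (donor_polymorphism_rate <= 0 || donor_polymorphism_rate > 1) {
    abort("`donor_polymorphism_rate` must be in (0, 1]")
  }
  stopifnot_scalar_seed(seed)
  n_snps <- nrow(map)
  donors <- matrix(
    as.integer(runif(n_families * n_snps) < donor_polymorphism_rate),
    nrow = n_families, ncol = n_snps
  )
  colnames(donors) <- map$snp_id
  ids <- sprintf("F%02d", seq_len(n_families))
  rownames(donors) <- ids
  structure(
    list(
      recurrent = setNames(integer(n_snps), map$snp_id),
      donors = donors,
      donor_ids = ids,
      map = map
    ),
    class = "nam_founders"
  )
}

#' @export
print.nam_founders <- function(x, ...) {
  cat(sprintf(
    "<nam_founders> %d donor(s), %d SNPs, mean donor polymorphism %.3f\n",
    length(x$donor_ids), ncol(x$donors), mean(x$donors)
  ))
  invisible(x)
}

# Split a map into per-chromosome pieces with the quantities the meiosis
# engine needs: column indices, sorted cM positions, and the cM range.
split_map <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  lapply(idx, function(i) {
    cm <- map$pos_cM[i]
    list(cols = i, cM = cm, lo = min(cm), hi = max(cm))
  })
}

# Simulate one gamete per line from diploid parents given as two haplotype
# matrices (lines x SNPs). Crossovers follow the Haldane model: per
# chromosome the crossover count is Poisson with mean equal to the map
# length in Morgans, positions uniform on the cM scale, no interference.
sim_gametes <- function(H1, H2, map_split) {
  n <- nrow(H1)
  G <- H1
  for (chr in map_split) {
    cols <- chr$cols
    L <- chr$hi - chr$lo
    n_xo <- rpois(n, L / 100)
    start <- as.integer(runif(n) < 0.5)
    ph_t <- matrix(0L, length(cols), n)    # SNP-major for cheap column writes
    for (i in which(n_xo > 0L)) {
      xo <- sort(runif(n_xo[i], chr$lo, chr$hi))
      ph_t[, i] <- findInterval(chr$cM, xo) %% 2L
    }
    phase <- (t(ph_t) + start) %% 2L
    g <- H1[, cols, drop = FALSE]
    h2 <- H2[, cols, drop = FALSE]
    take2 <- phase == 1L
    g[take2] <- h2[take2]
    G[, cols] <- g
  }
  G
}

#' Simulate a BC1S3 NAM family
#'
#' Crosses a wild donor to the recurrent parent (F1), backcrosses the F1 to
#' the recurrent parent once (BC1), then advances each line by three
#' generations of selfing with single-seed descent (BC1S3). Meioses are
#' independent across lines and generations; recombination uses the Haldane
#' (no-interference) model on the centimorgan map. At a locus polymorphic
#' between the parents the expected residual heterozygosity is
#' (1/2)(1/2)^3 = 1/16 = 6.25% and the expected donor-genome proportion 25%.
#'
#' @param donor Donor haplotype: 0/1 integer vector over the map's SNPs.
#' @param recurrent Recurrent-parent haplotype (normally all 0).
#' @param n_lines Number of BC1S3 lines to produce.
#' @param map Genetic map tibble.
#' @param family_id Label stored with each line.
#' @param seed Optional integer seed.
#'
#' @return An object of class `nam_family`: list with haplotype matrices
#'   `H1`, `H2` (lines x SNPs, donor-allele indicators), `line_id`,
#'   `family_id`, `generation = "BC1S3"` and the map. Use [family_calls()]
#'   for the 0/1/2 genotype table.
#' @export
simulate_bc1s3_family <- function(donor, recurrent, n_lines, map,
                                  family_id = "F01", seed = NULL) {
  if (n_lines < 1) abort("`n_lines` must be >= 1")
  if (length(donor) != nrow(map) || length(recurrent) != nrow(map)) {
    abort("donor/recurrent haplotypes must be defined on the same map")
  }
  stopifnot_scalar_seed(seed)
  ms <- split_map(map)
  one <- function(v) matrix(v, nrow = n_lines, ncol = length(v), byrow = TRUE)
  # F1 is donor/recurrent at every SNP; a BC1 line is one F1 gamete plus a
  # recurrent gamete (the recurrent parent is fully homozygous).
  H1 <- sim_gametes(one(donor), one(recurrent), ms)
  H2 <- one(recurrent)
  for (gen in 1:3) {            # S1..S3 by single-seed descent
    A <- sim_gametes(H1, H2, ms)
    B <- sim_gametes(H1, H2, ms)
    H1 <- A
    H2 <- B
  }
  colnames(H1) <- colnames(H2) <- map$snp_id
  structure(
    list(
      H1 = H1, H2 = H2,
      line_id = sprintf("%s_%04d", family_id, seq_len(n_lines)),
      family_id = family_id, generation = "BC1S3", map = map
    ),
    class = "nam_family"
  )
}

#' Genotype calls of a simulated family
#'
#' Collapses the two haplotypes of each line into donor-allele counts:
#' 0 = homozygous recurrent, 1 = heterozygous, 2 = homozygous donor.
#'
#' @param fam A `nam_family` from [simulate_bc1s3_family()].
#' @return Tibble with `line_id`, `family_id` and one integer column per SNP.
#' @export
family_calls <- function(fam) {
  m <- fam$H1 + fam$H2
  dplyr::bind_cols(
    tibble::tibble(line_id = fam$line_id, family_id = fam$family_id),
    tibble::as_tibble(m)
  )
}

#' Simulate a complete NAM population
#'
#' Generates founders and one BC1S3 family per donor, all on a shared map.
#'
#' @param n_families Number of families.
#' @param lines_per_family Lines per family (HEB-25 averages ~52).
#' @param map Genetic map; built with [sim_genetic_map()] when NULL.
#' @param donor_polymorphism_rate See [simulate_founders()].
#' @param seed Integer seed controlling founders and all meioses.
#' @inheritParams sim_genetic_map
#'
#' @return An object of class `nam_pop`: list with `geno` (tibble of 0/1/2
#'   calls with `line_id`, `family_id`), `map`, and `founders`.
#' @export
#' @examples
#' pop <- simulate_nam(n_families = 3, lines_per_family = 10,
#'                     n_snps = 100, seed = 1)
#' dim(pop$geno)
simulate_nam <- function(n_families = 25, lines_per_family = 52, map = NULL,
                         n_snps = 2000, donor_polymorphism_rate = 0.5,
                         seed = NULL) {
  stopifnot_scalar_seed(seed)
  if (is.null(map)) map <- sim_genetic_map(n_snps = n_snps)
  founders <- simulate_founders(n_families, map, donor_polymorphism_rate)
  geno <- purrr::map_dfr(seq_len(n_families), function(f) {
    fam <- simulate_bc1s3_family(
      founders$donors[f, ], founders$recurrent,
      n_lines = lines_per_family, map = map,
      family_id = founders$donor_ids[f]
    )
    family_calls(fam)
  })
  structure(list(geno = geno, map = map, founders = founders),
            class = "nam_pop")
}

#' @export
print.nam_pop <- function(x, ...) {
  cat(sprintf(
    "<nam_pop> %d lines in %d families, %d SNPs on %d chromosomes\n",
    nrow(x$geno), dplyr::n_distinct(x$geno$family_id),
    nrow(x$map), dplyr::n_distinct(x$map$chrom)
  ))
  invisible(x)
}
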