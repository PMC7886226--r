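#' Marker quality control
#'
#' Screens SNPs with the three chip-QC rules used for BC1S3 NAM genotypes:
#' a marker passes when it is polymorphic in at least one family, its
#' failure (missing-call) rate is below `fail_max`, and its heterozygous-call
#' rate is below `het_max` (6.25% heterozygosity is the BC1S3 expectancy, so
#' twice that flags unreliable clustering). Thresholds are strict
#' inequalities: a marker at exactly 10% missing fails.
#'
#' @param calls Genotype tibble: `line_id`, `family_id`, SNP columns coded
#'   0 = homozygous recurrent, 1 = heterozygous, 2 = homozygous donor,
#'   `NA` = missing.
#' @param fail_max Maximum tolerated missing-call fraction (exclusive),
#'   computed over all lines.
#' @param het_max Maximum tolerated heterozygous fraction (exclusive),
#'   computed over non-missing calls.
#'
#' @return A tibble (class `nam_qc`) with one row per SNP:
#'   `snp_id`, `polymorphic_in_any_family`, `failure_rate`, `het_rate`,
#'   `pass`.
#' @export
#' @examples
#' pop <- simulate_nam(n_families = 2, lines_per_family = 8,
#'                     n_snps = 50, seed = 1)
#' marker_qc(pop$geno)
marker_qc <- function(calls, fail_max = 0.10, het_max = 0.125) {
  m <- geno_matrix(calls)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty call matrix")
  if (anyNA(calls$family_id)) abort("every line needs a family label")
  n <- nrow(m)
  called <- colSums(!is.na(m))
  failure_rate <- (n - called) / n
  het_rate <- ifelse(called > 0, colSums(m == 1, na.rm = TRUE) / called, 0)
  poly <- rep(FALSE, ncol(m))
  for (f in unique(calls$family_id)) {
    fm <- m[calls$family_id == f, , drop = FALSE]
    n_states <- (colSums(fm == 0, na.rm = TRUE) > 0) +
      (colSums(fm == 1, na.rm = TRUE) > 0) +
      (colSums(fm == 2, na.rm = TRUE) > 0)
    poly <- poly | (n_states >= 2)
  }
  out <- tibble::tibble(
    snp_id = colnames(m),
    polymorphic_in_any_family = unname(poly),
    failure_rate = unname(failure_rate),
    het_rate = unname(het_rate),
    pass = unname(poly & failure_rate < fail_max & het_rate < het_max)
  )
  class(out) <- c("nam_qc", class(out))
  out
}

#' Quantitative IBS genotype coding
#'
#' Codes passing SNPs as identity-by-state scores — homozygous recurrent
#' (elite) allele 0, heterozygous 1, homozygous donor (wild) allele 2 —
#' then applies the family-wise recode: in any family where a SNP is
#' monomorphic (fewer than two distinct non-missing states, including the
#' all-missing case), all of that family's lines are set to 0 at that SNP,
#' because within that family the marker carries no contrast against the
#' recurrent allele.
#'
#' @param calls Genotype tibble as in [marker_qc()].
#' @param qc QC report from [marker_qc()]; only SNPs with `pass = TRUE` are
#'   retained. When NULL, QC is run with default thresholds.
#'
#' @return IBS tibble (`line_id`, `family_id`, one numeric column per
#'   passing SNP; `NA` where calls were missing in polymorphic families).
#'   Attribute `recoded` lists the (snp_id, family_id) pairs set to 0.
#' @export
code_ibs <- function(calls, qc = NULL) {
  if (is.null(qc)) qc <- marker_qc(calls)
  keep <- qc$snp_id[qc$pass]
  missing_snps <- setdiff(setdiff(names(calls), ID_COLS), qc$snp_id)
  if (length(missing_snps)) {
    abort(paste0("SNP(s) absent from QC report: ",
                 paste(head(missing_snps, 5), collapse = ", ")))
  }
  m <- geno_matrix(calls)[, keep, drop = FALSE]
  storage.mode(m) <- "double"
  fams <- unique(calls$family_id)
  recoded <- list()
  for (f in fams) {
    rows <- calls$family_id == f
    fm <- m[rows, , drop = FALSE]
    n_states <- (colSums(fm == 0, na.rm = TRUE) > 0) +
      (colSums(fm == 1, na.rm = TRUE) > 0) +
      (colSums(fm == 2, na.rm = TRUE) > 0)
    mono <- n_states < 2                # all-missing counts as monomorphic
    if (any(mono)) {
      m[rows, mono] <- 0
      recoded[[f]] <- tibble::tibble(snp_id = keep[mono], family_id = f)
    }
  }
  out <- geno_tibble(calls, m)
  attr(out, "recoded") <- dplyr::bind_rows(recoded)
  class(out) <- c("nam_ibs", class(out))
  out
}

#' Mean imputation (MNI) of missing IBS scores
#'
#' Replaces each missing score by the population-wide mean of the marker's
#' non-missing scores, yielding a complete matrix of values in \[0, 2\].
#'
#' @param ibs IBS tibble from [code_ibs()] (or any `line_id`/`family_id` +
#'   score-column tibble).
#' @param by_family Impute within families instead of population-wide.
#'   Off by default.
#'
#' @return The completed IBS tibble. Attribute `imputed` is a logical
#'   matrix marking imputed cells (used to keep imputed fractional scores
#'   out of the dominance kernel).
#' @export
impute_mni <- function(ibs, by_family = FALSE) {
  m <- geno_matrix(ibs)
  storage.mode(m) <- "double"
  mask <- is.na(m)
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing)) {
    abort(paste0("SNP(s) entirely missing, cannot impute: ",
                 paste(head(colnames(m)[all_missing], 5), collapse = ", ")))
  }
  fill_block <- function(block) {
    mu <- colMeans(block, na.rm = TRUE)
    idx <- which(is.na(block), arr.ind = TRUE)
    if (nrow(idx)) block[idx] <- mu[idx[, 2]]
    block
  }
  if (by_family) {
    for (f in unique(ibs$family_id)) {
      rows <- ibs$family_id == f
      m[rows, ] <- fill_block(m[rows, , drop = FALSE])
    }
    # fall back to population means where a family had no observed call
    if (anyNA(m)) m <- fill_block(m)
  } else {
    m <- fill_block(m)
  }
  out <- geno_tibble(ibs, m)
  attr(out, "recoded") <- attr(ibs, "recoded")
  attr(out, "imputed") <- mask
  class(out) <- c("nam_ibs", class(out))
  out
}
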