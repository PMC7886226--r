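#' Read and write genotype, map and phenotype tables
#'
#' Plain tab-separated interchange formats: genotypes as lines x SNPs with
#' values 0/1/2 (or IBS reals after imputation) and the missing token
#' `NA`; maps as `snp_id`, `chrom`, `pos_bp`, `pos_cM`; phenotypes as
#' `line_id`, `family_id` plus metabolite columns.
#'
#' @param path File path.
#' @param x Table to write.
#' @name nam_io
NULL

#' @rdname nam_io
#' @export
read_geno_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname nam_io
#' @export
write_geno_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname nam_io
#' @export
read_map_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), chrom = readr::col_integer(),
    pos_bp = readr::col_double(), pos_cM = readr::col_double()
  ), progress = FALSE)
}

#' @rdname nam_io
#' @export
write_map_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read raw chip calls coded A/H/B
#'
#' `A` = homozygous recurrent (elite) allele, `H` = heterozygous, `B` =
#' homozygous donor allele, `NA` = missing; recoded to the 0/1/2 integers
#' used throughout.
#'
#' @param path TSV with `line_id`, `family_id` and one A/H/B column per
#'   SNP.
#' @return Genotype tibble with integer calls.
#' @export
read_calls_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), family_id = readr::col_character(),
    .default = readr::col_character()
  ), na = c("NA", ""), progress = FALSE)
  code <- c(A = 0L, H = 1L, B = 2L)
  for (nm in setdiff(names(raw), ID_COLS)) {
    bad <- !is.na(raw[[nm]]) & !raw[[nm]] %in% names(code)
    if (any(bad)) abort(paste0("unknown call code in column ", nm))
    raw[[nm]] <- unname(code[raw[[nm]]])
  }
  raw
}

#' Import a PLINK-style additive dosage (.raw) file
#'
#' Expects the usual header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' per-SNP allele dosages (0/1/2, NA allowed). `FID` becomes the family
#' label and `IID` the line id; SNP column suffixes such as `_A` are
#' stripped.
#'
#' @param path Path to the .raw file (whitespace separated).
#' @return Genotype tibble (`line_id`, `family_id`, SNP columns).
#' @export
read_plink_raw <- function(path) {
  raw <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  need <- c("FID", "IID")
  if (!all(need %in% names(raw))) abort(".raw file needs FID and IID columns")
  snps <- setdiff(names(raw), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  out <- tibble::tibble(line_id = as.character(raw$IID),
                        family_id = as.character(raw$FID))
  for (nm in snps) {
    out[[sub("_[ACGT]$", "", nm)]] <- as.integer(raw[[nm]])
  }
  out
}
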