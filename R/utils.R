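#' @importFrom rlang .data abort warn
#' @importFrom stats pf pt rnorm runif rpois var sd cor qf quantile setNames
#' @importFrom utils head tail
NULL

# Columns of a line-by-SNP tibble that are not marker scores.
ID_COLS <- c("line_id", "family_id")

# Extract the SNP score columns of a genotype/IBS tibble as a matrix,
# preserving column order (assumed to follow the genetic map).
geno_matrix <- function(tbl) {
  snp_cols <- setdiff(names(tbl), ID_COLS)
  m <- as.matrix(tbl[snp_cols])
  rownames(m) <- tbl$line_id
  m
}

# Rebuild the tibble around a (possibly modified) score matrix.
geno_tibble <- function(tbl, m) {
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tbl[intersect(ID_COLS, names(tbl))], out)
}

stopifnot_scalar_seed <- function(seed) {
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L || is.na(seed))) {
    abort("`seed` must be NULL or a single number.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
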