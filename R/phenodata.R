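metabolite_cols <- function(table) {
  setdiff(names(table), c(ID_COLS, "date", "sampling_date", "control_id", "rep"))
}

#' Filter metabolites by missingness
#'
#' Drops metabolite columns whose missing-value fraction exceeds
#' `max_missing` (strictly greater, so a column at exactly 10% missing is
#' retained under the default).
#'
#' @param table Metabolite tibble: `line_id`, `family_id`, metabolite
#'   columns.
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#'
#' @return The filtered tibble; attribute `filter_report` holds a tibble of
#'   per-metabolite missing fractions and the keep decision.
#' @export
filter_metabolites <- function(table, max_missing = 0.10) {
  mets <- metabolite_cols(table)
  miss <- vapply(table[mets], function(x) mean(is.na(x)), numeric(1))
  keep <- miss <= max_missing
  if (!any(keep)) warn("all metabolite columns exceeded the missingness cap")
  out <- table[c(intersect(names(table), c(ID_COLS, "date")), mets[keep])]
  attr(out, "filter_report") <- tibble::tibble(
    metabolite = mets, missing_fraction = unname(miss), kept = unname(keep)
  )
  out
}

#' Minimum-value imputation of metabolite data
#'
#' Replaces remaining missing values of each metabolite with the minimum of
#' its observed values, the conventional stand-in for measurements below
#' the limit of quantification.
#'
#' @inheritParams filter_metabolites
#' @return The completed tibble.
#' @export
impute_min <- function(table) {
  for (nm in metabolite_cols(table)) {
    x <- table[[nm]]
    if (all(is.na(x))) {
      abort(paste0("metabolite '", nm, "' has no observed values; ",
                   "filter it out before imputing"))
    }
    x[is.na(x)] <- min(x, na.rm = TRUE)
    table[[nm]] <- x
  }
  table
}

# Profile log-likelihood of the Box-Cox model at a fixed lambda
# (normal likelihood with mu, sigma profiled out; Jacobian term included).
boxcox_loglik <- function(y, lambda) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Box-Cox transformation over a lambda grid
#'
#' Evaluates the Box-Cox profile log-likelihood on a fixed grid of lambda
#' values (default -3 to 3 in steps of 0.25), picks the maximizing lambda
#' (ties broken toward the value closest to 1, i.e. least distortion) and
#' returns the transformed values `(y^lambda - 1) / lambda` (`log(y)` at
#' lambda = 0). Non-positive inputs are shifted by `1 - min(y)` first.
#'
#' @param values Numeric vector, positive after the optional shift.
#' @param grid Candidate lambda values.
#' @param shift Allow automatic shifting of non-positive values.
#'
#' @return Object of class `nam_boxcox`: list with `lambda`, `shift`,
#'   `transformed`, and `profile` (tibble of lambda and log-likelihood).
#' @export
#' @examples
#' bc <- boxcox_transform(exp(rnorm(200)))
#' bc$lambda
boxcox_transform <- function(values, grid = seq(-3, 3, by = 0.25),
                             shift = TRUE) {
  y <- values[!is.na(values)]
  if (length(y) < 10) abort("need at least 10 observed values")
  if (sd(y) == 0) abort("constant input: Box-Cox likelihood is undefined")
  off <- 0
  if (min(y) <= 0) {
    if (!shift) abort("non-positive values and shifting disabled")
    off <- 1 - min(y)
    y <- y + off
  }
  ll <- vapply(grid, function(l) boxcox_loglik(y, l), numeric(1))
  best <- which(ll >= max(ll) - 1e-9 * abs(max(ll)))
  lambda <- grid[best[which.min(abs(grid[best] - 1))]]
  yy <- values + off
  z <- if (abs(lambda) < 1e-12) log(yy) else (yy^lambda - 1) / lambda
  structure(
    list(lambda = lambda, shift = off, transformed = z,
         profile = tibble::tibble(lambda = grid, loglik = ll)),
    class = "nam_boxcox"
  )
}

#' @export
print.nam_boxcox <- function(x, ...) {
  cat(sprintf("<nam_boxcox> lambda = %.2f, shift = %g\n", x$lambda, x$shift))
  invisible(x)
}

#' Box-Cox transform every metabolite of a table
#'
#' @inheritParams filter_metabolites
#' @inheritParams boxcox_transform
#' @return The transformed tibble; attribute `transform_report` records per
#'   metabolite the chosen lambda and shift.
#' @export
transform_metabolites <- function(table, grid = seq(-3, 3, by = 0.25)) {
  mets <- metabolite_cols(table)
  rep_rows <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    bc <- boxcox_transform(table[[mets[i]]], grid = grid)
    table[[mets[i]]] <- bc$transformed
    rep_rows[[i]] <- tibble::tibble(metabolite = mets[i],
                                    lambda = bc$lambda, shift = bc$shift)
  }
  attr(table, "transform_report") <- dplyr::bind_rows(rep_rows)
  table
}

#' Descriptive statistics per metabolite
#'
#' Mean, standard deviation, range, skewness (m3 / s^3) and excess
#' kurtosis (m4 / s^4 - 3) with population moments; constant columns get
#' skewness and kurtosis 0 with `degenerate = TRUE`.
#'
#' @inheritParams filter_metabolites
#' @return Tibble with one row per metabolite.
#' @export
descriptive_stats <- function(table) {
  purrr::map_dfr(metabolite_cols(table), function(nm) {
    x <- table[[nm]][!is.na(table[[nm]])]
    n <- length(x)
    m <- mean(x)
    m2 <- mean((x - m)^2)
    degenerate <- m2 == 0
    tibble::tibble(
      metabolite = nm, n = n, mean = m,
      sd = sd(x), min = min(x), max = max(x),
      skewness = if (degenerate) 0 else mean((x - m)^3) / m2^1.5,
      kurtosis = if (degenerate) 0 else mean((x - m)^4) / m2^2 - 3,
      degenerate = degenerate
    )
  })
}

#' Pairwise Pearson correlations between metabolites
#'
#' Pearson r on pairwise-complete observations with two-sided t-test
#' p-values and significance stars (* p<0.05, ** p<0.01, *** p<0.0001).
#' Two tables (e.g. two sampling dates) are matched on the intersection of
#' their `line_id`s. Pairs with fewer than 3 complete observations get
#' `NA`.
#'
#' @param tableA,tableB Metabolite tibbles; `tableB` defaults to `tableA`.
#' @return Object of class `nam_cor`: list of matrices `r`, `p`, `n` plus a
#'   long tibble via [generics::tidy()].
#' @export
metabolite_correlations <- function(tableA, tableB = NULL) {
  same <- is.null(tableB)
  if (same) tableB <- tableA
  ids <- intersect(tableA$line_id, tableB$line_id)
  if (!length(ids)) abort("no shared line ids")
  a <- as.matrix(tableA[match(ids, tableA$line_id), metabolite_cols(tableA)])
  b <- as.matrix(tableB[match(ids, tableB$line_id), metabolite_cols(tableB)])
  n <- crossprod(!is.na(a) * 1, !is.na(b) * 1)
  r <- suppressWarnings(cor(a, b, use = "pairwise.complete.obs"))
  r[n < 3] <- NA_real_
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), pmax(n - 2, 1))
  p[is.na(r)] <- NA_real_
  if (same) {
    diag(r) <- 1
    diag(p) <- 0
  }
  structure(list(r = r, p = p, n = n, same = same), class = "nam_cor")
}

cor_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 1e-4 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @export
print.nam_cor <- function(x, ...) {
  cat(sprintf("<nam_cor> %d x %d metabolite correlation matrix\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}
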