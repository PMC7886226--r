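#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stepwise model
#' @param x A `nam_model`.
#' @param ... Unused.
#' @return Tibble of selected terms (`snp_id`, `estimate`, `p_value`).
#' @export
tidy.nam_model <- function(x, ...) x$terms

#' @rdname tidy.nam_model
#' @export
glance.nam_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_terms = nrow(x$terms), n = x$n)
}

#' Tidy variance components
#' @param x A `nam_varcomp`.
#' @param ... Unused.
#' @return Tibble with one row per variance component.
#' @export
tidy.nam_varcomp <- function(x, ...) x$components

#' @rdname tidy.nam_varcomp
#' @export
glance.nam_varcomp <- function(x, ...) {
  tibble::tibble(h2_snp = x$h2, loglik = x$loglik,
                 converged = x$converged, n_iter = x$n_iter, n = x$n)
}

#' Tidy a detection table
#' @param x A `nam_detection`.
#' @param ... Unused.
#' @return The per-SNP detection tibble.
#' @export
tidy.nam_detection <- function(x, ...) x$detections

#' @rdname tidy.nam_detection
#' @export
glance.nam_detection <- function(x, ...) {
  tibble::tibble(
    metabolite = x$metabolite, n_runs = x$n_runs, mean_r2 = x$mean_r2,
    max_dr = max(x$detections$dr),
    mean_model_size = mean(x$runs$model_size)
  )
}

#' Tidy a repeatability estimate
#' @param x A `nam_repeatability`.
#' @param ... Unused.
#' @return One-row tibble with the components and the estimate.
#' @export
tidy.nam_repeatability <- function(x, ...) {
  tibble::tibble(V_G = x$V_G, V_R = x$V_R, r = x$r,
                 repeatability = x$repeatability,
                 n_genotypes = x$n_genotypes, n_obs = x$n_obs)
}

#' Tidy a detection-rate threshold
#' @param x A `nam_threshold`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.nam_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, percentile = x$percentile,
                 n_shuffles = x$n_shuffles, n_runs = x$n_runs,
                 pool_size = sum(x$pool$n))
}

#' Tidy a metabolite correlation matrix
#' @param x A `nam_cor`.
#' @param ... Unused.
#' @return Long tibble `metabolite_a`, `metabolite_b`, `r`, `p`, `n`,
#'   `stars`.
#' @export
tidy.nam_cor <- function(x, ...) {
  long <- tibble::tibble(
    metabolite_a = rep(rownames(x$r), times = ncol(x$r)),
    metabolite_b = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p),
    n = as.vector(x$n)
  )
  long$stars <- cor_stars(long$p)
  long
}
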