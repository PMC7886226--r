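#' Build additive, dominance and epistatic relationship kernels
#'
#' Constructs the three line-by-line genomic relationship matrices behind
#' the SNP-based heritability decomposition: a VanRaden-style additive
#' kernel from column-centered IBS scores, a dominance kernel from centered
#' heterozygosity indicators, and an additive-by-additive epistatic kernel
#' as the Hadamard square of the additive one. Each kernel is scaled to
#' mean diagonal 1 so variance components share the phenotype's units.
#' Imputed (fractional) scores contribute 0 to the dominance indicator.
#'
#' @param ibs Imputed IBS tibble from [impute_mni()].
#' @return Object of class `nam_kernels`: list with matrices `A`, `D`, `I`
#'   and the line ids.
#' @export
build_kernels <- function(ibs) {
  m <- geno_matrix(ibs)
  if (anyNA(m)) abort("IBS matrix must be imputed first (see impute_mni)")
  zc <- scale(m, center = TRUE, scale = FALSE)
  a0 <- tcrossprod(zc)
  da <- mean(diag(a0))
  if (da <= 0) abort("zero-variance score matrix: no genetic relationships")
  A <- a0 / da

  het <- m > 0.5 & m <= 1.5
  imputed <- attr(ibs, "imputed")
  if (!is.null(imputed)) het[imputed] <- FALSE
  if (any(het)) {
    wc <- scale(het * 1, center = TRUE, scale = FALSE)
    d0 <- tcrossprod(wc)
    dd <- mean(diag(d0))
    D <- if (dd > 0) d0 / dd else d0
  } else {
    D <- matrix(0, nrow(m), nrow(m))       # fully inbred panel
  }

  i0 <- A * A
  I <- i0 / mean(diag(i0))
  ids <- ibs$line_id
  dimnames(A) <- dimnames(D) <- dimnames(I) <- list(ids, ids)
  structure(list(A = A, D = D, I = I, line_id = ids),
            class = "nam_kernels")
}

#' @export
print.nam_kernels <- function(x, ...) {
  cat(sprintf("<nam_kernels> %d lines; mean diag A/D/I = %.2f/%.2f/%.2f\n",
              length(x$line_id), mean(diag(x$A)), mean(diag(x$D)),
              mean(diag(x$I))))
  invisible(x)
}

# Restricted log-likelihood and derived quantities at a given set of
# variance components. X is the fixed-effect design (intercept).
reml_eval <- function(y, X, Ks, vc) {
  n <- length(y)
  V <- diag(vc[["R"]], n)
  for (nm in names(Ks)) V <- V + vc[[nm]] * Ks[[nm]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi <- chol2inv(cV)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  Py <- drop(P %*% y)
  ll <- -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py)
}

#' SNP-based heritability by AI-REML
#'
#' Fits the variance-component model y = mu + g_A + g_D + g_I + e with
#' Var(g_X) = sigma2_X * K_X by average-information REML (EM steps first for
#' stability, components constrained non-negative) and returns the genomic
#' heritability h2_SNP = (s2A + s2D + s2I) / (s2A + s2D + s2I + s2R).
#'
#' @param y Numeric phenotype vector aligned to the kernels' lines (or a
#'   named vector matched by name).
#' @param kernels `nam_kernels` from [build_kernels()], or a named list of
#'   relationship matrices.
#' @param components Which kernels to fit (subset of the kernel names).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   restricted log-likelihood.
#'
#' @return Object of class `nam_varcomp`: tibble of components via
#'   [generics::tidy()], with `h2`, `loglik`, `converged`, `n_iter`.
#' @export
estimate_h2_snp <- function(y, kernels, components = c("A", "D", "I"),
                            max_iter = 60, tol = 1e-6) {
  Ks <- if (inherits(kernels, "nam_kernels")) {
    kernels[intersect(components, c("A", "D", "I"))]
  } else {
    kernels[intersect(components, names(kernels))]
  }
  if (!length(Ks)) abort("no kernels selected")
  # drop structurally empty kernels (e.g. dominance with no heterozygotes)
  Ks <- Ks[vapply(Ks, function(k) mean(diag(k)) > 1e-12, logical(1))]
  n <- length(y)
  if (n < 50) warn("fewer than 50 lines: variance components will be noisy")
  if (!is.null(names(y)) && inherits(kernels, "nam_kernels")) {
    y <- y[kernels$line_id]
  }
  if (anyNA(y)) abort("phenotype contains missing values")
  X <- matrix(1, n, 1)
  vy <- var(y)
  if (vy == 0) abort("constant phenotype")
  floor_v <- 1e-8 * vy
  k <- length(Ks)
  vc <- setNames(rep(vy / (k + 1), k + 1), c(names(Ks), "R"))
  ev <- reml_eval(y, X, Ks, vc)
  if (is.null(ev)) abort("initial covariance matrix not positive definite")
  converged <- FALSE
  iter <- 0
  stall <- 0
  Kmats <- c(Ks, list(R = NULL))         # NULL marks the identity kernel
  while (iter < max_iter) {
    iter <- iter + 1
    KPy <- lapply(Kmats, function(K) if (is.null(K)) ev$Py else drop(K %*% ev$Py))
    trPK <- vapply(Kmats, function(K) {
      if (is.null(K)) sum(diag(ev$P)) else sum(ev$P * K)
    }, numeric(1))
    score <- vapply(seq_along(Kmats), function(i) {
      -0.5 * (trPK[i] - sum(ev$Py * KPy[[i]]))
    }, numeric(1))
    # components pinned at the zero boundary with a negative gradient stay
    # put and are dropped from the average-information system
    active <- which(vc > 2 * floor_v | score > 0)
    new_vc <- vc
    if (iter <= 2 || !length(active)) {
      # EM updates: slow but monotone, good far from the optimum
      new_vc <- vapply(seq_along(Kmats), function(i) {
        vc[i] + vc[i]^2 * (sum(ev$Py * KPy[[i]]) - trPK[i]) / n
      }, numeric(1))
    } else {
      m <- length(active)
      AI <- matrix(0, m, m)
      PKPy <- lapply(KPy[active], function(v) drop(ev$P %*% v))
      for (i in seq_len(m)) {
        for (j in i:m) {
          AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[active[i]]] * PKPy[[j]])
        }
      }
      delta <- tryCatch(solve(AI + diag(1e-9 * max(diag(AI)), m),
                              score[active]),
                        error = function(e) score[active] * 0)
      new_vc[active] <- vc[active] + delta
    }
    new_vc <- pmax(new_vc, floor_v)
    names(new_vc) <- names(vc)
    new_ev <- reml_eval(y, X, Ks, new_vc)
    step <- 1
    while ((is.null(new_ev) || new_ev$ll < ev$ll - 1e-10) && step > 1e-4) {
      step <- step / 2
      new_vc <- pmax(vc + step * (new_vc - vc), floor_v)
      new_ev <- reml_eval(y, X, Ks, new_vc)
    }
    if (is.null(new_ev)) break
    stall <- if (abs(new_ev$ll - ev$ll) < tol) stall + 1 else 0
    vc <- new_vc
    ev <- new_ev
    if (stall >= 2 && iter > 4) {        # two quiet iterations in a row
      converged <- TRUE
      break
    }
  }
  vc[vc <= 2 * floor_v] <- 0             # boundary estimates reported as 0
  gen <- sum(vc[names(Ks)])
  full <- setNames(numeric(4), c("A", "D", "I", "R"))
  full[names(vc)] <- vc
  structure(
    list(
      components = tibble::tibble(
        component = c("A", "D", "I", "R"),
        variance = unname(full),
        fitted = c(c("A", "D", "I") %in% names(Ks), TRUE)
      ),
      h2 = if (gen + vc[["R"]] > 0) gen / (gen + vc[["R"]]) else 0,
      loglik = ev$ll, converged = converged, n_iter = iter, n = n
    ),
    class = "nam_varcomp"
  )
}

#' @export
print.nam_varcomp <- function(x, ...) {
  cat(sprintf("<nam_varcomp> h2_SNP = %.3f (%s, %d iterations)\n",
              x$h2, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  v <- setNames(x$components$variance, x$components$component)
  cat(sprintf("  s2A = %.4g  s2D = %.4g  s2I = %.4g  s2R = %.4g\n",
              v["A"], v["D"], v["I"], v["R"]))
  invisible(x)
}

#' Repeatability from variance components
#'
#' The closed form rep = V_G / (V_G + V_R / r), clamped to \[0, 1\]; the
#' degenerate V_G = V_R = 0 case returns 0.
#'
#' @param V_G,V_R Genetic and residual variance components (>= 0).
#' @param r Number of replications per genotype (>= 1; the unbalanced-design
#'   coefficient n0 in general).
#' @return Repeatability in \[0, 1\].
#' @export
repeatability_formula <- function(V_G, V_R, r) {
  if (any(V_G < 0) || any(V_R < 0)) abort("variance components must be >= 0")
  if (any(r < 1)) abort("`r` must be >= 1")
  denom <- V_G + V_R / r
  out <- ifelse(denom > 0, V_G / denom, 0)
  pmin(pmax(out, 0), 1)
}

#' Repeatability from replicated control genotypes
#'
#' One-way random-effects ANOVA over control genotypes: the genetic and
#' residual variance components V_G and V_R come from the expected mean
#' squares, with the unbalanced-design replication coefficient
#' n0 = (N - sum(n_i^2)/N) / (g - 1) taking the role of the number of
#' replications r. Repeatability is V_G / (V_G + V_R / r), clamped to
#' \[0, 1\].
#'
#' @param data Tibble of replicated measurements.
#' @param genotype,value Column names (strings) of the genotype label and
#'   the measurement.
#'
#' @return Object of class `nam_repeatability` with fields `V_G`, `V_R`,
#'   `r`, `repeatability`, `n_genotypes`, `n_obs`.
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(letters[1:5], each = 3),
#'                     y = rnorm(15) + rep(rnorm(5, sd = 2), each = 3))
#' repeatability(d, genotype = "g", value = "y")
repeatability <- function(data, genotype = "control_id", value = "value") {
  g <- as.factor(data[[genotype]])
  y <- data[[value]]
  ok <- !is.na(y) & !is.na(g)
  g <- droplevels(g[ok])
  y <- y[ok]
  ni <- table(g)
  if (nlevels(g) < 2) abort("repeatability needs at least two genotypes")
  if (!any(ni >= 2)) abort("need replicate measurements for at least one genotype")
  N <- length(y)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ss_b <- sum(ni * (means - mean(y))^2)
  ss_w <- sum((y - means[g])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  V_R <- ms_w
  V_G <- max((ms_b - ms_w) / n0, 0)
  rep_est <- repeatability_formula(V_G, V_R, n0)
  structure(
    list(V_G = V_G, V_R = V_R, r = n0, repeatability = rep_est,
         n_genotypes = k, n_obs = N),
    class = "nam_repeatability"
  )
}

#' @export
print.nam_repeatability <- function(x, ...) {
  cat(sprintf(
    "<nam_repeatability> rep = %.3f (V_G = %.3g, V_R = %.3g, r = %.2f)\n",
    x$repeatability, x$V_G, x$V_R, x$r
  ))
  invisible(x)
}
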