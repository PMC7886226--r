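# Independent reference implementations used as oracles. These are kept
# deliberately naive (literal loops, stats::lm, matrix powers) and share no
# code with the package internals they check.

# Exact single-locus genotype distribution of a BC1S3 line at a locus
# polymorphic between donor and recurrent parent, by enumerating the
# crossing scheme as a Markov chain over {hom recurrent, het, hom donor}.
bc1s3_exact_probs <- function(n_selfings = 3) {
  # BC1 = gamete of F1 (het) x recurrent gamete
  v <- c(hom_rec = 0.5, het = 0.5, hom_donor = 0)
  selfing <- matrix(
    c(1, 0, 0,
      0.25, 0.5, 0.25,
      0, 0, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(names(v), names(v))
  )
  for (i in seq_len(n_selfings)) v <- drop(v %*% selfing)
  v
}

# Literal stepwise forward-backward selector built on stats::lm and
# anova(): at each step the marginal F-test of every candidate is computed
# by fitting the enlarged model, the smallest p enters if below p_enter,
# then backward elimination removes the worst term while its marginal p is
# at or above p_remove.
naive_stepwise <- function(y, X, p_enter = 0.001, p_remove = 0.001,
                           max_terms = min(50, floor(length(y) / 10))) {
  d <- as.data.frame(X)
  d$..y <- y
  sel <- character(0)
  repeat {
    added <- FALSE
    cand <- setdiff(colnames(X), sel)
    if (length(cand) && length(sel) < max_terms) {
      base_fit <- stats::lm(stats::reformulate(c("1", sel), "..y"), data = d)
      ps <- vapply(cand, function(s) {
        fit2 <- stats::lm(stats::reformulate(c("1", sel, s), "..y"), data = d)
        if (anyNA(stats::coef(fit2))) return(1)
        stats::anova(base_fit, fit2)$`Pr(>F)`[2]
      }, numeric(1))
      j <- which.min(ps)
      if (ps[j] < p_enter) {
        sel <- c(sel, cand[j])
        added <- TRUE
      }
    }
    removed <- FALSE
    while (length(sel)) {
      fit <- stats::lm(stats::reformulate(c("1", sel), "..y"), data = d)
      pv <- summary(fit)$coefficients[-1, 4]
      worst <- which.max(pv)
      if (pv[worst] >= p_remove) {
        sel <- sel[-worst]
        removed <- TRUE
      } else {
        break
      }
    }
    if (!added && !removed) break
  }
  fit <- stats::lm(stats::reformulate(c("1", sel), "..y"), data = d)
  list(sel = sel, beta = stats::coef(fit))
}

# Brute-force REML for the single-kernel model y = mu + g + e,
# Var(g) = s2A * A: profile the restricted likelihood on a grid of the
# variance ratio via spectral decomposition.
grid_reml_single <- function(y, A, ratios = exp(seq(log(1e-3), log(1e3),
                                                    length.out = 2001))) {
  n <- length(y)
  eg <- eigen(A, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  best <- list(ll = -Inf)
  for (r in ratios) {                    # r = s2A / s2R
    d <- r * lam + 1                     # V = s2R * (r*A + I)
    w <- 1 / d
    xtwx <- sum(xt^2 * w)
    beta <- sum(xt * yt * w) / xtwx
    res2 <- sum((yt - xt * beta)^2 * w)
    s2R <- res2 / (n - 1)
    ll <- -0.5 * (sum(log(d)) + (n - 1) * log(s2R) + log(xtwx) + (n - 1))
    if (ll > best$ll) best <- list(ll = ll, s2A = r * s2R, s2R = s2R)
  }
  best
}

# Small deterministic NAM fixture shared by several tests.
small_pop <- function(seed = 101, n_families = 4, lines_per_family = 20,
                      n_snps = 120) {
  simulate_nam(n_families = n_families, lines_per_family = lines_per_family,
               n_snps = n_snps, seed = seed)
}
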