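#' Stepwise forward-backward multiple-SNP regression
#'
#' The core selection engine: starting from an intercept-only model, the
#' forward step adds the candidate SNP with the smallest marginal-F p-value
#' if it is below `p_enter`; after every forward step, backward elimination
#' repeatedly removes the selected SNP with the largest marginal p-value
#' while it is at or above `p_remove`, refitting jointly after every
#' change. A rank guard skips candidates whose inclusion would make the
#' design matrix numerically rank deficient (so of two identical columns
#' only the first in map order can enter). Ties on p-values resolve to the
#' earliest column, i.e. lowest (chromosome, bp) when columns follow the
#' map.
#'
#' @param y Numeric response (no missing values).
#' @param X Numeric matrix of candidate SNP scores with column names in map
#'   order.
#' @param p_enter,p_remove Marginal-F p-value thresholds to enter (strictly
#'   below) and stay (strictly below) in the model; both default to 0.001.
#' @param max_terms Cap on model size; default `min(50, floor(n/10))`.
#'
#' @return Object of class `nam_model`: list with `terms` (tibble `snp_id`,
#'   `estimate`, `p_value` in selection order), `intercept`, `r_squared`,
#'   `n`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 20), 200, dimnames = list(NULL, paste0("s", 1:20)))
#' y <- 2 * X[, 3] + rnorm(200, sd = 0.5)
#' stepwise_select(y, X)$terms
stepwise_select <- function(y, X, p_enter = 0.001, p_remove = 0.001,
                            max_terms = NULL) {
  n <- length(y)
  if (!is.matrix(X) || ncol(X) == 0L) abort("`X` must be a matrix with columns")
  if (nrow(X) != n) abort("`y` and `X` disagree on the number of lines")
  if (anyNA(y) || anyNA(X)) abort("missing values are not allowed here")
  if (sd(y) == 0) abort("constant response")
  max_terms <- max_terms %||% min(50L, floor(n / 10))
  m <- ncol(X)
  col_ss <- colSums(scale(X, center = TRUE, scale = FALSE)^2)
  sel <- integer(0)
  tss <- sum((y - mean(y))^2)

  joint_fit <- function(sel) {
    Xm <- cbind(1, X[, sel, drop = FALSE])
    xtx <- crossprod(Xm)
    xtxi <- chol2inv(chol(xtx))
    beta <- drop(xtxi %*% crossprod(Xm, y))
    res <- y - drop(Xm %*% beta)
    rss <- sum(res^2)
    df <- n - ncol(Xm)
    se <- sqrt(pmax(diag(xtxi), 0) * rss / df)
    p <- 2 * pt(-abs(beta / se), df)
    list(beta = beta, p = p, rss = rss, df = df)
  }

  # Residualized state: Xr and ry are X and y projected off the current
  # model (intercept + selected SNPs); ss and by are the candidate sums of
  # squares and cross-products with ry. Forward steps update these with a
  # rank-1 sweep; backward removals trigger a full rebuild (rare).
  rebuild <- function(sel) {
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    Xr <- X - Q %*% crossprod(Q, X)
    ry <- drop(y - Q %*% crossprod(Q, y))
    list(Xr = Xr, ry = ry, rss0 = sum(ry^2),
         ss = colSums(Xr^2), by = drop(crossprod(Xr, ry)))
  }
  st <- rebuild(sel)

  for (outer in seq_len(200)) {
    # forward: marginal F-test of each candidate given the current model,
    # from partial correlations of the residualized columns
    added <- FALSE
    df <- n - (length(sel) + 2L)
    if (df >= 1 && length(sel) < max_terms && st$rss0 > 0) {
      ok <- col_ss > 0 &
        st$ss / pmax(col_ss, .Machine$double.xmin) > 1e-10
      if (any(ok)) {
        rho2 <- numeric(m)
        rho2[ok] <- (st$by[ok]^2) / (st$ss[ok] * st$rss0)
        rho2 <- pmin(rho2, 1 - 1e-14)
        pv <- rep(1, m)
        pv[ok] <- pf(rho2[ok] * df / (1 - rho2[ok]), 1, df,
                     lower.tail = FALSE)
        j <- which.min(pv)              # first minimum = lowest map order
        if (pv[j] < p_enter) {
          sel <- c(sel, j)
          q <- st$Xr[, j] / sqrt(st$ss[j])
          w <- drop(crossprod(q, st$Xr))
          wy <- sum(q * st$ry)
          st$Xr <- st$Xr - q %*% t(w)
          st$ry <- st$ry - q * wy
          st$rss0 <- max(st$rss0 - wy^2, 0)
          st$ss <- pmax(st$ss - w^2, 0)
          st$by <- st$by - w * wy
          added <- TRUE
        }
      }
    }
    # backward elimination to exhaustion
    removed_any <- FALSE
    while (length(sel)) {
      fit <- joint_fit(sel)
      p_snp <- fit$p[-1]
      worst <- which.max(p_snp)
      if (p_snp[worst] >= p_remove) {
        sel <- sel[-worst]
        removed_any <- TRUE
      } else {
        break
      }
    }
    if (removed_any) st <- rebuild(sel)
    if (!added && !removed_any) break
  }

  if (length(sel)) {
    fit <- joint_fit(sel)
    terms <- tibble::tibble(
      snp_id = colnames(X)[sel],
      estimate = unname(fit$beta[-1]),
      p_value = unname(fit$p[-1])
    )
    intercept <- unname(fit$beta[1])
    r2 <- 1 - fit$rss / tss
  } else {
    terms <- tibble::tibble(snp_id = character(), estimate = numeric(),
                            p_value = numeric())
    intercept <- mean(y)
    r2 <- 0
  }
  structure(list(terms = terms, intercept = intercept, r_squared = r2, n = n),
            class = "nam_model")
}

#' @export
print.nam_model <- function(x, ...) {
  cat(sprintf("<nam_model> %d SNP(s), training R^2 = %.3f, n = %d\n",
              nrow(x$terms), x$r_squared, x$n))
  if (nrow(x$terms)) print(x$terms, n = 10)
  invisible(x)
}

#' Predict from a selected model
#'
#' @param object A `nam_model`.
#' @param newdata IBS tibble or score matrix containing the model's SNPs.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.nam_model <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else geno_matrix(newdata)
  if (!nrow(object$terms)) return(rep(object$intercept, nrow(m)))
  drop(object$intercept +
         m[, object$terms$snp_id, drop = FALSE] %*% object$terms$estimate)
}

#' Family-stratified cross-validation folds
#'
#' Deals the lines of each family into `k` folds per repetition, shuffled
#' with a seeded RNG, so each fold holds ~1/k of every family and fold
#' sizes within a family differ by at most one.
#'
#' @param lines Tibble with `line_id` and `family_id` (an IBS tibble
#'   works).
#' @param k Number of folds.
#' @param n_reps Number of repetitions with fresh random folds.
#' @param seed Integer seed.
#'
#' @return Object of class `nam_folds`: tibble `rep`, `line_id`,
#'   `family_id`, `fold`.
#' @export
make_folds <- function(lines, k = 5, n_reps = 20, seed = NULL) {
  if (k < 2) abort("`k` must be at least 2")
  stopifnot_scalar_seed(seed)
  small <- table(lines$family_id) < k
  if (any(small)) {
    warn(paste0("families with fewer than k lines (round-robin filled): ",
                paste(names(small)[small], collapse = ", ")))
  }
  out <- purrr::map_dfr(seq_len(n_reps), function(r) {
    purrr::map_dfr(split(seq_len(nrow(lines)), lines$family_id), function(ix) {
      nf <- length(ix)
      offset <- sample.int(k, 1L)
      tibble::tibble(
        rep = r,
        line_id = lines$line_id[sample(ix)],
        family_id = lines$family_id[ix[1]],
        fold = ((seq_len(nf) - 1L + offset) %% k) + 1L
      )
    })
  })
  structure(out, class = c("nam_folds", class(out)), k = k, n_reps = n_reps)
}

#' Prediction ability
#'
#' Squared Pearson correlation between observed and predicted values of a
#' validation set. Constant predictions (an empty or degenerate model)
#' yield 0 with attribute `constant = TRUE`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return r-squared in \[0, 1\].
#' @export
prediction_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("length mismatch")
  if (length(observed) < 3) abort("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    return(structure(0, constant = TRUE))
  }
  structure(cor(observed, predicted)^2, constant = FALSE)
}

#' Cross-validated stepwise GWAS
#'
#' For every repetition and held-out fold (k folds x n_reps repetitions =
#' n_runs cross-validation runs), fits the stepwise forward-backward model
#' on the training 4/5 of the lines, predicts the held-out fold, and
#' records which SNPs entered the final model and the validation
#' prediction ability. A SNP's detection rate (DR) is the number of runs
#' that retained it.
#'
#' @param ibs Imputed IBS tibble (`line_id`, `family_id`, SNP columns in
#'   map order).
#' @param pheno Phenotype tibble with `line_id` and the metabolite column
#'   (Box-Cox transformed upstream), or a numeric vector aligned to `ibs`.
#' @param metabolite Name of the phenotype column when `pheno` is a tibble.
#' @param plan Fold plan from [make_folds()].
#' @inheritParams stepwise_select
#'
#' @return Object of class `nam_detection`: list with `detections` (tibble
#'   `snp_id`, `dr`, `mean_beta`, `n_included`), `runs` (tibble `rep`,
#'   `fold`, `r2`, `model_size`, `constant`), `models` (long tibble `rep`,
#'   `fold`, `snp_id`, `estimate`), `n_runs`, `metabolite`.
#' @export
cross_validate <- function(ibs, pheno, metabolite = NULL, plan,
                           p_enter = 0.001, p_remove = 0.001,
                           max_terms = NULL) {
  X <- geno_matrix(ibs)
  if (is.numeric(pheno)) {
    y <- pheno
    metabolite <- metabolite %||% "phenotype"
  } else {
    metabolite <- metabolite %||% metabolite_cols(pheno)[1]
    y <- pheno[[metabolite]][match(ibs$line_id, pheno$line_id)]
  }
  if (anyNA(y)) abort("phenotype missing for some lines (impute upstream)")
  k <- attr(plan, "k")
  n_reps <- attr(plan, "n_reps")
  fold_of <- function(r) {
    sub <- plan[plan$rep == r, ]
    sub$fold[match(ibs$line_id, sub$line_id)]
  }
  runs <- vector("list", k * n_reps)
  models <- vector("list", k * n_reps)
  i <- 0
  for (r in seq_len(n_reps)) {
    fold <- fold_of(r)
    if (anyNA(fold)) abort("fold plan does not cover all lines")
    for (f in seq_len(k)) {
      i <- i + 1
      train <- fold != f
      if (!is.null(max_terms) && sum(train) < 2 * max_terms) {
        abort("training set smaller than twice `max_terms`")
      }
      fit <- stepwise_select(y[train], X[train, , drop = FALSE],
                             p_enter = p_enter, p_remove = p_remove,
                             max_terms = max_terms)
      pred <- predict(fit, X[!train, , drop = FALSE])
      r2 <- prediction_ability(y[!train], pred)
      runs[[i]] <- tibble::tibble(
        rep = r, fold = f, r2 = as.numeric(r2),
        model_size = nrow(fit$terms),
        constant = isTRUE(attr(r2, "constant"))
      )
      if (nrow(fit$terms)) {
        models[[i]] <- dplyr::mutate(fit$terms[c("snp_id", "estimate")],
                                     rep = r, fold = f, .before = 1)
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  models <- dplyr::bind_rows(models)
  incl <- if (nrow(models)) {
    dplyr::summarise(dplyr::group_by(models, .data$snp_id),
                     dr = dplyr::n(), mean_beta = mean(.data$estimate),
                     .groups = "drop")
  } else {
    tibble::tibble(snp_id = character(), dr = integer(),
                   mean_beta = numeric())
  }
  detections <- tibble::tibble(snp_id = colnames(X)) |>
    dplyr::left_join(incl, by = "snp_id") |>
    dplyr::mutate(
      dr = dplyr::coalesce(.data$dr, 0L),
      n_included = .data$dr,
      mean_beta = ifelse(.data$dr > 0, .data$mean_beta, NA_real_)
    )
  structure(
    list(detections = detections, runs = runs, models = models,
         n_runs = k * n_reps, metabolite = metabolite,
         mean_r2 = mean(runs$r2)),
    class = "nam_detection"
  )
}

#' @export
print.nam_detection <- function(x, ...) {
  cat(sprintf(
    "<nam_detection> '%s': %d runs, mean prediction r2 = %.3f, max DR = %d\n",
    x$metabolite, x$n_runs, x$mean_r2, max(x$detections$dr)
  ))
  invisible(x)
}

#' Detection-rate threshold from a pooled null distribution
#'
#' The smallest integer t such that at least `percentile` percent of the
#' pooled null detection rates are strictly below t — the reading
#' "99.99% of markers have fewer detections".
#'
#' @param dr_values Integer vector of pooled null DR values (zeros for
#'   never-selected SNPs included).
#' @param percentile Percentile in (0, 100\].
#' @return Integer threshold.
#' @export
#' @examples
#' dr_threshold(c(rep(0L, 1e5), rep(5L, 20)), 99.99)  # 6
dr_threshold <- function(dr_values, percentile = 99.99) {
  if (!length(dr_values)) abort("empty DR pool")
  target <- percentile / 100
  for (t in 0:(max(dr_values) + 1L)) {
    if (mean(dr_values < t) >= target) return(as.integer(t))
  }
  as.integer(max(dr_values) + 1L)       # unreachable
}

#' Permutation-calibrated detection-rate threshold
#'
#' Shuffles the phenotype table's rows relative to the genotype matrix
#' (whole records, preserving inter-metabolite correlation), reruns the
#' full cross-validation GWAS on each shuffled matrix, pools the per-SNP
#' per-metabolite detection rates across shuffles, and returns the
#' percentile threshold via [dr_threshold()].
#'
#' @inheritParams cross_validate
#' @param metabolites Metabolite columns to include (default: all).
#' @param n_shuffles Number of shuffled matrices.
#' @param k,n_reps Fold-plan parameters for each shuffled run.
#' @param percentile Percentile of the pooled null DR distribution.
#' @param seed Integer seed driving the shuffles and fold plans.
#'
#' @return Object of class `nam_threshold`: list with `threshold`,
#'   `percentile`, `n_shuffles`, `n_runs`, and `pool` (tibble of DR value
#'   counts).
#' @export
permutation_threshold <- function(ibs, pheno, metabolites = NULL,
                                  n_shuffles = 3, k = 5, n_reps = 20,
                                  percentile = 99.99, p_enter = 0.001,
                                  p_remove = 0.001, max_terms = NULL,
                                  seed = NULL) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1")
  stopifnot_scalar_seed(seed)
  metabolites <- metabolites %||% metabolite_cols(pheno)
  pheno <- pheno[match(ibs$line_id, pheno$line_id), ]
  pool <- list()
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(nrow(pheno))
    shuffled <- pheno
    shuffled[metabolites] <- pheno[perm, metabolites]
    plan <- make_folds(ibs, k = k, n_reps = n_reps,
                       seed = sample.int(2^30, 1))
    for (met in metabolites) {
      det <- cross_validate(ibs, shuffled, metabolite = met, plan = plan,
                            p_enter = p_enter, p_remove = p_remove,
                            max_terms = max_terms)
      pool[[length(pool) + 1L]] <- det$detections$dr
    }
  }
  pool <- unlist(pool)
  structure(
    list(
      threshold = dr_threshold(pool, percentile),
      percentile = percentile, n_shuffles = n_shuffles,
      n_runs = k * n_reps,
      pool = dplyr::count(tibble::tibble(dr = pool), .data$dr)
    ),
    class = "nam_threshold"
  )
}

#' @export
print.nam_threshold <- function(x, ...) {
  cat(sprintf(
    "<nam_threshold> DR >= %d (%.2f%% percentile of %d pooled null DRs, %d shuffles)\n",
    x$threshold, x$percentile, sum(x$pool$n), x$n_shuffles
  ))
  invisible(x)
}
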