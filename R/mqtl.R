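#' Group significant SNPs into mQTL regions
#'
#' SNPs whose detection rate reaches the threshold are sorted along each
#' chromosome and merged into one region while consecutive significant
#' SNPs lie at most `gap_bp` apart; regions are numbered consecutively per
#' chromosome ("3H-2" = second region on chromosome 3, with an optional
#' sampling-date suffix as in "3H-2_1"). The peak SNP has the maximal DR,
#' ties broken by the largest |mean effect|, then map order.
#'
#' @param detections A `nam_detection` from [cross_validate()] (or its
#'   `detections` tibble).
#' @param map Genetic map tibble.
#' @param threshold Integer DR threshold (e.g. from
#'   [permutation_threshold()]).
#' @param gap_bp Maximum base-pair gap between consecutive significant
#'   SNPs within one region.
#' @param date_tag Optional sampling-date suffix for the mQTL ids.
#'
#' @return Tibble of class `nam_regions`: `mqtl_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `peak_snp`, `peak_dr`, `metabolite`, and the
#'   list-column `member_snps`.
#' @export
group_mqtl <- function(detections, map, threshold, gap_bp = 5e6,
                       date_tag = NULL) {
  if (threshold < 1) abort("`threshold` must be >= 1")
  metab <- NA_character_
  if (inherits(detections, "nam_detection")) {
    metab <- detections$metabolite
    detections <- detections$detections
  }
  sig <- dplyr::inner_join(
    dplyr::filter(detections, .data$dr >= threshold),
    map, by = "snp_id"
  )
  if (!nrow(sig)) {
    out <- tibble::tibble(
      mqtl_id = character(), chrom = integer(), start_bp = integer(),
      end_bp = integer(), n_snps = integer(), peak_snp = character(),
      peak_dr = integer(), metabolite = character(),
      member_snps = list()
    )
    class(out) <- c("nam_regions", class(out))
    return(out)
  }
  sig <- dplyr::arrange(sig, .data$chrom, .data$pos_bp)
  out <- purrr::map_dfr(split(sig, sig$chrom), function(chr_tbl) {
    brk <- c(0, cumsum(diff(chr_tbl$pos_bp) > gap_bp))
    purrr::imap_dfr(split(chr_tbl, brk), function(g, key) {
      pk <- g[order(-g$dr, -abs(g$mean_beta), g$pos_bp), ][1, ]
      tibble::tibble(
        chrom = g$chrom[1],
        start_bp = min(g$pos_bp), end_bp = max(g$pos_bp),
        n_snps = nrow(g),
        peak_snp = pk$snp_id, peak_dr = as.integer(pk$dr),
        metabolite = metab,
        member_snps = list(g$snp_id)
      )
    })
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start_bp)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$chrom),
    mqtl_id = sprintf("%dH-%d%s", .data$chrom, dplyr::row_number(),
                      if (is.null(date_tag)) "" else paste0("_", date_tag)),
    .before = 1
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("nam_regions", class(out))
  out
}

#' Explained phenotypic variance of mQTL regions
#'
#' Fits, for each region, all member SNPs jointly in an ordinary multiple
#' regression of the phenotype on the whole data set and records the
#' coefficient of determination. Collinear members are pruned via the
#' pivoted QR rank guard and flagged.
#'
#' @param regions `nam_regions` tibble from [group_mqtl()].
#' @param ibs Imputed IBS tibble.
#' @param pheno Phenotype tibble or numeric vector (as in
#'   [cross_validate()]).
#' @param metabolite Phenotype column name when `pheno` is a tibble.
#'
#' @return `regions` with columns `region_r2` and `pruned` added.
#' @export
region_r2 <- function(regions, ibs, pheno, metabolite = NULL) {
  X <- geno_matrix(ibs)
  y <- if (is.numeric(pheno)) {
    pheno
  } else {
    metabolite <- metabolite %||% metabolite_cols(pheno)[1]
    pheno[[metabolite]][match(ibs$line_id, pheno$line_id)]
  }
  fit_one <- function(snps) {
    miss <- setdiff(snps, colnames(X))
    if (length(miss)) abort(paste0("member SNP(s) not in IBS matrix: ",
                                   paste(head(miss, 5), collapse = ", ")))
    Xm <- cbind(1, X[, snps, drop = FALSE])
    q <- qr(Xm)
    pruned <- q$rank < ncol(Xm)
    res <- qr.resid(q, y)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    tibble::tibble(region_r2 = max(min(r2, 1), 0), pruned = pruned)
  }
  dplyr::bind_cols(regions, purrr::map_dfr(regions$member_snps, fit_one))
}

# A SNP segregates in a family when its IBS scores there span a real
# contrast (range >= 0.5 keeps imputed fractional scores from counting).
segregating_matrix <- function(ibs, snps) {
  m <- geno_matrix(ibs)[, snps, drop = FALSE]
  fams <- sort(unique(ibs$family_id))
  seg <- matrix(FALSE, length(snps), length(fams),
                dimnames = list(snps, fams))
  for (f in fams) {
    fm <- m[ibs$family_id == f, , drop = FALSE]
    seg[, f] <- apply(fm, 2, function(x) diff(range(x)) >= 0.5)
  }
  seg
}

#' Family-specific cumulated mQTL effects
#'
#' Applies the cumulation method across cross-validation runs: within each
#' run and family, the effects (2 x the allele-substitution estimate, the
#' homozygous wild vs elite contrast) of all region member SNPs that were
#' in that run's final model and segregate in the family are summed; the
#' family-specific mQTL effect is the mean of these sums over all runs.
#' Families in which no member SNP segregates get an exact 0.
#'
#' @param detections `nam_detection` carrying the per-run models.
#' @param regions `nam_regions` from [group_mqtl()].
#' @param ibs Imputed IBS tibble (defines segregation per family).
#'
#' @return Tibble `mqtl_id`, `family_id`, `effect`, `n_runs_contributing`.
#' @export
family_effects <- function(detections, regions, ibs) {
  models <- detections$models
  n_runs <- detections$n_runs
  fams <- sort(unique(ibs$family_id))
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    snps <- regions$member_snps[[i]]
    seen <- intersect(snps, unique(models$snp_id))
    if (length(seen) < length(snps)) {
      warn(sprintf("region %s: %d member SNP(s) never entered any model",
                   regions$mqtl_id[i], length(snps) - length(seen)))
    }
    seg <- segregating_matrix(ibs, snps)
    sub <- models[models$snp_id %in% snps, , drop = FALSE]
    purrr::map_dfr(fams, function(f) {
      seg_snps <- snps[seg[, f]]
      m <- sub[sub$snp_id %in% seg_snps, , drop = FALSE]
      if (nrow(m)) {
        per_run <- dplyr::summarise(
          dplyr::group_by(m, .data$rep, .data$fold),
          eff = sum(2 * .data$estimate), .groups = "drop"
        )
        eff <- sum(per_run$eff) / n_runs   # runs without members count as 0
        nr <- nrow(per_run)
      } else {
        eff <- 0
        nr <- 0L
      }
      tibble::tibble(mqtl_id = regions$mqtl_id[i], family_id = f,
                     effect = eff, n_runs_contributing = nr)
    })
  })
}
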