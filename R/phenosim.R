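#' Specify planted QTL for phenotype simulation
#'
#' @param snp_id Character vector of causal SNP ids (must exist in the map).
#' @param effect Additive allele-substitution effect per IBS unit, recycled
#'   to the number of QTL.
#' @param family_multiplier Optional QTL x family matrix (or vector recycled
#'   across QTL) scaling each effect within a family; defaults to 1
#'   everywhere. Column names, when present, must be family ids.
#' @param h2_target Narrow-sense heritability of the simulated trait in
#'   \[0, 1\].
#' @param link `"identity"` for a Gaussian trait or `"exp"` for a positive,
#'   right-skewed metabolite-like trait (`exp(z / sd(z))` of the latent
#'   Gaussian trait z).
#'
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(snp_id, effect, family_multiplier = NULL,
                     h2_target = 0.5, link = c("identity", "exp")) {
  link <- match.arg(link)
  if (h2_target < 0 || h2_target > 1) abort("`h2_target` must be in [0, 1]")
  effect <- rep_len(effect, length(snp_id))
  structure(
    list(snp_id = snp_id, effect = effect,
         family_multiplier = family_multiplier,
         h2_target = h2_target, link = link),
    class = "qtl_spec"
  )
}

qtl_multiplier_matrix <- function(qtl, families) {
  k <- length(qtl$snp_id)
  fm <- qtl$family_multiplier
  if (is.null(fm)) {
    fm <- matrix(1, k, length(families), dimnames = list(NULL, families))
  } else if (is.matrix(fm)) {
    if (is.null(colnames(fm))) colnames(fm) <- families
    fm <- fm[, families, drop = FALSE]
  } else {
    fm <- matrix(rep_len(fm, k), k, length(families),
                 dimnames = list(NULL, families))
  }
  fm
}

#' Simulate metabolite-like phenotypes with known genetic architecture
#'
#' Computes each line's genetic value as the sum of planted QTL effects
#' times its IBS scores (donor-allele dosages), scales white noise so the
#' planted narrow-sense heritability holds, and optionally exponentiates to
#' produce positive right-skewed values. The returned truth object records
#' everything needed for recovery tests.
#'
#' @param geno Genotype tibble (`line_id`, `family_id`, SNP columns of
#'   dosages), e.g. `simulate_nam(...)$geno`.
#' @param qtl A [qtl_spec()] or a named list of them (one metabolite each).
#' @param seed Optional integer seed for the noise draw.
#'
#' @return A list with `pheno` (tibble `line_id`, `family_id`, one column
#'   per metabolite) and `truth` (class `sim_truth`): per-metabolite genetic
#'   values, noise variance, realized heritability and per-family mean
#'   genetic effects.
#' @export
simulate_phenotypes <- function(geno, qtl, seed = NULL) {
  stopifnot_scalar_seed(seed)
  if (inherits(qtl, "qtl_spec")) qtl <- list(met_1 = qtl)
  if (is.null(names(qtl))) names(qtl) <- paste0("met_", seq_along(qtl))
  m <- geno_matrix(geno)
  fam <- geno$family_id
  fams <- unique(fam)
  out <- geno[ID_COLS]
  truth <- list()
  for (nm in names(qtl)) {
    q <- qtl[[nm]]
    miss <- setdiff(q$snp_id, colnames(m))
    if (length(miss)) abort(paste0("QTL SNP(s) not in genotypes: ",
                                   paste(miss, collapse = ", ")))
    g <- numeric(nrow(m))
    if (length(q$snp_id)) {
      fm <- qtl_multiplier_matrix(q, fams)
      for (j in seq_along(q$snp_id)) {
        g <- g + q$effect[j] * unname(fm[j, match(fam, fams)]) *
          unname(m[, q$snp_id[j]])
      }
    }
    vg <- var(g)
    if (q$h2_target > 0 && length(q$snp_id) && vg == 0) {
      abort("Var(g) = 0 with h2_target > 0: cannot scale noise")
    }
    sigma2_e <- if (q$h2_target >= 1) {
      0
    } else if (vg == 0) {
      1                       # pure-noise trait: unit residual variance
    } else {
      vg * (1 - q$h2_target) / q$h2_target
    }
    z <- g + rnorm(length(g), sd = sqrt(sigma2_e))
    y <- if (q$link == "exp") exp(z / sd(z)) else z
    out[[nm]] <- y
    truth[[nm]] <- list(
      g = setNames(g, geno$line_id),
      sigma2_e = sigma2_e,
      var_g = vg,
      h2_target = q$h2_target,
      h2_realized = if (vg + sigma2_e > 0) vg / (vg + sigma2_e) else 0,
      qtl = q,
      family_mean_g = tapply(g, fam, mean)
    )
  }
  list(pheno = out, truth = structure(truth, class = "sim_truth"))
}

#' Add missing values and replicated control genotypes
#'
#' Sets phenotype cells missing completely at random and appends a table of
#' replicated control genotypes whose measurements share a genotype-specific
#' mean, for repeatability estimation.
#'
#' @param pheno Phenotype tibble (`line_id`, `family_id`, metabolite
#'   columns).
#' @param missing_rate MCAR missingness probability per cell, in \[0, 1).
#' @param n_controls Number of control genotypes.
#' @param reps_per_control Replicates per control; a scalar or a vector of
#'   length `n_controls`.
#' @param between_sd,within_sd Standard deviations of the control genotype
#'   means and of the replicate noise.
#' @param seed Optional integer seed.
#'
#' @return List with `pheno` (values blanked at `missing_rate`) and
#'   `controls`: tibble `control_id`, `rep`, one column per metabolite.
#' @export
inject_missingness_and_controls <- function(pheno, missing_rate = 0,
                                            n_controls = 17,
                                            reps_per_control = 4,
                                            between_sd = 1, within_sd = 0.5,
                                            seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)")
  }
  stopifnot_scalar_seed(seed)
  mets <- setdiff(names(pheno), ID_COLS)
  if (missing_rate > 0) {
    for (nm in mets) {
      hit <- runif(nrow(pheno)) < missing_rate
      pheno[[nm]][hit] <- NA_real_
    }
  }
  controls <- NULL
  if (n_controls > 0) {
    reps <- rep_len(reps_per_control, n_controls)
    controls <- tibble::tibble(
      control_id = rep(sprintf("CTRL%02d", seq_len(n_controls)), reps),
      rep = unlist(lapply(reps, seq_len))
    )
    for (nm in mets) {
      mu <- rnorm(n_controls, mean = mean(pheno[[nm]], na.rm = TRUE),
                  sd = between_sd)
      controls[[nm]] <- rep(mu, reps) + rnorm(nrow(controls), sd = within_sd)
    }
  }
  list(pheno = pheno, controls = controls)
}

#' Simulate the default mQTL validation scenario
#'
#' Builds a full NAM population (by default 25 families x 52 lines, 2000
#' SNPs on 7 chromosomes of 150 cM) and a phenotype controlled by three
#' planted QTL on distinct chromosomes whose variance shares sum to the
#' trait heritability. Effects are calibrated on the realized genotypes so
#' that each QTL explains its target share of phenotypic variance.
#'
#' @param seed Integer seed for the whole scenario.
#' @param h2 Trait heritability (equals the summed QTL variance shares).
#' @param shares Per-QTL shares of phenotypic variance; must sum to `h2`.
#' @param qtl_chroms Chromosome of each planted QTL.
#' @param link Phenotype link passed to [qtl_spec()].
#' @inheritParams simulate_nam
#'
#' @return List with `pop` (the `nam_pop`), `pheno`, `truth`, and
#'   `qtl` (tibble of planted SNPs with chromosome, positions, effect,
#'   variance share).
#' @export
simulate_mqtl_scenario <- function(seed = 1, n_families = 25,
                                   lines_per_family = 52, n_snps = 2000,
                                   h2 = 0.6, shares = c(0.3, 0.2, 0.1),
                                   qtl_chroms = c(1, 3, 5),
                                   link = "identity") {
  stopifnot(length(shares) == length(qtl_chroms))
  if (abs(sum(shares) - h2) > 1e-8) {
    abort("`shares` must sum to `h2` so each QTL keeps its variance share")
  }
  stopifnot_scalar_seed(seed)
  pop <- simulate_nam(n_families = n_families,
                      lines_per_family = lines_per_family, n_snps = n_snps)
  m <- geno_matrix(pop$geno)
  # pick, near the middle of each target chromosome, the SNP with the
  # largest dosage variance (well-segregating, easy to calibrate against)
  qtl_snps <- vapply(qtl_chroms, function(chr) {
    sub <- pop$map[pop$map$chrom == chr, ]
    mid <- sub[abs(sub$pos_cM - stats::median(sub$pos_cM)) <= 25, ]
    v <- apply(m[, mid$snp_id, drop = FALSE], 2, var)
    names(v)[which.max(v)]
  }, character(1))
  vx <- apply(m[, qtl_snps, drop = FALSE], 2, var)
  # Var(y) is normalized to Var(g)/h2; effect_j = sqrt(share_j/Var(x_j))
  # then gives QTL j a variance share of approximately share_j.
  effects <- sqrt(shares / vx)
  spec <- qtl_spec(qtl_snps, effects, h2_target = h2, link = link)
  sim <- simulate_phenotypes(pop$geno, spec)
  qtl_tbl <- dplyr::left_join(
    tibble::tibble(snp_id = qtl_snps, effect = unname(effects),
                   share = shares),
    pop$map, by = "snp_id"
  )
  list(pop = pop, pheno = sim$pheno, truth = sim$truth, qtl = qtl_tbl)
}
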