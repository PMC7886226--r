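fake_detection <- function(detections, models = NULL, n_runs = 100,
                           metabolite = "met_1") {
  structure(
    list(detections = detections, models = models, n_runs = n_runs,
         metabolite = metabolite,
         runs = tibble::tibble(rep = integer(), fold = integer(),
                               r2 = numeric(), model_size = integer(),
                               constant = logical()),
         mean_r2 = NA_real_),
    class = "nam_detection"
  )
}

mbp_map <- function(pos_mbp, chrom = 1L) {
  tibble::tibble(
    snp_id = sprintf("S%d_%02d", chrom, seq_along(pos_mbp)),
    chrom = chrom, pos_bp = as.integer(pos_mbp * 1e6),
    pos_cM = pos_mbp / 4
  )
}

test_that("positional merging groups significant SNPs within the gap", {
  map <- mbp_map(c(14.3, 16.0, 20.2, 40.0, 48.0))
  det <- tibble::tibble(snp_id = map$snp_id,
                        dr = c(30L, 28L, 40L, 26L, 27L),
                        mean_beta = c(0.4, 0.3, 0.5, 0.2, 0.2),
                        n_included = 1L)
  # first three merge (gaps 1.7 and 4.2 Mbp); last two are 8 Mbp apart
  reg <- group_mqtl(fake_detection(det), map, threshold = 25, gap_bp = 5e6)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$start_bp[1], 14300000)
  expect_equal(reg$end_bp[1], 20200000)
  expect_equal(reg$n_snps, c(3L, 1L, 1L))
  expect_equal(reg$peak_snp[1], "S1_03")
  expect_equal(reg$mqtl_id, c("1H-1", "1H-2", "1H-3"))

  # with a date tag the ids carry the sampling-date suffix
  reg2 <- group_mqtl(fake_detection(det), map, threshold = 25, gap_bp = 5e6,
                     date_tag = 2)
  expect_equal(reg2$mqtl_id[1], "1H-1_2")

  # nothing significant -> empty, not an error
  expect_equal(nrow(group_mqtl(fake_detection(det), map, threshold = 99)), 0)
  expect_error(group_mqtl(fake_detection(det), map, threshold = 0), ">= 1")
})

test_that("peak choice breaks DR ties by absolute mean effect", {
  map <- mbp_map(c(1, 2, 3))
  det <- tibble::tibble(snp_id = map$snp_id, dr = c(30L, 30L, 28L),
                        mean_beta = c(0.2, -0.9, 1.5), n_included = 1L)
  reg <- group_mqtl(fake_detection(det), map, threshold = 25)
  expect_equal(reg$peak_snp, "S1_02")
})

test_that("region r2 is the joint OLS coefficient of determination", {
  set.seed(80)
  n <- 400
  m <- matrix(sample(0:2, n * 6, replace = TRUE), n, 6,
              dimnames = list(NULL, sprintf("S1_%02d", 1:6)))
  ibs <- dplyr::bind_cols(
    tibble::tibble(line_id = sprintf("L%03d", 1:n),
                   family_id = rep(c("A", "B"), each = n / 2)),
    tibble::as_tibble(m)
  )
  region <- tibble::tibble(mqtl_id = "1H-1", member_snps = list(c("S1_01")))
  y_exact <- 1 + 0.7 * m[, "S1_01"]
  r <- region_r2(region, ibs, y_exact)
  expect_equal(r$region_r2, 1, tolerance = 1e-12)
  expect_false(r$pruned)

  # adding members never decreases r2; union >= max of the parts
  y <- 0.5 * m[, "S1_01"] + rnorm(n)
  r1 <- region_r2(tibble::tibble(mqtl_id = "a",
                                 member_snps = list("S1_01")), ibs, y)
  r12 <- region_r2(tibble::tibble(mqtl_id = "ab",
                                  member_snps = list(c("S1_01", "S1_02"))),
                   ibs, y)
  r3 <- region_r2(tibble::tibble(mqtl_id = "c",
                                 member_snps = list("S1_03")), ibs, y)
  run <- region_r2(tibble::tibble(
    mqtl_id = "u", member_snps = list(c("S1_01", "S1_03"))), ibs, y)
  expect_gte(r12$region_r2, r1$region_r2)
  expect_gte(run$region_r2, max(r1$region_r2, r3$region_r2))

  # duplicated member is pruned, fit still succeeds
  ibs$S1_06 <- ibs$S1_01
  rp <- region_r2(tibble::tibble(
    mqtl_id = "p", member_snps = list(c("S1_01", "S1_06"))), ibs, y)
  expect_true(rp$pruned)
  expect_equal(rp$region_r2, r1$region_r2, tolerance = 1e-12)

  expect_error(region_r2(tibble::tibble(mqtl_id = "x",
                                        member_snps = list("nope")),
                         ibs, y), "not in IBS")
})

test_that("null region r2 stays near zero at NAM scale", {
  hits <- vapply(1:20, function(s) {
    set.seed(5000 + s)
    n <- 1300
    m <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    ibs <- dplyr::bind_cols(
      tibble::tibble(line_id = as.character(1:n), family_id = "F"),
      tibble::as_tibble(m)
    )
    reg <- tibble::tibble(mqtl_id = "r", member_snps = list(c("a", "b", "c")))
    region_r2(reg, ibs, rnorm(n))$region_r2 <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("family effect cumulation follows the 2-beta segregation rule", {
  # 3 families; SNP q1 segregates only in family F3, q2 only in F1
  ibs <- tibble::tibble(
    line_id = sprintf("L%02d", 1:12),
    family_id = rep(c("F1", "F2", "F3"), each = 4),
    q1 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 1, 0),
    q2 = c(0, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  regions <- tibble::tibble(mqtl_id = c("1H-1", "1H-2"),
                            member_snps = list("q1", "q2"))

  # q1 in all 100 models at beta 0.5 -> F3 gets 1.0, others exactly 0
  models_all <- tidyr::crossing(rep = 1:20, fold = 1:5) |>
    dplyr::mutate(snp_id = "q1", estimate = 0.5)
  fe <- family_effects(fake_detection(NULL, models_all), regions[1, ], ibs)
  expect_equal(fe$effect[fe$family_id == "F3"], 1.0)
  expect_equal(fe$effect[fe$family_id != "F3"], c(0, 0))

  # q2 in 50 of 100 runs at beta 1 -> mean cumulated effect 1.0 for F1
  models_half <- tidyr::crossing(rep = 1:10, fold = 1:5) |>
    dplyr::mutate(snp_id = "q2", estimate = 1)
  fe2 <- family_effects(fake_detection(NULL, models_half), regions[2, ], ibs)
  expect_equal(fe2$effect[fe2$family_id == "F1"], 1.0)
  expect_equal(fe2$effect[fe2$family_id != "F1"], c(0, 0))

  # a member SNP never seen in any model warns and contributes 0
  expect_warning(
    fe3 <- family_effects(fake_detection(NULL, models_all), regions, ibs),
    "never entered"
  )
  expect_equal(fe3$effect[fe3$mqtl_id == "1H-2"], c(0, 0, 0))
})

test_that("family-specific effect signs are recovered from planted multipliers", {
  # Architecture that lets a family-varying QTL be tagged: the causal SNP
  # "c" is polymorphic in both families, flanked in complete linkage by
  # "mA"/"mB" carried only by donor A or donor B. After family-wise
  # recoding, mA and mB are the family-private proxies of the QTL.
  map <- dplyr::bind_rows(
    tibble::tibble(snp_id = c("c", "mA", "mB"), chrom = 1L,
                   pos_bp = 1:3, pos_cM = 0),
    tibble::tibble(snp_id = sprintf("f%02d", 1:20), chrom = 2L,
                   pos_bp = as.integer(seq(1e6, 6e8, length.out = 20)),
                   pos_cM = seq(1e6, 6e8, length.out = 20) / 4e6)
  )
  agree <- vapply(1:10, function(s) {
    set.seed(6000 + s)
    donorA <- c(1L, 1L, 0L, as.integer(runif(20) < 0.5))
    donorB <- c(1L, 0L, 1L, as.integer(runif(20) < 0.5))
    famA <- simulate_bc1s3_family(donorA, integer(23), 60, map, "FA",
                                  seed = 6100 + s)
    famB <- simulate_bc1s3_family(donorB, integer(23), 60, map, "FB",
                                  seed = 6200 + s)
    geno <- dplyr::bind_rows(family_calls(famA), family_calls(famB))
    sim <- simulate_phenotypes(
      geno,
      qtl_spec("c", 1.2, family_multiplier = matrix(c(1, -1), 1,
                                                    dimnames = list(NULL, c("FA", "FB"))),
               h2_target = 0.8),
      seed = 6500 + s
    )
    ibs <- impute_mni(code_ibs(geno, marker_qc(geno)))
    plan <- make_folds(ibs, k = 5, n_reps = 2, seed = 6900 + s)
    det <- cross_validate(ibs, sim$pheno, "met_1", plan)
    reg <- group_mqtl(det, map, threshold = round(0.5 * det$n_runs))
    reg <- reg[reg$chrom == 1, ]
    if (nrow(reg) == 0) return(NA)
    fe <- family_effects(det, reg[1, ], ibs)
    # oracle: the planted multipliers say FA responds +, FB responds -
    fe$effect[fe$family_id == "FA"] > 0 && fe$effect[fe$family_id == "FB"] < 0
  }, logical(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.9)
  expect_gte(sum(!is.na(agree)), 8)
})

test_that("report bundles round-trip and tolerate empty regions", {
  pop <- small_pop(seed = 71, n_families = 2, lines_per_family = 12,
                   n_snps = 30)
  ibs <- impute_mni(code_ibs(pop$geno, marker_qc(pop$geno)))
  m <- as.matrix(ibs[-(1:2)])
  y <- 1.5 * m[, 3] + rnorm(nrow(m), sd = 0.4)
  plan <- make_folds(ibs, k = 4, n_reps = 2, seed = 72)
  det <- cross_validate(ibs, y, plan = plan)
  reg <- group_mqtl(det, pop$map, threshold = 2)
  reg <- region_r2(reg, ibs, y)
  fe <- if (nrow(reg)) family_effects(det, reg, ibs) else NULL

  dir <- withr::local_tempdir()
  paths <- write_mqtl_report(det, pop$map, dir, threshold = 2, regions = reg,
                             family_effects = fe,
                             config = list(k = 4, n_reps = 2, seed = 72))
  expect_true(all(file.exists(paths)))
  bundle <- read_mqtl_report(dir)
  expect_equal(bundle$manhattan$dr[order(bundle$manhattan$snp_id)],
               det$detections$dr[order(det$detections$snp_id)])
  expect_equal(nrow(bundle$mqtl_summary), nrow(reg))
  expect_equal(bundle$metadata$n_runs, det$n_runs)
  expect_equal(names(bundle$manhattan),
               c("snp_id", "chrom", "pos_bp", "dr", "mean_beta",
                 "significant"))

  # empty regions still produce a valid, readable bundle
  empty <- group_mqtl(det, pop$map, threshold = 99)
  dir2 <- withr::local_tempdir()
  write_mqtl_report(det, pop$map, dir2, threshold = 99,
                    regions = region_r2(empty, ibs, y))
  bundle2 <- read_mqtl_report(dir2)
  expect_equal(nrow(bundle2$mqtl_summary), 0)
})
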