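# Hand-built 6-line, 4-SNP toy used across the QC tests:
#   mono  : hom recurrent everywhere            -> fails polymorphism
#   miss  : 1/6 missing (16.7% >= 10%)          -> fails failure rate
#   hetty : 2/6 heterozygous (33% >= 12.5%)     -> fails het rate
#   clean : polymorphic, complete, no hets      -> passes
toy_calls <- function() {
  tibble::tibble(
    line_id = paste0("L", 1:6),
    family_id = rep(c("F1", "F2"), each = 3),
    mono = c(0L, 0L, 0L, 0L, 0L, 0L),
    miss = c(0L, 2L, 0L, NA, 2L, 0L),
    hetty = c(0L, 1L, 2L, 0L, 1L, 2L),
    clean = c(0L, 2L, 0L, 2L, 0L, 2L)
  )
}

test_that("marker QC applies the three chip rules with strict boundaries", {
  qc <- marker_qc(toy_calls())
  expect_equal(qc$pass, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(qc$snp_id[qc$pass], "clean")
  expect_false(qc$polymorphic_in_any_family[qc$snp_id == "mono"])
  expect_equal(qc$failure_rate[qc$snp_id == "miss"], 1 / 6)
  expect_equal(qc$het_rate[qc$snp_id == "hetty"], 2 / 6)

  # exactly-at-threshold markers fail ("< 10%", "< 12.5%" strictly)
  ten <- tibble::tibble(
    line_id = paste0("L", 1:10), family_id = rep(c("A", "B"), each = 5),
    at_fail = c(NA, rep(c(0L, 2L), length.out = 9)),
    below_fail = rep(c(0L, 2L), 5)
  )
  qc10 <- marker_qc(ten)
  expect_false(qc10$pass[qc10$snp_id == "at_fail"])     # 10% missing
  expect_true(qc10$pass[qc10$snp_id == "below_fail"])

  eight <- tibble::tibble(
    line_id = paste0("L", 1:8), family_id = rep(c("A", "B"), each = 4),
    at_het = c(1L, rep(c(0L, 2L), length.out = 7)),
    no_het = rep(c(0L, 2L), 4)
  )
  qc8 <- marker_qc(eight)
  expect_equal(qc8$het_rate[qc8$snp_id == "at_het"], 0.125)
  expect_false(qc8$pass[qc8$snp_id == "at_het"])        # 12.5% het
  expect_true(qc8$pass[qc8$snp_id == "no_het"])
})

test_that("marker QC is invariant to line and SNP permutations", {
  pop <- small_pop(seed = 55)
  calls <- pop$geno
  calls[[20]][c(3, 9)] <- NA
  qc <- marker_qc(calls)
  set.seed(1)
  rows <- sample(nrow(calls))
  cols <- c(1:2, sample(3:ncol(calls)))
  qc_perm <- marker_qc(calls[rows, cols])
  expect_equal(qc_perm[match(qc$snp_id, qc_perm$snp_id), ], qc,
               ignore_attr = TRUE)
})

test_that("IBS coding maps states and recodes family-monomorphic SNPs to 0", {
  calls <- tibble::tibble(
    line_id = paste0("L", 1:6),
    family_id = rep(c("F1", "F2"), each = 3),
    s1 = c(2L, 2L, 2L, 0L, 1L, 2L),   # F1 all hom donor, F2 polymorphic
    s2 = c(0L, 2L, 1L, 0L, 2L, 1L)    # both families polymorphic
  )
  ibs <- code_ibs(calls, marker_qc(calls, het_max = 0.5))
  # F1 monomorphic (all hom donor) at s1 -> recoded to 0 despite raw code 2
  expect_equal(ibs$s1, c(0, 0, 0, 0, 1, 2))
  expect_equal(ibs$s2, c(0, 2, 1, 0, 2, 1))
  rec <- attr(ibs, "recoded")
  expect_equal(rec$snp_id, "s1")
  expect_equal(rec$family_id, "F1")

  # all families polymorphic, nothing missing: plain 0/1/2, idempotent
  ibs2 <- code_ibs(ibs |> dplyr::mutate(dplyr::across(c(s1, s2), as.integer)),
                   marker_qc(calls, het_max = 0.5))
  expect_equal(ibs2$s2, ibs$s2)
})

test_that("family-monomorphic scoring invariant holds on simulated data", {
  pop <- small_pop(seed = 77)
  qc <- marker_qc(pop$geno)
  ibs <- code_ibs(pop$geno, qc)
  m <- as.matrix(ibs[-(1:2)])
  dos <- as.matrix(pop$geno[match(ibs$line_id, pop$geno$line_id),
                            colnames(m)])
  rec <- attr(ibs, "recoded")
  for (f in unique(ibs$family_id)) {
    rows <- ibs$family_id == f
    mono_snps <- rec$snp_id[rec$family_id == f]
    if (length(mono_snps)) {
      expect_true(all(m[rows, mono_snps] == 0))
    }
    # everywhere else IBS equals the donor-allele dosage
    other <- setdiff(colnames(m), mono_snps)
    expect_equal(m[rows, other], dos[rows, other], ignore_attr = TRUE)
  }
})

test_that("mean imputation fills with column means and preserves them", {
  ibs <- tibble::tibble(
    line_id = paste0("L", 1:4), family_id = "F1",
    a = c(0, 2, NA, 2), b = c(0, 0, 0, NA)
  )
  out <- impute_mni(ibs)
  expect_equal(out$a, c(0, 2, 4 / 3, 2))
  expect_equal(out$b, rep(0, 4))
  expect_true(all(!is.na(as.matrix(out[-(1:2)]))))
  expect_equal(which(attr(out, "imputed"), arr.ind = TRUE)[, "col"],
               c(1L, 2L), ignore_attr = TRUE)

  # column [0, 2, missing] -> 1.0
  one <- impute_mni(tibble::tibble(line_id = c("a", "b", "c"),
                                   family_id = "F", s = c(0, 2, NA)))
  expect_equal(one$s[3], 1.0)

  expect_error(
    impute_mni(tibble::tibble(line_id = c("a", "b"), family_id = "F",
                              s = c(NA_real_, NA_real_))),
    "entirely missing"
  )
})

test_that("imputation preserves column means on a large sparse pattern", {
  set.seed(5)
  n <- 1000
  m <- matrix(sample(0:2, n * 200, replace = TRUE), n, 200,
              dimnames = list(NULL, sprintf("s%03d", 1:200)))
  holes <- sample(length(m), round(0.0084 * length(m)))
  pre_means <- colMeans(`[<-`(m, holes, NA), na.rm = TRUE)
  tbl <- dplyr::bind_cols(
    tibble::tibble(line_id = sprintf("L%04d", 1:n), family_id = "F1"),
    tibble::as_tibble(`[<-`(m, holes, NA))
  )
  out <- impute_mni(tbl)
  expect_equal(colMeans(as.matrix(out[-(1:2)])), pre_means,
               tolerance = 1e-12)
})

test_that("coding and imputation leave families without missing data unchanged", {
  pop <- small_pop(seed = 88)
  calls <- pop$geno
  # missingness only in family 1
  f1_rows <- which(calls$family_id == calls$family_id[1])
  calls[[5]][f1_rows[1:3]] <- NA
  full <- impute_mni(code_ibs(calls, marker_qc(calls)))
  keep_fams <- setdiff(unique(calls$family_id), calls$family_id[1])
  dropped <- calls[calls$family_id %in% keep_fams, ]
  sub <- impute_mni(code_ibs(dropped, marker_qc(dropped)))
  shared <- intersect(names(sub), names(full))
  common_pass <- setdiff(shared, c("line_id", "family_id"))
  # scores of unaffected families agree wherever neither run recoded
  rec_all <- dplyr::bind_rows(attr(full, "recoded"), attr(sub, "recoded"))
  for (f in keep_fams) {
    snps <- setdiff(common_pass, rec_all$snp_id[rec_all$family_id == f])
    expect_equal(
      as.matrix(full[full$family_id == f, snps]),
      as.matrix(sub[sub$family_id == f, snps]),
      ignore_attr = TRUE
    )
  }
})

test_that("call/geno/map readers and writers round-trip", {
  dir <- withr::local_tempdir()
  pop <- small_pop(seed = 61, n_families = 2, lines_per_family = 5,
                   n_snps = 10)
  gpath <- file.path(dir, "geno.tsv")
  write_geno_tsv(pop$geno, gpath)
  back <- read_geno_tsv(gpath)
  expect_equal(as.data.frame(back), as.data.frame(pop$geno))

  mpath <- file.path(dir, "map.tsv")
  write_map_tsv(pop$map, mpath)
  expect_equal(as.data.frame(read_map_tsv(mpath)), as.data.frame(pop$map))

  # A/H/B coded calls
  code <- c("A", "H", "B")
  chr <- pop$geno
  for (nm in names(chr)[-(1:2)]) chr[[nm]] <- code[chr[[nm]] + 1L]
  chr[[3]][2] <- NA
  cpath <- file.path(dir, "calls.tsv")
  readr::write_tsv(chr, cpath, na = "NA")
  calls <- read_calls_tsv(cpath)
  expect_equal(calls[[3]][2], NA_integer_)
  expect_equal(calls[[4]], pop$geno[[4]])
})

test_that("PLINK .raw importer extracts dosages and ids", {
  dir <- withr::local_tempdir()
  raw <- data.frame(
    FID = c("F1", "F1", "F2"), IID = c("L1", "L2", "L3"),
    PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
    snpA_A = c(0, 1, 2), snpB_G = c(2, NA, 0)
  )
  p <- file.path(dir, "geno.raw")
  write.table(raw, p, row.names = FALSE, quote = FALSE)
  out <- read_plink_raw(p)
  expect_equal(names(out), c("line_id", "family_id", "snpA", "snpB"))
  expect_equal(out$snpB, c(2L, NA, 0L))
  expect_equal(out$family_id, c("F1", "F1", "F2"))
})
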