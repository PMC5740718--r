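test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(0, 0), "zero pairs")
  expect_error(cohort_config(age_range = c(70, 60)), "min < max")
  expect_error(cohort_config(followup_years = c(15, 9.6, 13.4)), "within")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("generate_cohort honours the MZ constraints and the stated world", {
  coh <- generate_cohort(cohort_config(seed = 3))
  # default cohort: 86 male + 83 female pairs, two rows per pair
  expect_equal(length(unique(coh$pair_id)), 169)
  by_pair_sex <- tapply(coh$sex, coh$pair_id, unique)
  expect_equal(sum(sapply(split(coh$sex, coh$pair_id), unique) == "male") , 86)
  expect_equal(sum(sapply(split(coh$sex, coh$pair_id), unique) == "female"), 83)
  # within-pair sex identical, age difference exactly 0
  expect_true(all(sapply(split(coh$sex, coh$pair_id), function(s) length(unique(s)) == 1)))
  expect_true(all(sapply(split(coh$age_followup, coh$pair_id), function(a) diff(a) == 0)))
  # follow-up gap inside the configured window
  expect_true(all(coh$followup_years > 9.6 & coh$followup_years < 13.4))
  expect_true(all(coh$age_followup >= 56 & coh$age_followup <= 79))
  # quit < 2 years => current smoker
  smokers <- coh[coh$pack_years_total > 0, ]
  expect_true(all(smokers$smoking_status[smokers$quit_years_ago < 2] == "current"))
  expect_true(all(smokers$smoking_status[smokers$quit_years_ago >= 2] == "non-current"))
  expect_true(all(coh$smoking_status[coh$pack_years_total == 0] == "never"))
  # determinism: same seed twice is byte-identical
  expect_identical(coh, generate_cohort(cohort_config(seed = 3)))
  # different seed differs
  expect_false(identical(coh$fev1_followup,
                         generate_cohort(cohort_config(seed = 4))$fev1_followup))
})

test_that("cohort distributions sit near the stated demographic centres", {
  # pair-level gamma draws make single-cohort means noisy (MC SE ~ 3
  # pack-years): average three seeds and allow ~3 SE
  cohorts <- lapply(10:12, function(s) generate_cohort(cohort_config(seed = s)))
  m <- do.call(rbind, lapply(cohorts, function(c) c[c$sex == "male", ]))
  f <- do.call(rbind, lapply(cohorts, function(c) c[c$sex == "female", ]))
  expect_lt(abs(median(m$height_followup_cm) - 174), 2.5)
  expect_lt(abs(median(f$height_followup_cm) - 161.9), 2.5)
  expect_lt(abs(mean(m$pack_years_total) - 20.8), 6)
  expect_lt(abs(mean(f$pack_years_total) - 7.3), 3)
  # pack-years heavily right-skewed (zero-inflated gamma)
  expect_gt(mean(m$pack_years_total == 0), 0.15)
  expect_gt(sd(m$pack_years_total), mean(m$pack_years_total) * 0.8)
})

test_that("smoking_discordance = 0 yields concordant pack-years", {
  coh <- generate_cohort(cohort_config(
    smoking_discordance = c(male = 0, female = 0), seed = 5))
  d <- sapply(split(coh$pack_years_total, coh$pair_id), function(x) abs(diff(x)))
  expect_equal(unname(max(d)), 0)
})

test_that("generate_lms_table is smooth, positive and round-trips through TSV", {
  tab <- generate_lms_table()
  expect_true(all(tab$S > 0))
  expect_true(all(tab$M > 0))
  # M decreasing in age for every stratum
  for (key in split(tab, list(tab$metric, tab$sex))) {
    expect_true(all(diff(key$M) < 0))
  }
  expect_error(generate_lms_table(age_grid = c(50, 40)), "increasing")
  # single-age grid: constant coefficients returned everywhere in range
  one <- generate_lms_table(age_grid = 60)
  cf <- interpolate_lms(one, "FEV1", "male", 60, 176)
  expect_equal(nrow(one[one$metric == "FEV1" & one$sex == "male", ]), 1)
  expect_equal(cf$M, one$M[one$metric == "FEV1" & one$sex == "male"])
  # TSV round trip reproduces L/M/S at grid points
  path <- tempfile(fileext = ".tsv")
  write_lms_table(tab, path)
  back <- read_lms_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(attr(back, "meta"), attr(tab, "meta"), tolerance = 1e-12)
  # jittered variant still enforces S > 0
  expect_true(all(generate_lms_table(jitter = 0.05, seed = 2)$S > 0))
})

test_that("generate_manifest produces unique annotated probes at the NA rate", {
  expect_error(generate_manifest(100, 10, na_fraction = 1), "na_fraction")
  expect_error(generate_manifest(100, 0, na_fraction = 0.2), "n_genes")
  man <- generate_manifest(1000, 200, na_fraction = 0.2, seed = 9)
  expect_equal(anyDuplicated(man$probe_id), 0)
  n_na <- sum(is.na(man$gene))
  ci <- 2.576 * sqrt(1000 * 0.2 * 0.8)
  expect_lt(abs(n_na - 200), ci)
  # intergenic probes carry the IGR context
  expect_true(all(grepl("^IGR-", man$cgi_feature[is.na(man$gene)])))
  expect_false(any(grepl("^IGR-", man$cgi_feature[!is.na(man$gene)])))
  expect_true(all(man$cgi_feature %in% as.vector(outer(
    c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR", "IGR"),
    c("island", "shore", "shelf", "open sea"), paste, sep = "-"))))
})

test_that("generate_cell_panel emits a valid, bimodal, distinct panel", {
  man <- generate_manifest(400, 100, seed = 2)
  panel <- generate_cell_panel(man, seed = 2)
  expect_s3_class(panel, "cell_reference_panel")
  expect_true(all(panel$reference_betas >= 0 & panel$reference_betas <= 1))
  # bimodality: most baseline betas near 0 or 1
  mid <- rowMeans(panel$reference_betas)
  expect_gt(mean(mid < 0.3 | mid > 0.7), 0.5)
  # columns pairwise distinct
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(mean(abs(panel$reference_betas[, i] - panel$reference_betas[, j])), 0)
  }
})

test_that("generate_methylomes respects clipping, determinism and planting rules", {
  coh <- small_cohort(6, 6, seed = 8)
  man <- generate_manifest(80, 30, seed = 8)
  panel <- generate_cell_panel(man, seed = 8)
  meth <- generate_methylomes(coh, panel, man, seed = 8)
  beta <- meth$dataset$beta
  expect_true(all(beta > 0 & beta < 1))
  expect_equal(dim(beta), c(80, 24))
  expect_true(all(abs(rowSums(as.matrix(meth$cell_fractions[, -1])) - 1) < 1e-9))
  # null dataset carries no planted truth
  expect_equal(nrow(meth$truth), 0)
  # determinism
  meth2 <- generate_methylomes(coh, panel, man, seed = 8)
  expect_identical(meth$dataset$beta, meth2$dataset$beta)
  expect_identical(meth$dataset$detection_p, meth2$dataset$detection_p)
  # planted probe absent from manifest errors with its name
  expect_error(
    generate_methylomes(coh, panel, man,
                        planted = list(planted_effect("cgNOPE", "zFEV1", -0.1))),
    "cgNOPE")
})

test_that("within-pair M correlation increases with pair_correlation", {
  coh <- small_cohort(20, 20, seed = 13)
  man <- generate_manifest(150, 50, seed = 13)
  panel <- generate_cell_panel(man, seed = 13)
  cors <- sapply(c(0.1, 0.5, 0.9), function(rho) {
    meth <- generate_methylomes(coh, panel, man, pair_correlation = rho,
                                bad_probe_fraction = 0, seed = 13)
    M <- beta_to_m(meth$dataset$beta)
    M <- M - rowMeans(M)
    t1 <- M[, coh$subject_id[coh$twin == 1]]
    t2 <- M[, coh$subject_id[coh$twin == 2]]
    cor(as.vector(t1), as.vector(t2))
  })
  expect_true(all(diff(cors) > 0))
})

test_that("planted associations surface in the EWAS at the planted strength", {
  coh <- generate_cohort(cohort_config(n_male_pairs = 40, n_female_pairs = 40,
                                       seed = 17))
  man <- generate_manifest(120, 40, seed = 17)
  panel <- generate_cell_panel(man, seed = 17)
  planted <- list(planted_effect(man$probe_id[10], "zFEV1", -0.6, noise_sd = 0.05))
  meth <- generate_methylomes(coh, panel, man, planted = planted,
                              bad_probe_fraction = 0, seed = 17)
  zp <- standardize_cohort(coh, attr(coh, "lms"))
  design <- build_pair_design(coh, zp, meth$cell_fractions, "zFEV1")
  dm <- difference_methylation(beta_to_m(meth$dataset$beta), design)
  run <- run_ewas(dm, design)
  row <- run$results[run$results$probe == man$probe_id[10], ]
  expect_lt(row$p, 1e-10)
  expect_equal(row$estimate, -0.6, tolerance = 0.1)
  expect_equal(row$direction, "Hyper")
})
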