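random_design_matrix <- function(n, p_cov, seed) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, predictor = rnorm(n))
  if (p_cov > 0) {
    X <- cbind(X, matrix(rnorm(n * p_cov), n, p_cov,
                         dimnames = list(NULL, paste0("c", seq_len(p_cov)))))
  }
  X
}

test_that("fit_probe agrees with the normal-equations oracle on random instances", {
  for (i in 1:100) {
    n <- sample(15:40, 1)
    p_cov <- sample(0:4, 1)
    X <- random_design_matrix(n, p_cov, seed = 1000 + i)
    y <- rnorm(n, sd = runif(1, 0.5, 2))
    got <- fit_probe(y, X)
    want <- ols_oracle(y, X)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("fit_probe handles exact fits and rejects bad designs", {
  X <- cbind(`(Intercept)` = 1, predictor = seq(-1, 1, length.out = 20))
  expect_warning(fit <- fit_probe(2 * X[, 2], X), "zero-residual")
  expect_equal(fit$estimate, 2)
  expect_equal(fit$p, 0)
  # rank-deficient design names the collinear column
  Xc <- cbind(X, dup = X[, "predictor"])
  expect_error(fit_probe(rnorm(20), Xc), "dup")
  # too few pairs
  expect_error(fit_probe(rnorm(2), X[1:2, ]), "at least")
  expect_error(fit_probe(rnorm(5), X), "does not match")
})

test_that("permutation null: predictor carries no signal in ~5% of probes at 0.05", {
  set.seed(77)
  n <- 50
  X <- random_design_matrix(n, 2, seed = 99)
  p <- replicate(2000, fit_probe(rnorm(n), X)$p)
  frac <- mean(p < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), ci + 1e-12)
})

test_that("bh_adjust equals the closed form and the brute-force oracle", {
  expect_equal(bh_adjust(c(1e-4, 0.02, 0.9)), c(3e-4, 0.03, 0.9))
  p <- rep(0.2, 7)
  expect_equal(bh_adjust(p), p)  # all equal => adj = p * n/n
  # randomized suite against the double-loop oracle, lengths <= 50
  set.seed(4)
  for (i in 1:60) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
    n_big <- m + sample(0:1000, 1)
    expect_equal(bh_adjust(p, n_tests = n_big), bh_oracle(p, n_tests = n_big))
    # monotone along sorted p, bounded by 1
    adj <- bh_adjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_adjust(runif(10), n_tests = 5), ">=")
})

test_that("genomic_inflation follows the median chi-square convention", {
  expect_equal(genomic_inflation(0.5), 1)
  set.seed(6)
  expect_lt(abs(genomic_inflation(runif(1e5)) - 1), 0.02)
  expect_gt(genomic_inflation(rep(1e-8, 10)), 10)
  expect_error(genomic_inflation(numeric(0)), "non-empty")
})

test_that("direction labels follow the inferior-twin convention", {
  expect_equal(classify_direction(-0.054), "Hyper")
  expect_equal(classify_direction(0.0617), "Hypo")
  expect_warning(d <- classify_direction(0), "undefined")
  expect_true(is.na(d))
  expect_equal(classify_direction(c(-1, 2)), c("Hyper", "Hypo"))
})

test_that("select_hits applies strict thresholds with significant within table", {
  res <- data.frame(probe = paste0("cg", 1:4),
                    p = c(9.9e-7, 5e-6, 1e-5, 0.2),
                    estimate = 1, se = 1, t = 1, fdr = 1, direction = "Hypo",
                    n_pairs = 10, metric = "zFEV1", flavour = "cross-sectional",
                    stringsAsFactors = FALSE)
  run <- structure(list(results = res, n_tests = 4, lambda = 1,
                        thresholds = c(significant = 1e-6, table = 1e-5)),
                   class = "ewas_run")
  hits <- select_hits(run)
  expect_equal(hits$significant$probe, "cg1")
  expect_equal(hits$table$probe, c("cg1", "cg2"))  # 1e-5 exactly is excluded
  expect_true(all(hits$significant$probe %in% hits$table$probe))
})

test_that("run_ewas matches probe-wise fit_probe and is row-order invariant", {
  coh <- small_cohort(12, 12, seed = 14)
  zp <- standardize_cohort(coh, attr(coh, "lms"))
  set.seed(2)
  cf <- data.frame(sample_id = coh$subject_id,
                   t(apply(matrix(rgamma(nrow(coh) * 5, 5), ncol = 5), 1,
                           function(w) w / sum(w))), stringsAsFactors = FALSE)
  names(cf)[-1] <- blood_cell_types()
  design <- build_pair_design(coh, zp, cf, "zFEV1")
  dm <- matrix(rnorm(30 * nrow(design), sd = 0.2), 30,
               dimnames = list(sprintf("cg%03d", 1:30), design$pair_id))
  run <- run_ewas(dm, design)
  expect_equal(run$n_tests, 30)
  X <- design_matrix(design)
  for (i in c(1, 17, 30)) {
    ref <- fit_probe(dm[i, ], X)
    expect_equal(run$results$estimate[i], ref$estimate, tolerance = 1e-10)
    expect_equal(run$results$p[i], ref$p, tolerance = 1e-10)
  }
  # fdr column is BH over all tested probes
  expect_equal(run$results$fdr, bh_oracle(run$results$p))
  # permuting matrix rows permutes results identically
  perm <- sample(30)
  run2 <- run_ewas(dm[perm, ], design)
  expect_equal(run2$results$probe, run$results$probe[perm])
  expect_equal(run2$results$p, run$results$p[perm])
  expect_equal(run2$lambda, run$lambda)
  # misaligned pair ids error
  dm_bad <- dm; colnames(dm_bad) <- rev(colnames(dm))
  expect_error(run_ewas(dm_bad, design), "align")
})

test_that("annotate_hits is a pure idempotent join preserving NA genes", {
  man <- data.frame(probe_id = c("cg1", "cg2"), chromosome = c("5", "12"),
                    bp = c(100L, 200L), gene = c(NA, "GLI1"),
                    cgi_feature = c("IGR-shore", "Body-island"),
                    stringsAsFactors = FALSE)
  rows <- data.frame(probe = c("cg2", "cg1"), p = c(1e-7, 1e-6),
                     stringsAsFactors = FALSE)
  ann <- annotate_hits(rows, man)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$gene, c("GLI1", NA))
  expect_equal(ann$cgi_feature, c("Body-island", "IGR-shore"))
  expect_equal(annotate_hits(ann, man), ann)
  expect_error(annotate_hits(data.frame(probe = "cgX"), man), "cgX")
})

test_that("manhattan and qq tables follow the plotting conventions", {
  coh <- small_cohort(8, 8, seed = 31)
  zp <- standardize_cohort(coh, attr(coh, "lms"))
  set.seed(3)
  cf <- data.frame(sample_id = coh$subject_id,
                   t(apply(matrix(rgamma(nrow(coh) * 5, 5), ncol = 5), 1,
                           function(w) w / sum(w))), stringsAsFactors = FALSE)
  names(cf)[-1] <- blood_cell_types()
  design <- build_pair_design(coh, zp, cf, "zFVC")
  man <- generate_manifest(25, 10, seed = 2)
  dm <- matrix(rnorm(25 * nrow(design), sd = 0.2), 25,
               dimnames = list(man$probe_id, design$pair_id))
  run <- run_ewas(dm, design)
  tabs <- manhattan_qq_tables(run, man)
  expect_equal(nrow(tabs$manhattan), run$n_tests)
  # genome-sorted
  o <- order(as.integer(tabs$manhattan$chromosome), tabs$manhattan$bp)
  expect_equal(o, seq_len(25))
  # expected quantiles -log10((i - 0.5)/n), monotone decreasing
  expect_equal(tabs$qq$expected, -log10((seq_len(25) - 0.5) / 25))
  expect_true(all(diff(tabs$qq$expected) < 0))
  expect_true(all(diff(tabs$qq$observed) <= 0))
})
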