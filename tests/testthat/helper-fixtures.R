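# Shared fixtures, all built in code.

tiny_lms <- function() {
  grid <- expand.grid(metric = c("FEV1", "FVC", "FEV1/FVC"),
                      sex = c("male", "female"), age = c(40, 60, 80),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$metric, grid$sex, grid$age), ]
  grid$L <- 1
  # ratio median constant and equal to M_FEV1 / M_FVC so a subject on all
  # volume medians is also on the ratio median
  grid$M <- ifelse(grid$metric == "FEV1/FVC", 3.5 / 4.5,
                   ifelse(grid$metric == "FEV1", 3.5, 4.5) *
                     (1 - 0.004 * (grid$age - 40)))
  grid$S <- 0.1
  meta <- expand.grid(metric = c("FEV1", "FVC", "FEV1/FVC"),
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  meta$reference_height_cm <- ifelse(meta$sex == "male", 176, 163)
  meta$height_exponent <- ifelse(meta$metric == "FEV1/FVC", 0, 2)
  lms_table(grid, meta)
}

small_cohort <- function(n_male = 8, n_female = 8, seed = 11) {
  generate_cohort(cohort_config(n_male_pairs = n_male, n_female_pairs = n_female,
                                seed = seed))
}

# 20-probe QC fixture with scripted failures over 100 samples.
# Hand enumeration of the expected removal set:
#   qp01 bead < 3 in 6 samples          -> removed (failed fraction 6%)
#   qp02 detection p > 0.01 in 6        -> removed
#   qp03 beta NA in 6                   -> removed (zero signal)
#   qp04 bead < 3 in exactly 5          -> retained (5% not > 5%)
#   qp05 2 bead + 2 detp + 2 NA         -> removed (6 distinct failures)
#   qp06 bead & detp fail in SAME 3     -> retained (3 failed measurements)
#   qp07 clean but blacklisted          -> removed (blacklist)
#   qp08 blacklisted AND 10% failed     -> removed, attributed to blacklist
#   qp09 beta == 0 with bead 0 in 6     -> removed (zero signal)
#   qp10 beta == 0 with healthy bead, 6 -> retained (not zero signal)
#   qp11..qp20 clean                    -> retained
qc_fixture <- function() {
  n <- 100
  probes <- sprintf("qp%02d", 1:20)
  samples <- sprintf("s%03d", 1:n)
  beta <- matrix(0.5, 20, n, dimnames = list(probes, samples))
  detp <- matrix(0.001, 20, n, dimnames = list(probes, samples))
  bead <- matrix(10L, 20, n, dimnames = list(probes, samples))
  bead["qp01", 1:6] <- 2L
  detp["qp02", 1:6] <- 0.02
  beta["qp03", 1:6] <- NA
  bead["qp04", 1:5] <- 0L
  bead["qp05", 1:2] <- 1L; detp["qp05", 3:4] <- 0.5; beta["qp05", 5:6] <- NA
  bead["qp06", 1:3] <- 2L; detp["qp06", 1:3] <- 0.9
  bead["qp08", 1:10] <- 0L
  beta["qp09", 1:6] <- 0; bead["qp09", 1:6] <- 0L
  beta["qp10", 1:6] <- 0
  manifest <- data.frame(probe_id = probes, chromosome = "1",
                         bp = seq_len(20) * 1000L, gene = "GENE1",
                         cgi_feature = "Body-shore", stringsAsFactors = FALSE)
  methylation_dataset(beta, detp, bead, manifest,
                      blacklist = c("qp07", "qp08"))
}

qc_expected_removed <- c("qp01", "qp02", "qp03", "qp05", "qp07", "qp08", "qp09")

# distinguishable 5-column reference panel on an interior beta range
toy_panel <- function(n_probes = 60, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(n_probes * 5, 0.1, 0.9), n_probes, 5,
              dimnames = list(sprintf("pp%03d", 1:n_probes), NULL))
  cell_reference_panel(m)
}
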