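#' Configuration for the synthetic twin cohort
#'
#' Defaults emulate the study cohort the pipeline is designed for: 86 male
#' and 83 female monozygotic pairs, follow-up ages 56-79 with a median near
#' 66, an ~11-year follow-up gap drawn uniformly in (9.6, 13.4) years, and
#' heavily skewed smoking histories (zero-inflated gamma pack-years;
#' among smoking-discordant pairs the mean within-pair pack-year difference
#' is ~14 for males and ~8 for females).
#'
#' @param n_male_pairs,n_female_pairs Pair counts (> 0).
#' @param age_range Follow-up age range in years, `c(min, max)`.
#' @param followup_years `c(mean, min, max)` follow-up gap in years; the
#'   gap is drawn uniformly in (min, max).
#' @param smoking_discordance Named mean within-pair pack-year difference
#'   among discordant pairs, `c(male = , female = )`; 0 forces concordant
#'   smoking histories.
#' @param seed Integer seed; every random draw flows from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_male_pairs = 86, n_female_pairs = 83,
                          age_range = c(56, 79),
                          followup_years = c(mean = 11.0, min = 9.6, max = 13.4),
                          smoking_discordance = c(male = 14, female = 8),
                          seed = 1L) {
  if (n_male_pairs + n_female_pairs <= 0) stop("zero pairs requested", call. = FALSE)
  if (n_male_pairs < 0 || n_female_pairs < 0) stop("pair counts must be >= 0", call. = FALSE)
  if (age_range[1] >= age_range[2]) stop("age_range must satisfy min < max", call. = FALSE)
  fu <- unname(followup_years)
  if (!(fu[1] > fu[2] && fu[1] < fu[3])) {
    stop("followup mean must lie within (min, max)", call. = FALSE)
  }
  if (any(smoking_discordance < 0)) stop("smoking_discordance must be >= 0", call. = FALSE)
  structure(list(n_male_pairs = as.integer(n_male_pairs),
                 n_female_pairs = as.integer(n_female_pairs),
                 age_range = age_range, followup_years = fu,
                 smoking_discordance = smoking_discordance,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# distribution centres per sex (height cm, weight kg, pack-year model)
.sex_params <- list(
  # py_mean is the smoking-pair gamma mean, chosen so the zero-inflated
  # marginal mean lands on the published 20.8 (M) / 7.3 (F) pack-years
  male = list(height_mean = 174.0, height_sd = 6.5, weight_mean = 81.9,
              weight_sd = 11, p_never_pair = 0.35, py_mean = 32, py_shape = 1.1,
              disc_fraction = 0.6),
  female = list(height_mean = 161.9, height_sd = 6.0, weight_mean = 67.7,
                weight_sd = 11, p_never_pair = 0.55, py_mean = 16, py_shape = 1.1,
                disc_fraction = 0.6)
)

#' Default synthetic LMS reference table
#'
#' Smooth parametric L/M/S curves over an age grid, with the structure of
#' published spirometry reference equations (M decays with age, scales with
#' height to a per-metric power; S grows slowly with age; S > 0, M > 0
#' everywhere). Coefficients are synthetic stand-ins — a real coefficient
#' table in the same TSV format can be dropped in.
#'
#' @param metrics Measures to tabulate.
#' @param sexes Sex strata.
#' @param age_grid Strictly increasing ages in years.
#' @param jitter Optional SD of multiplicative jitter on M (default 0,
#'   deterministic); S positivity is enforced regardless.
#' @param seed Seed used only when `jitter > 0`.
#' @return An [lms_table()].
#' @export
generate_lms_table <- function(metrics = c("FEV1", "FVC", "FEV1/FVC"),
                               sexes = c("male", "female"),
                               age_grid = seq(40, 85, by = 5),
                               jitter = 0, seed = 1L) {
  if (is.unsorted(age_grid, strictly = TRUE)) {
    stop("age grid must be strictly increasing", call. = FALSE)
  }
  pars <- list(
    "FEV1" = list(male = c(M0 = 4.35), female = c(M0 = 3.15),
                  decay = 0.013, S0 = 0.115, Sslope = 9e-4, L0 = 1.0,
                  Lslope = 2e-3, hexp = 2.0,
                  ref_h = c(male = 176, female = 163)),
    "FVC" = list(male = c(M0 = 5.40), female = c(M0 = 3.95),
                 decay = 0.010, S0 = 0.112, Sslope = 8e-4, L0 = 0.95,
                 Lslope = 2e-3, hexp = 2.1,
                 ref_h = c(male = 176, female = 163)),
    "FEV1/FVC" = list(male = c(M0 = 0.790), female = c(M0 = 0.806),
                      decay = 0.0016, S0 = 0.055, Sslope = 3e-4, L0 = 1.2,
                      Lslope = 0, hexp = 0,
                      ref_h = c(male = 176, female = 163))
  )
  unknown <- setdiff(metrics, names(pars))
  if (length(unknown)) stop("no curve family for metric(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (jitter > 0) set.seed(seed)
  grid <- list(); meta <- list()
  for (m in metrics) {
    p <- pars[[m]]
    for (sx in sexes) {
      a <- age_grid - 40
      M <- p[[sx]][["M0"]] * exp(-p$decay * a)
      if (jitter > 0) M <- M * exp(stats::rnorm(length(M), 0, jitter))
      grid[[paste(m, sx)]] <- data.frame(
        metric = m, sex = sx, age = age_grid,
        L = p$L0 + p$Lslope * a,
        M = M,
        S = pmax(p$S0 + p$Sslope * a, 1e-4),
        stringsAsFactors = FALSE)
      meta[[paste(m, sx)]] <- data.frame(
        metric = m, sex = sx, reference_height_cm = unname(p$ref_h[sx]),
        height_exponent = p$hexp, stringsAsFactors = FALSE)
    }
  }
  lms_table(do.call(rbind, grid), do.call(rbind, meta))
}

#' Generate a synthetic monozygotic twin cohort
#'
#' Each pair shares sex and age exactly. Lung-function z-scores are drawn
#' with a pair-shared component plus individual deviations (so intra-pair
#' z-differences are continuous, right-skewed in absolute value) and then
#' inverted through the LMS table to measured FEV1/FVC volumes at both
#' visits, using follow-up height — the same convention the
#' standardization module applies, so standardizing the cohort recovers the
#' generated z-scores. Pack-years follow a zero-inflated gamma per sex;
#' smokers who quit less than 2 years before follow-up are classified as
#' current smokers.
#'
#' @param config A [cohort_config()].
#' @param lms An [lms_table()] used to invert z-scores to measured values
#'   (attached to the result as attribute `lms`).
#' @return data.frame with one row per subject (2 per pair): identifiers,
#'   sex, ages, follow-up height, weights/BMI at both visits, FEV1/FVC at
#'   both visits, pack-years (total and follow-up period), smoking status
#'   and quit time. Deterministic given `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config(), lms = generate_lms_table()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sexes <- rep(c("male", "female"), c(config$n_male_pairs, config$n_female_pairs))
  n_pairs <- length(sexes)
  pair_id <- sprintf("P%04d", seq_len(n_pairs))

  age_fu <- sample(seq(config$age_range[1], config$age_range[2]), n_pairs, replace = TRUE)
  gap <- stats::runif(n_pairs, config$followup_years[2], config$followup_years[3])

  # pair-shared + individual z components; FEV1/FVC correlated within subject
  rho_lvl <- 0.90; rho_chg <- 0.80
  mix <- function(g1, g2, rho) rho * g1 + sqrt(1 - rho^2) * g2
  g1 <- stats::rnorm(n_pairs); g2 <- stats::rnorm(n_pairs)
  gc1 <- stats::rnorm(n_pairs); gc2 <- stats::rnorm(n_pairs)
  zF_pair <- -0.44 + 1.10 * g1
  zV_pair <- -0.19 + 1.10 * mix(g1, g2, rho_lvl)
  zFc_pair <- 0.08 + 0.40 * gc1
  zVc_pair <- 0.50 + 0.40 * mix(gc1, gc2, rho_chg)

  per_subject <- function(pair_vec) rep(pair_vec, each = 2)
  n <- 2L * n_pairs
  u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
  uc1 <- stats::rnorm(n); uc2 <- stats::rnorm(n)
  zF_fu <- per_subject(zF_pair) + 0.55 * u1
  zV_fu <- per_subject(zV_pair) + 0.55 * mix(u1, u2, rho_lvl)
  zF_ch <- per_subject(zFc_pair) + 0.68 * uc1
  zV_ch <- per_subject(zVc_pair) + 0.68 * mix(uc1, uc2, rho_chg)
  zF_bl <- zF_fu - zF_ch
  zV_bl <- zV_fu - zV_ch

  sex_s <- per_subject(sexes)
  sp <- .sex_params
  height_pair <- vapply(seq_len(n_pairs), function(i) {
    p <- sp[[sexes[i]]]
    stats::rnorm(1, p$height_mean, p$height_sd)
  }, numeric(1))
  height <- per_subject(height_pair) + stats::rnorm(n, 0, 1.5)
  weight_pair <- vapply(seq_len(n_pairs), function(i) {
    p <- sp[[sexes[i]]]
    stats::rnorm(1, p$weight_mean, p$weight_sd)
  }, numeric(1))
  weight_fu <- pmax(per_subject(weight_pair) + stats::rnorm(n, 0, 4), 35)
  weight_bl <- pmax(weight_fu + stats::rnorm(n, -1.5, 4), 35)

  # smoking: zero-inflated gamma pair base, exponential discordance split
  py1 <- py2 <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    p <- sp[[sexes[i]]]
    if (stats::runif(1) < p$p_never_pair) next
    base <- stats::rgamma(1, shape = p$py_shape, scale = p$py_mean / p$py_shape)
    disc <- config$smoking_discordance[[sexes[i]]]
    d <- if (disc > 0 && stats::runif(1) < p$disc_fraction) stats::rexp(1, 1 / disc) else 0
    a <- base + d / 2
    b <- max(0, base - d / 2)
    if (stats::runif(1) < 0.5) { py1[i] <- a; py2[i] <- b } else { py1[i] <- b; py2[i] <- a }
  }
  py_total <- as.vector(rbind(py1, py2))
  smoker <- py_total > 0
  active <- smoker & stats::runif(n) < 0.35
  quit_years <- ifelse(!smoker, NA_real_,
                       ifelse(active, 0, stats::runif(n, 0, 25)))
  status <- ifelse(!smoker, "never",
                   ifelse(quit_years < 2, "current", "non-current"))
  gap_s <- per_subject(gap)
  age_fu_s <- per_subject(age_fu)
  smoked_years <- pmax(age_fu_s - 20 - ifelse(smoker, quit_years, 0), 1)
  rate <- ifelse(smoker, py_total / smoked_years, 0)
  py_followup <- rate * pmax(gap_s - ifelse(smoker, quit_years, 0), 0)

  to_measure <- function(measure, z, age) {
    y <- numeric(n)
    for (sx in c("male", "female")) {
      i <- sex_s == sx
      if (!any(i)) next
      cf <- interpolate_lms(lms, measure, sx, age[i], height[i])
      y[i] <- lms_inverse(z[i], cf$L, cf$M, cf$S)
    }
    y
  }
  age_bl_s <- age_fu_s - gap_s
  fev1_fu <- to_measure("FEV1", zF_fu, age_fu_s)
  fev1_bl <- to_measure("FEV1", zF_bl, age_bl_s)
  fvc_fu <- to_measure("FVC", zV_fu, age_fu_s)
  fvc_bl <- to_measure("FVC", zV_bl, age_bl_s)

  cohort <- data.frame(
    subject_id = sprintf("%s_T%d", per_subject(pair_id), rep(1:2, n_pairs)),
    pair_id = per_subject(pair_id),
    twin = rep(1:2, n_pairs),
    sex = sex_s,
    age_baseline = age_bl_s,
    age_followup = age_fu_s,
    followup_years = gap_s,
    height_followup_cm = height,
    weight_baseline_kg = weight_bl,
    weight_followup_kg = weight_fu,
    fev1_baseline = fev1_bl, fev1_followup = fev1_fu,
    fvc_baseline = fvc_bl, fvc_followup = fvc_fu,
    pack_years_total = py_total,
    pack_years_followup = py_followup,
    smoking_status = status,
    quit_years_ago = quit_years,
    stringsAsFactors = FALSE
  )
  cohort$bmi_baseline <- cohort$weight_baseline_kg / (cohort$height_followup_cm / 100)^2
  cohort$bmi_followup <- cohort$weight_followup_kg / (cohort$height_followup_cm / 100)^2
  attr(cohort, "lms") <- lms
  attr(cohort, "config") <- config
  cohort
}

#' Generate a 450K-style probe manifest
#'
#' Each probe gets a unique ID, a chromosome and hg19-style position, a
#' most-proximal gene (or NA for intergenic probes, at `na_fraction`), and
#' a CpG-island context feature combining a gene context (IGR when
#' intergenic) with island/shore/shelf/open-sea relation.
#'
#' @param n_probes,n_genes Counts (> 0).
#' @param na_fraction Fraction of intergenic (NA-gene) probes, in \[0, 1).
#' @param seed Integer seed.
#' @return data.frame: `probe_id`, `chromosome`, `bp`, `gene`,
#'   `cgi_feature`.
#' @export
generate_manifest <- function(n_probes, n_genes, na_fraction = 0.2, seed = 1L) {
  if (na_fraction < 0 || na_fraction >= 1) {
    stop("na_fraction must lie in [0, 1): with na_fraction = 1 no probe could be annotated",
         call. = FALSE)
  }
  if (n_genes <= 0) stop("n_genes must be > 0 when annotatable probes are requested",
                         call. = FALSE)
  set.seed(seed)
  probe_id <- sprintf("cg%08d", sample.int(99999999L, n_probes))
  genes_pool <- sprintf("GENE%05d", seq_len(n_genes))
  gene <- sample(genes_pool, n_probes, replace = TRUE)
  gene[stats::runif(n_probes) < na_fraction] <- NA_character_
  relation <- sample(c("island", "shore", "shelf", "open sea"), n_probes,
                     replace = TRUE, prob = c(0.3, 0.25, 0.1, 0.35))
  context <- ifelse(is.na(gene), "IGR",
                    sample(c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR"),
                           n_probes, replace = TRUE,
                           prob = c(0.12, 0.13, 0.1, 0.08, 0.45, 0.12)))
  data.frame(
    probe_id = probe_id,
    chromosome = as.character(sample(1:22, n_probes, replace = TRUE)),
    bp = sample.int(240000000L, n_probes, replace = TRUE),
    gene = gene,
    cgi_feature = paste(context, relation, sep = "-"),
    stringsAsFactors = FALSE
  )
}

#' Cell-type reference panel
#'
#' Reference beta profiles (probes x cell types) for the five leukocyte
#' subtypes used in the cell-composition adjustment.
#'
#' @param reference_betas Numeric matrix, probes x cell types, beta values
#'   in \[0, 1\], rownames probe IDs.
#' @param cell_types Cell-type labels (default [blood_cell_types()]).
#' @return list of class `cell_reference_panel`.
#' @export
cell_reference_panel <- function(reference_betas, cell_types = blood_cell_types()) {
  if (ncol(reference_betas) != length(cell_types)) {
    stop("reference matrix must have one column per cell type", call. = FALSE)
  }
  if (any(reference_betas < 0 | reference_betas > 1)) {
    stop("reference betas must lie in [0, 1]", call. = FALSE)
  }
  colnames(reference_betas) <- cell_types
  for (i in seq_along(cell_types)) for (j in seq_len(i - 1)) {
    if (mean(abs(reference_betas[, i] - reference_betas[, j])) <= 0) {
      stop("reference columns must be pairwise distinct: ",
           cell_types[j], " vs ", cell_types[i], call. = FALSE)
    }
  }
  structure(list(cell_types = cell_types, reference_betas = reference_betas),
            class = "cell_reference_panel")
}

#' Generate a synthetic cell-type reference panel
#'
#' Per-probe baseline betas come from a bimodal mixture (mostly
#' unmethylated or mostly methylated, a minority intermediate — the
#' hallmark of array beta distributions). A fraction of probes is
#' cell-type informative: each cell type gets an independent M-scale shift
#' there, making the reference columns distinct and the deconvolution
#' problem well-posed.
#'
#' @param manifest Probe manifest (or character vector of probe IDs).
#' @param informative_fraction Fraction of cell-discriminating probes.
#' @param shift_sd SD of the informative M-scale shifts.
#' @param seed Integer seed.
#' @return A [cell_reference_panel()].
#' @export
generate_cell_panel <- function(manifest, informative_fraction = 0.25,
                                shift_sd = 1.5, seed = 1L) {
  probes <- if (is.character(manifest)) manifest else manifest$probe_id
  set.seed(seed)
  np <- length(probes)
  comp <- sample(c("low", "mid", "high"), np, replace = TRUE,
                 prob = c(0.42, 0.16, 0.42))
  base_beta <- numeric(np)
  base_beta[comp == "low"] <- stats::rbeta(sum(comp == "low"), 3, 30)
  base_beta[comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 8, 8)
  base_beta[comp == "high"] <- stats::rbeta(sum(comp == "high"), 30, 3)
  base_m <- beta_to_m(base_beta)
  informative <- stats::runif(np) < informative_fraction
  k <- length(blood_cell_types())
  shifts <- matrix(0, np, k)
  shifts[informative, ] <- stats::rnorm(sum(informative) * k, 0, shift_sd)
  ref_m <- base_m + shifts
  ref_beta <- pmin(pmax(m_to_beta(ref_m), 1e-6), 1 - 1e-6)
  rownames(ref_beta) <- probes
  cell_reference_panel(ref_beta)
}

#' Planted probe-level association
#'
#' Describes a true effect injected into the synthetic methylome: at
#' `probe_id`, the intra-pair M-value difference (superior minus inferior
#' under `metric`'s ordering) contains `slope` times the transformed
#' intra-pair z-difference — exactly the coefficient the EWAS estimates.
#'
#' @param probe_id Probe identifier (must exist in the manifest used for
#'   generation).
#' @param metric One of the six analysis metrics.
#' @param slope Effect size, M-value units per unit (possibly
#'   log-transformed) intra-pair z-difference.
#' @param noise_sd Individual-level M noise SD at this probe (replaces the
#'   default individual noise).
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(probe_id, metric, slope, noise_sd = 0.1) {
  metric_info(metric)  # validates
  structure(list(probe_id = probe_id, metric = metric,
                 slope = slope, noise_sd = noise_sd),
            class = "planted_effect")
}

#' Generate synthetic methylomes for a twin cohort
#'
#' Subject beta values are cell-type mixtures: the reference panel's
#' columns weighted by subject-specific leukocyte fractions (Dirichlet
#' around typical blood composition). On the M scale each probe then
#' receives an additive pair-shared random intercept and individual noise;
#' `pair_correlation` is the fraction of that residual variance shared
#' within pairs, making the within-pair correlation analytically
#' controllable. Planted effects are injected on the M scale after mixture
#' construction, split +/- half between the superior and inferior twin so
#' the pair difference carries exactly `slope * predictor`. Betas are
#' clipped to `[1e-6, 1 - 1e-6]`, and QC metadata is generated with a
#' configurable fraction of failing probes.
#'
#' @param cohort Cohort from [generate_cohort()] (its `lms` attribute is
#'   used to compute the z-scores that planted effects follow, unless
#'   `lms` is supplied).
#' @param panel A [cell_reference_panel()] whose probes define the array.
#' @param manifest Probe manifest covering the panel probes.
#' @param planted list of [planted_effect()]s (default none: null data).
#' @param pair_correlation Fraction of residual M variance shared within
#'   pairs, in \[0, 1\].
#' @param total_sd Total residual M SD per measurement.
#' @param bad_probe_fraction Fraction of probes given concentrated QC
#'   failures (removed by [qc_filter()]).
#' @param blacklist Probe IDs to record as cross-reactive.
#' @param lms Optional LMS table override.
#' @param seed Integer seed.
#' @return list: `dataset` (a [methylation_dataset()]), `cell_fractions`
#'   (data.frame `sample_id` + five cell types, the true fractions), and
#'   `truth` (data.frame of planted effects).
#' @export
generate_methylomes <- function(cohort, panel, manifest, planted = list(),
                                pair_correlation = 0.5, total_sd = 0.16,
                                bad_probe_fraction = 0.01,
                                blacklist = character(),
                                lms = NULL, seed = 1L) {
  stopifnot(inherits(panel, "cell_reference_panel"))
  if (inherits(planted, "planted_effect")) planted <- list(planted)
  probes <- rownames(panel$reference_betas)
  bad_planted <- vapply(planted, function(e) !(e$probe_id %in% manifest$probe_id),
                        logical(1))
  if (any(bad_planted)) {
    stop("planted probe(s) absent from manifest: ",
         paste(vapply(planted[bad_planted], `[[`, "", "probe_id"), collapse = ", "),
         call. = FALSE)
  }
  if (pair_correlation < 0 || pair_correlation > 1) {
    stop("pair_correlation must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(lms)) lms <- attr(cohort, "lms")
  if (is.null(lms)) stop("no LMS table: supply `lms` or use a generated cohort", call. = FALSE)

  set.seed(seed)
  n <- nrow(cohort)
  np <- length(probes)
  subjects <- cohort$subject_id
  pair_index <- match(cohort$pair_id, unique(cohort$pair_id))
  n_pairs <- max(pair_index)

  # subject leukocyte fractions: Dirichlet around typical blood composition
  target <- c(monocytes = 0.08, lymphocytes = 0.30, basophils = 0.01,
              neutrophils = 0.57, eosinophils = 0.04)
  conc <- 150
  g <- matrix(stats::rgamma(n * 5, shape = rep(conc * target, each = n)), n, 5)
  fractions <- g / rowSums(g)
  colnames(fractions) <- blood_cell_types()

  beta_base <- panel$reference_betas %*% t(fractions)  # probes x subjects
  M <- beta_to_m(beta_base)

  sd_pair <- total_sd * sqrt(pair_correlation)
  sd_ind <- total_sd * sqrt(1 - pair_correlation)
  pair_eff <- matrix(stats::rnorm(np * n_pairs, 0, sd_pair), np, n_pairs)
  ind_sd <- rep(sd_ind, np)
  names(ind_sd) <- probes
  for (e in planted) ind_sd[e$probe_id] <- e$noise_sd
  noise <- matrix(stats::rnorm(np * n, 0, 1), np, n) * ind_sd
  M <- M + pair_eff[, pair_index] + noise

  if (length(planted)) {
    zpanel <- standardize_cohort(cohort, lms)
    col_of <- match(subjects, cohort$subject_id)
    for (e in planted) {
      ordering <- order_pairs(zpanel, e$metric)
      x <- suppressWarnings(transform_predictor(ordering$delta_z, e$metric))
      ok <- is.finite(x)
      sup <- match(ordering$superior_id[ok], subjects)
      inf <- match(ordering$inferior_id[ok], subjects)
      r <- match(e$probe_id, probes)
      M[r, sup] <- M[r, sup] + e$slope * x[ok] / 2
      M[r, inf] <- M[r, inf] - e$slope * x[ok] / 2
    }
  }

  beta <- pmin(pmax(m_to_beta(M), 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(probes, subjects)

  detp <- matrix(stats::runif(np * n, 0, 0.009), np, n, dimnames = dimnames(beta))
  bead <- matrix(4L + stats::rpois(np * n, 10), np, n, dimnames = dimnames(beta))
  n_bad <- round(bad_probe_fraction * np)
  if (n_bad > 0) {
    planted_ids <- vapply(planted, `[[`, "", "probe_id")
    eligible <- setdiff(probes, planted_ids)
    bad <- sample(eligible, min(n_bad, length(eligible)))
    for (pb in bad) {
      nfail <- max(1L, round(stats::runif(1, 0.06, 0.15) * n))
      cols <- sample(n, nfail)
      half <- stats::runif(nfail) < 0.5
      detp[pb, cols[half]] <- stats::runif(sum(half), 0.02, 0.2)
      bead[pb, cols[!half]] <- sample(0:2, sum(!half), replace = TRUE)
    }
  }

  dataset <- methylation_dataset(beta, detp, bead, manifest, blacklist)
  truth <- if (length(planted)) {
    data.frame(probe = vapply(planted, `[[`, "", "probe_id"),
               metric = vapply(planted, `[[`, "", "metric"),
               slope = vapply(planted, `[[`, 0, "slope"),
               noise_sd = vapply(planted, `[[`, 0, "noise_sd"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe = character(), metric = character(),
               slope = numeric(), noise_sd = numeric(), stringsAsFactors = FALSE)
  }
  list(dataset = dataset,
       cell_fractions = data.frame(sample_id = subjects, fractions,
                                   check.names = FALSE, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate synthetic gene-set collections
#'
#' Random gene sets over a gene universe, optionally with one "spiked" set
#' concentrated on supplied genes (e.g. the proximal genes of planted
#' probes) for end-to-end enrichment tests.
#'
#' @param genes Gene universe (non-empty character vector).
#' @param n_sets Number of random sets (0 allowed).
#' @param size_range `c(min, max)` set sizes; max must not exceed the
#'   universe size.
#' @param spike Optional character vector: genes of the spiked set
#'   (`"SPIKED_SET"`), prepended to the collection.
#' @param seed Integer seed.
#' @return Named list of gene sets with a `descriptions` attribute.
#' @export
generate_genesets <- function(genes, n_sets = 50, size_range = c(5, 50),
                              spike = NULL, seed = 1L) {
  if (!length(genes)) stop("empty gene universe", call. = FALSE)
  if (size_range[2] > length(genes)) {
    stop("size_range max exceeds number of genes", call. = FALSE)
  }
  set.seed(seed)
  sets <- list()
  desc <- character()
  if (!is.null(spike)) {
    sets[["SPIKED_SET"]] <- unique(spike)
    desc["SPIKED_SET"] <- "synthetic spiked set"
  }
  if (n_sets > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    for (i in seq_len(n_sets)) {
      nm <- sprintf("PATH_%03d", i)
      sets[[nm]] <- sample(genes, sizes[i])
      desc[nm] <- "synthetic random set"
    }
  }
  structure(sets, descriptions = desc)
}
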