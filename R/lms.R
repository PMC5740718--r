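#' LMS coefficient tables for spirometry reference equations
#'
#' Reference equations of the GLI type describe the healthy, non-smoking
#' distribution of a lung-function measure with three age- and sex-specific
#' curves: L (Box-Cox skewness power), M (predicted median in measure units)
#' and S (coefficient of variation). The measured value `y` is standardized
#' as
#' \deqn{z = \frac{(y/M)^L - 1}{L \cdot S}}
#' with the limit \eqn{z = \log(y/M)/S} as \eqn{L \to 0}. Height enters by
#' scaling M with `(height / reference_height)^height_exponent`.
#'
#' An `lms_table` stores the coefficient grid as a data.frame with columns
#' `metric`, `sex`, `age`, `L`, `M`, `S`, plus a per-(metric, sex) metadata
#' table (`reference_height_cm`, `height_exponent`) in attribute `meta`.
#'
#' @param grid data.frame with columns metric, sex, age, L, M, S.
#' @param meta data.frame with columns metric, sex, reference_height_cm,
#'   height_exponent.
#' @return An object of class `lms_table`.
#' @export
lms_table <- function(grid, meta) {
  need <- c("metric", "sex", "age", "L", "M", "S")
  if (!all(need %in% names(grid))) {
    stop("LMS grid must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  need_m <- c("metric", "sex", "reference_height_cm", "height_exponent")
  if (!all(need_m %in% names(meta))) {
    stop("LMS meta must have columns: ", paste(need_m, collapse = ", "), call. = FALSE)
  }
  if (any(grid$S <= 0)) stop("LMS table invalid: S must be > 0 everywhere", call. = FALSE)
  if (any(grid$M <= 0)) stop("LMS table invalid: M must be > 0 everywhere", call. = FALSE)
  for (key in split(grid, list(grid$metric, grid$sex), drop = TRUE)) {
    if (is.unsorted(key$age, strictly = TRUE)) {
      stop("LMS age grid must be strictly increasing within (metric, sex): ",
           key$metric[1], "/", key$sex[1], call. = FALSE)
    }
  }
  grid <- grid[, need]
  meta <- meta[, need_m]
  rownames(grid) <- NULL
  rownames(meta) <- NULL
  structure(grid, meta = meta, class = c("lms_table", "data.frame"))
}

#' @export
print.lms_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("LMS coefficient table:", nrow(x), "grid rows;",
      nrow(meta), "(metric, sex) strata\n")
  for (i in seq_len(nrow(meta))) {
    sub <- x[x$metric == meta$metric[i] & x$sex == meta$sex[i], ]
    cat(sprintf("  %-9s %-6s ages %.0f-%.0f  ref height %.1f cm, height exp %.2f\n",
                meta$metric[i], meta$sex[i], min(sub$age), max(sub$age),
                meta$reference_height_cm[i], meta$height_exponent[i]))
  }
  invisible(x)
}

lms_meta <- function(table, metric, sex) {
  meta <- attr(table, "meta")
  i <- which(meta$metric == metric & meta$sex == sex)
  if (length(i) != 1) {
    stop("no LMS coefficients for metric '", metric, "', sex '", sex, "'", call. = FALSE)
  }
  meta[i, ]
}

#' Interpolate LMS coefficients at a given age and height
#'
#' L and S are linearly interpolated in age; M is linearly interpolated in
#' age and then scaled by `(height/reference_height)^height_exponent`. Ages
#' outside the coefficient grid are a hard error: the reference equations
#' are not extrapolated.
#'
#' @param table An [lms_table()].
#' @param metric Spirometry measure, e.g. `"FEV1"`, `"FVC"`, `"FEV1/FVC"`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (vectorized).
#' @param height Standing height in cm (vectorized, recycled against age).
#' @return data.frame with columns `L`, `M`, `S`.
#' @export
interpolate_lms <- function(table, metric, sex, age, height) {
  meta <- lms_meta(table, metric, sex)
  sub <- table[table$metric == metric & table$sex == sex, ]
  if (any(age < min(sub$age) - 1e-9) || any(age > max(sub$age) + 1e-9)) {
    stop("age outside LMS grid range [", min(sub$age), ", ", max(sub$age),
         "] for ", metric, "/", sex, "; extrapolation is not supported",
         call. = FALSE)
  }
  interp <- function(v) {
    if (nrow(sub) == 1) rep(v, length(age))
    else stats::approx(sub$age, v, xout = age, rule = 1)$y
  }
  L <- interp(sub$L)
  S <- interp(sub$S)
  M <- interp(sub$M) * (height / meta$reference_height_cm) ^ meta$height_exponent
  data.frame(L = L, M = M, S = S)
}

#' LMS z-score
#'
#' Standardizes a measured value against an LMS-parameterized reference
#' distribution: `z = ((y/M)^L - 1) / (L*S)`, computed via `expm1` so the
#' `L -> 0` limit `log(y/M)/S` is reached smoothly. The z-score counts how
#' many reference SDs the measurement lies from the predicted median.
#'
#' @param y Measured value (> 0), in the measure's units.
#' @param L,M,S LMS coefficients (`M > 0`, `S > 0`).
#' @return z-score in SD units. Vectorized over all arguments.
#' @export
#' @examples
#' lms_zscore(2.0, L = 1, M = 1.8, S = 0.1)  # (2/1.8 - 1)/0.1
lms_zscore <- function(y, L, M, S) {
  if (any(!is.finite(y)) || any(y <= 0)) stop("measured value y must be finite and > 0", call. = FALSE)
  if (any(M <= 0) || any(S <= 0)) stop("LMS coefficients require M > 0 and S > 0", call. = FALSE)
  r <- log(y / M)
  ifelse(abs(L) < 1e-12, r / S, expm1(L * r) / (L * S))
}

#' Invert an LMS z-score back to the measurement scale
#'
#' Closed-form inverse of [lms_zscore()]: `y = M * (1 + L*S*z)^(1/L)`, with
#' `y = M * exp(S*z)` in the `L -> 0` limit.
#'
#' @inheritParams lms_zscore
#' @param z z-score in SD units.
#' @return Measured value in the measure's units.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop("LMS coefficients require M > 0 and S > 0", call. = FALSE)
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * exp(log1p(L * S * z) / L))
}

#' Change in z-score over the follow-up period
#'
#' Defined as the follow-up z-score minus the baseline z-score.
#'
#' @param z_baseline,z_followup z-scores in SD units (vectorized).
#' @return `z_followup - z_baseline`, in SD units.
#' @export
zscore_change <- function(z_baseline, z_followup) {
  if (any(!is.finite(z_baseline)) || any(!is.finite(z_followup))) {
    stop("z-scores must be finite", call. = FALSE)
  }
  z_followup - z_baseline
}

#' Standardize a twin cohort's spirometry to z-scores
#'
#' Computes zFEV1, zFVC and zFEV1/FVC at baseline and follow-up, and their
#' changes, for every subject. Follow-up height is used for BOTH visits
#' (height is only objectively measured at follow-up, and height change in
#' this age group is negligible); baseline z-scores use the baseline age.
#' The FEV1/FVC ratio is standardized from the measured ratio with its own
#' coefficient rows — never as a ratio of z-scores.
#'
#' @param cohort Phenotype data.frame (see [generate_cohort()]) with columns
#'   `subject_id`, `pair_id`, `sex`, `age_baseline`, `age_followup`,
#'   `height_followup_cm`, `fev1_baseline`, `fev1_followup`,
#'   `fvc_baseline`, `fvc_followup`.
#' @param table An [lms_table()] covering metrics FEV1, FVC and FEV1/FVC.
#' @return data.frame (one row per subject) with `subject_id`, `pair_id`,
#'   `sex`, and columns `zFEV1_baseline`, `zFEV1_followup`, `zFEV1_change`
#'   (and likewise `zFVC_*`, `zFEV1FVC_*`).
#' @export
standardize_cohort <- function(cohort, table) {
  need <- c("subject_id", "pair_id", "sex", "age_baseline", "age_followup",
            "height_followup_cm", "fev1_baseline", "fev1_followup",
            "fvc_baseline", "fvc_followup")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- cohort$subject_id[!is.finite(cohort$height_followup_cm)]
  if (length(bad)) {
    stop("missing follow-up height for subjects: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  z_at <- function(measure, y, age) {
    out <- numeric(nrow(cohort))
    for (sx in unique(cohort$sex)) {
      i <- cohort$sex == sx
      cf <- interpolate_lms(table, measure, sx, age[i], cohort$height_followup_cm[i])
      out[i] <- lms_zscore(y[i], cf$L, cf$M, cf$S)
    }
    out
  }

  ratio_bl <- cohort$fev1_baseline / cohort$fvc_baseline
  ratio_fu <- cohort$fev1_followup / cohort$fvc_followup
  panel <- data.frame(
    subject_id = cohort$subject_id,
    pair_id = cohort$pair_id,
    sex = cohort$sex,
    zFEV1_baseline    = z_at("FEV1", cohort$fev1_baseline, cohort$age_baseline),
    zFEV1_followup    = z_at("FEV1", cohort$fev1_followup, cohort$age_followup),
    zFVC_baseline     = z_at("FVC", cohort$fvc_baseline, cohort$age_baseline),
    zFVC_followup     = z_at("FVC", cohort$fvc_followup, cohort$age_followup),
    zFEV1FVC_baseline = z_at("FEV1/FVC", ratio_bl, cohort$age_baseline),
    zFEV1FVC_followup = z_at("FEV1/FVC", ratio_fu, cohort$age_followup),
    stringsAsFactors = FALSE
  )
  panel$zFEV1_change    <- zscore_change(panel$zFEV1_baseline, panel$zFEV1_followup)
  panel$zFVC_change     <- zscore_change(panel$zFVC_baseline, panel$zFVC_followup)
  panel$zFEV1FVC_change <- zscore_change(panel$zFEV1FVC_baseline, panel$zFEV1FVC_followup)
  panel
}

#' Write / read an LMS coefficient table as TSV
#'
#' One block per (metric, sex): comment headers `#metric`, `#sex`,
#' `#reference_height_cm`, `#height_exponent`, then tab-separated columns
#' `age  L  M  S`.
#'
#' @param table An [lms_table()].
#' @param path File path.
#' @return `write_lms_table` returns `path` invisibly; `read_lms_table`
#'   returns an [lms_table()].
#' @export
write_lms_table <- function(table, path) {
  meta <- attr(table, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(meta))) {
    sub <- table[table$metric == meta$metric[i] & table$sex == meta$sex[i], ]
    writeLines(c(
      paste0("#metric\t", meta$metric[i]),
      paste0("#sex\t", meta$sex[i]),
      paste0("#reference_height_cm\t", format(meta$reference_height_cm[i], digits = 15)),
      paste0("#height_exponent\t", format(meta$height_exponent[i], digits = 15)),
      "age\tL\tM\tS"
    ), con)
    writeLines(sprintf("%s\t%s\t%s\t%s",
                       format(sub$age, digits = 15), format(sub$L, digits = 15),
                       format(sub$M, digits = 15), format(sub$S, digits = 15)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_lms_table
#' @export
read_lms_table <- function(path) {
  lines <- readLines(path)
  grid <- list(); meta <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      if (is.null(cur) || kv[1] == "metric") cur <- list()
      cur[[kv[1]]] <- kv[2]
      next
    }
    if (startsWith(ln, "age\t")) {
      meta[[length(meta) + 1]] <- data.frame(
        metric = cur$metric, sex = cur$sex,
        reference_height_cm = as.numeric(cur$reference_height_cm),
        height_exponent = as.numeric(cur$height_exponent),
        stringsAsFactors = FALSE)
      next
    }
    v <- as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
    grid[[length(grid) + 1]] <- data.frame(
      metric = cur$metric, sex = cur$sex,
      age = v[1], L = v[2], M = v[3], S = v[4], stringsAsFactors = FALSE)
    cur$metric <- cur$metric  # keep block context
  }
  lms_table(do.call(rbind, grid), do.call(rbind, meta))
}
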