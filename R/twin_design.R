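#' Order twin pairs into superior / inferior by a lung-function metric
#'
#' Within each monozygotic pair the twin with the higher z-score for the
#' chosen metric is the "superior" twin and the co-twin the "inferior"
#' twin; the intra-pair difference `delta_z = z_superior - z_inferior` is
#' therefore non-negative by construction. Output does not depend on the
#' order twins are stored in. Exact ties are flagged (`tied = TRUE`) and
#' excluded downstream.
#'
#' @param panel Z-score panel from [standardize_cohort()].
#' @param metric One of the six analysis metrics in [lung_metrics()].
#' @return data.frame with one row per pair: `pair_id`, `superior_id`,
#'   `inferior_id`, `delta_z`, `tied`.
#' @export
order_pairs <- function(panel, metric) {
  col <- metric_panel_column(metric)
  if (!col %in% names(panel)) stop("z-score panel lacks column ", col, call. = FALSE)
  split_panel <- split(panel, panel$pair_id)
  rows <- lapply(split_panel, function(p) {
    if (nrow(p) != 2) {
      stop("pair ", p$pair_id[1], " does not have exactly two twins", call. = FALSE)
    }
    z <- p[[col]]
    if (anyNA(z)) {
      stop("missing ", metric, " value in pair ", p$pair_id[1], call. = FALSE)
    }
    # deterministic tie handling: keep stored order, flag the tie
    sup <- if (z[1] >= z[2]) 1L else 2L
    inf <- 3L - sup
    data.frame(pair_id = p$pair_id[1],
               superior_id = p$subject_id[sup],
               inferior_id = p$subject_id[inf],
               delta_z = z[sup] - z[inf],
               tied = z[1] == z[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pair_id), , drop = FALSE]
}

#' Transform the intra-pair z-difference into the regression predictor
#'
#' Intra-pair differences of zFEV1, zFVC and their changes are extremely
#' right-skewed and enter the model as natural logs; the two FEV1/FVC ratio
#' metrics enter untransformed. A zero difference under a log metric has no
#' defined predictor and yields `NA` with a warning (the pair is excluded
#' from that metric's analysis).
#'
#' @param delta_z Non-negative intra-pair z-difference (vectorized).
#' @param metric One of the six analysis metrics.
#' @return Predictor values (natural log scale for log metrics).
#' @export
transform_predictor <- function(delta_z, metric) {
  info <- metric_info(metric)
  if (any(delta_z < 0, na.rm = TRUE)) stop("delta_z must be >= 0", call. = FALSE)
  if (!info$log_transform) return(delta_z)
  zero <- !is.na(delta_z) & delta_z == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with delta_z = 0 excluded from log-transformed metric ",
            metric, call. = FALSE)
  }
  out <- ifelse(zero, NA_real_, log(delta_z))
  out
}

#' Intra-pair covariate differences under a metric's ordering
#'
#' Every differenced covariate is superior minus inferior under the given
#' ordering. Sex and age are identical within an MZ pair, so they enter as
#' pair-level values (sex as an indicator, female = 1). Smoking status at
#' follow-up is coded ordinally (never = 0, non-current = 1, current = 2)
#' and differenced. The cross-sectional flavour uses follow-up BMI and
#' total pack-years; the longitudinal flavour uses BMI change over the
#' follow-up period and follow-up-period pack-years. Cell fractions are
#' differenced for all five leukocyte types; the regression later drops
#' neutrophils (the reference type) because the five differences sum to
#' zero.
#'
#' @param cohort Phenotype data.frame (see [generate_cohort()]).
#' @param ordering Output of [order_pairs()].
#' @param cell_fractions data.frame from [fill_cell_fractions()] (or the
#'   true fractions), with `sample_id` matching `subject_id` and the five
#'   cell-type columns.
#' @param flavour `"cross-sectional"` or `"longitudinal"`.
#' @return data.frame keyed by `pair_id` with `sex`, `age`, `d_bmi`,
#'   `d_pack_years`, `d_smoking_status` and `d_<cell type>` columns, plus
#'   a `dropped` attribute listing pairs removed for missing covariates.
#' @export
difference_covariates <- function(cohort, ordering, cell_fractions,
                                  flavour = c("cross-sectional", "longitudinal")) {
  flavour <- match.arg(flavour)
  cts <- blood_cell_types()
  idx <- function(ids, df, key) match(ids, df[[key]])
  sup <- idx(ordering$superior_id, cohort, "subject_id")
  inf <- idx(ordering$inferior_id, cohort, "subject_id")
  if (anyNA(sup) || anyNA(inf)) stop("ordering references subjects absent from cohort", call. = FALSE)

  status_code <- c(never = 0, `non-current` = 1, current = 2)
  code <- status_code[cohort$smoking_status]
  if (anyNA(code)) stop("smoking_status must be never/non-current/current", call. = FALSE)

  if (flavour == "cross-sectional") {
    bmi <- cohort$bmi_followup
    py <- cohort$pack_years_total
  } else {
    bmi <- cohort$bmi_followup - cohort$bmi_baseline
    py <- cohort$pack_years_followup
  }

  fsup <- idx(ordering$superior_id, cell_fractions, "sample_id")
  finf <- idx(ordering$inferior_id, cell_fractions, "sample_id")
  if (anyNA(fsup) || anyNA(finf)) {
    stop("cell fractions missing for some subjects in ordering", call. = FALSE)
  }

  out <- data.frame(
    pair_id = ordering$pair_id,
    sex = as.numeric(cohort$sex[sup] == "female"),
    age = cohort$age_followup[sup],
    d_bmi = bmi[sup] - bmi[inf],
    d_pack_years = py[sup] - py[inf],
    d_smoking_status = code[sup] - code[inf],
    stringsAsFactors = FALSE
  )
  for (ct in cts) {
    out[[paste0("d_", ct)]] <- cell_fractions[[ct]][fsup] - cell_fractions[[ct]][finf]
  }

  complete <- stats::complete.cases(out)
  dropped <- out$pair_id[!complete]
  if (length(dropped)) {
    message("dropping ", length(dropped), " pair(s) with missing covariates: ",
            paste(dropped, collapse = ", "))
  }
  res <- out[complete, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Intra-pair methylation differences
#'
#' One column per pair: M-value of the superior twin minus M-value of the
#' inferior twin under the given metric's ordering. Orderings differ by
#' metric, so each analysis has its own delta-M matrix.
#'
#' @param m_matrix Probes x samples M-value matrix.
#' @param ordering Output of [order_pairs()].
#' @return Probes x pairs matrix of intra-pair M differences (columns named
#'   by `pair_id`).
#' @export
difference_methylation <- function(m_matrix, ordering) {
  miss <- setdiff(c(ordering$superior_id, ordering$inferior_id), colnames(m_matrix))
  if (length(miss)) {
    stop("samples missing from M-value matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dm <- m_matrix[, ordering$superior_id, drop = FALSE] -
    m_matrix[, ordering$inferior_id, drop = FALSE]
  colnames(dm) <- ordering$pair_id
  dm
}

#' Assemble the pair-level design for one analysis
#'
#' Combines pair ordering, predictor transformation and covariate
#' differencing for a metric, excluding tied pairs, pairs with an undefined
#' log predictor and pairs with missing covariates. Exclusions are
#' accounted: input pairs = analyzed pairs + excluded pairs.
#'
#' @inheritParams difference_covariates
#' @param panel Z-score panel from [standardize_cohort()].
#' @param metric One of the six analysis metrics.
#' @return data.frame (class `pair_design`) with `pair_id`, `superior_id`,
#'   `inferior_id`, `delta_z`, `predictor`, the covariate columns of
#'   [difference_covariates()], and attributes `metric`, `flavour`,
#'   `exclusions` (data.frame pair_id, reason).
#' @export
build_pair_design <- function(cohort, panel, cell_fractions, metric) {
  info <- metric_info(metric)
  ordering <- order_pairs(panel, metric)
  predictor <- suppressWarnings(transform_predictor(ordering$delta_z, metric))

  excl <- list()
  bad_tie <- ordering$tied
  if (any(bad_tie)) {
    excl$tied <- data.frame(pair_id = ordering$pair_id[bad_tie], reason = "tied",
                            stringsAsFactors = FALSE)
  }
  bad_log <- !bad_tie & is.na(predictor)
  if (any(bad_log)) {
    excl$log <- data.frame(pair_id = ordering$pair_id[bad_log],
                           reason = "zero delta under log transform",
                           stringsAsFactors = FALSE)
  }
  keep <- !(bad_tie | bad_log)
  ordering <- ordering[keep, , drop = FALSE]
  predictor <- predictor[keep]

  cov <- difference_covariates(cohort, ordering, cell_fractions, info$flavour)
  if (length(attr(cov, "dropped"))) {
    excl$cov <- data.frame(pair_id = attr(cov, "dropped"),
                           reason = "missing covariate", stringsAsFactors = FALSE)
  }
  keep2 <- ordering$pair_id %in% cov$pair_id
  ordering <- ordering[keep2, , drop = FALSE]
  predictor <- predictor[keep2]

  out <- cbind(ordering[, c("pair_id", "superior_id", "inferior_id", "delta_z")],
               predictor = predictor,
               cov[match(ordering$pair_id, cov$pair_id),
                   setdiff(names(cov), "pair_id"), drop = FALSE])
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(pair_id = character(), reason = character(), stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  structure(out, metric = metric, flavour = info$flavour,
            exclusions = exclusions, class = c("pair_design", "data.frame"))
}

#' @export
print.pair_design <- function(x, ...) {
  cat("pair_design:", nrow(x), "pairs | metric", attr(x, "metric"),
      "|", attr(x, "flavour"), "|", nrow(attr(x, "exclusions")), "excluded\n")
  NextMethod()
}

#' Write a pair design table as TSV with a provenance header
#'
#' @param design A `pair_design` from [build_pair_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#metric\t", attr(design, "metric")),
               paste0("#flavour\t", attr(design, "flavour")),
               paste0("#n_pairs\t", nrow(design)),
               paste0("#n_excluded\t", nrow(attr(design, "exclusions")))), con)
  utils::write.table(as.data.frame(design), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
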