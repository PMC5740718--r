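#' Container for 450K-style methylation data
#'
#' Bundles the beta-value matrix (proportion methylated, probes x samples)
#' with per-measurement QC metadata (detection p-values and bead counts on
#' the same shape), the probe manifest, and a cross-reactive probe
#' blacklist.
#'
#' @param beta Numeric matrix, probes x samples, values in \[0, 1\] (NA for
#'   missing signal). Rownames are probe IDs, colnames sample IDs.
#' @param detection_p Numeric matrix, same shape: detection p per measurement.
#' @param bead_count Integer matrix, same shape: beads per measurement.
#' @param manifest data.frame with columns `probe_id`, `chromosome`, `bp`,
#'   `gene` (NA for intergenic), `cgi_feature`.
#' @param blacklist Character vector of probe IDs to remove (cross-reactive
#'   probes), possibly empty.
#' @return An object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(beta, detection_p, bead_count, manifest,
                                blacklist = character()) {
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix needs probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) stop("probe IDs must be unique", call. = FALSE)
  for (nm in c("detection_p", "bead_count")) {
    m <- get(nm)
    if (!identical(dim(m), dim(beta))) {
      stop(nm, " matrix shape does not match beta", call. = FALSE)
    }
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]", call. = FALSE)
  need <- c("probe_id", "chromosome", "bp", "gene", "cgi_feature")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(rownames(beta), manifest$probe_id)
  if (length(miss)) {
    stop("probes missing from manifest: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  }
  structure(list(beta = beta, detection_p = detection_p, bead_count = bead_count,
                 manifest = manifest, blacklist = as.character(blacklist)),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", nrow(x$beta), "probes x", ncol(x$beta), "samples;",
      length(x$blacklist), "blacklisted probe IDs\n")
  invisible(x)
}

#' Probe-level quality control
#'
#' A single measurement fails QC if its bead count is below 3, its detection
#' p-value exceeds 0.01, or it has zero signal (beta missing, or exactly 0
#' with bead count 0). A probe is removed when it fails in more than 5% of
#' samples (strict inequality) or appears on the cross-reactive blacklist.
#' Blacklist removal takes precedence in the attribution: a blacklisted
#' probe is counted under the blacklist rule even if it also fails QC.
#'
#' @param dataset A [methylation_dataset()].
#' @param max_failed_fraction Failure-fraction threshold (default 0.05,
#'   removal requires strictly greater).
#' @return The filtered `methylation_dataset`, with a `qc_report` attribute:
#'   a data.frame of rule-wise counts (measurement-level failure counts and
#'   probe-level removal attribution) and a `removed` attribute naming
#'   removed probes per rule.
#' @export
qc_filter <- function(dataset, max_failed_fraction = 0.05) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  beta <- dataset$beta
  detp <- dataset$detection_p
  bead <- dataset$bead_count
  if (anyNA(detp) || anyNA(bead)) stop("QC metadata (detection p / bead count) is incomplete", call. = FALSE)

  low_bead <- bead < 3
  high_detp <- detp > 0.01
  zero_signal <- is.na(beta) | (beta == 0 & bead == 0)
  failed <- low_bead | high_detp | zero_signal

  frac_failed <- rowMeans(failed)
  over_threshold <- frac_failed > max_failed_fraction
  blacklisted <- rownames(beta) %in% dataset$blacklist

  removed_blacklist <- rownames(beta)[blacklisted]
  removed_failed <- rownames(beta)[over_threshold & !blacklisted]
  keep <- !(blacklisted | over_threshold)

  report <- data.frame(
    rule = c("measurements_low_bead_count", "measurements_high_detection_p",
             "measurements_zero_signal",
             "probes_removed_failed_fraction", "probes_removed_blacklist",
             "probes_in", "probes_retained"),
    count = c(sum(low_bead), sum(high_detp), sum(zero_signal),
              length(removed_failed), length(removed_blacklist),
              nrow(beta), sum(keep)),
    stringsAsFactors = FALSE
  )

  out <- methylation_dataset(
    beta = beta[keep, , drop = FALSE],
    detection_p = detp[keep, , drop = FALSE],
    bead_count = bead[keep, , drop = FALSE],
    manifest = dataset$manifest,
    blacklist = dataset$blacklist
  )
  attr(out, "qc_report") <- report
  attr(out, "removed") <- list(blacklist = removed_blacklist,
                               failed_fraction = removed_failed)
  out
}

#' Beta-value / M-value transforms
#'
#' M-values are the base-2 logit of the methylated proportion:
#' `M = log2(beta / (1 - beta))`. Betas of exactly 0 or 1 arise from
#' rounding, not biology, so betas are clipped to
#' `[1e-6, 1 - 1e-6]` before the logit to keep M finite.
#'
#' @param beta Proportion methylated in \[0, 1\] (vector or matrix).
#' @param clip Clipping bound applied before the logit (default `1e-6`).
#' @return M-values, same shape as input.
#' @export
#' @examples
#' beta_to_m(0.8)  # log2(4) = 2
beta_to_m <- function(beta, clip = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, clip), 1 - clip)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(m) <- dim(beta)
  if (!is.null(dimnames(beta))) dimnames(m) <- dimnames(beta)
  m
}

#' @rdname beta_to_m
#' @param m M-value (finite; vector or matrix).
#' @export
m_to_beta <- function(m) {
  b <- 1 / (1 + 2 ^ (-m))
  if (!is.null(dimnames(m))) dimnames(b) <- dimnames(m)
  b
}

# Exact nonnegative sum-to-one least squares in few dimensions.
# Enumerates support subsets; for the optimal support the equality-
# constrained KKT solution coincides with the global constrained optimum,
# so the feasible subset solution with minimal objective is exact.
simplex_lsq <- function(A, b) {
  k <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    ns <- length(S)
    K <- rbind(cbind(2 * AtA[S, S, drop = FALSE], rep(1, ns)),
               c(rep(1, ns), 0))
    rhs <- c(2 * Atb[S], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    f <- sol[seq_len(ns)]
    if (any(f < -1e-10)) next
    full <- numeric(k)
    full[S] <- pmax(f, 0)
    full <- full / sum(full)
    obj <- sum((A %*% full - b)^2)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- full
    }
  }
  if (is.null(best)) stop("constrained least squares failed", call. = FALSE)
  best
}

#' Reference-based blood cell deconvolution
#'
#' Estimates the leukocyte composition of a bulk methylome by constrained
#' least squares: the sample's beta profile is modelled as a mixture of the
#' cell-type reference beta profiles with non-negative fractions summing to
#' one. With five cell types the simplex-constrained optimum is computed
#' exactly by support enumeration.
#'
#' @param sample_beta Named numeric vector (or probes x samples matrix) of
#'   beta values; names/rownames are probe IDs covering the panel probes.
#' @param panel A [cell_reference_panel()].
#' @return Named fraction vector (or samples x cell-types matrix) on the
#'   probability simplex.
#' @export
estimate_cell_fractions <- function(sample_beta, panel) {
  stopifnot(inherits(panel, "cell_reference_panel"))
  A <- panel$reference_betas
  if (is.null(dim(sample_beta))) {
    sample_beta <- matrix(sample_beta, ncol = 1,
                          dimnames = list(names(sample_beta), "sample"))
  }
  miss <- setdiff(rownames(A), rownames(sample_beta))
  if (length(miss)) {
    stop("panel probes absent from sample: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  B <- sample_beta[rownames(A), , drop = FALSE]
  usable <- rowSums(is.na(B)) == 0 & rowSums(is.na(A)) == 0
  if (sum(usable) < 2 * ncol(A)) {
    stop("fewer than 2 usable panel probes per cell type (",
         sum(usable), " usable for ", ncol(A), " cell types)", call. = FALSE)
  }
  A <- A[usable, , drop = FALSE]
  B <- B[usable, , drop = FALSE]
  out <- t(apply(B, 2, function(b) simplex_lsq(A, b)))
  colnames(out) <- panel$cell_types
  if (nrow(out) == 1) out[1, ] else out
}

#' Complete a cell-count table by methylome-based imputation
#'
#' Samples with measured differential counts pass through unchanged
#' (flagged `"measured"`); samples without counts get fractions estimated
#' from their methylome by [estimate_cell_fractions()] (flagged
#' `"imputed"`).
#'
#' @param measured data.frame with column `sample_id` plus one column per
#'   cell type in [blood_cell_types()], rows normalized to fractions; may
#'   omit samples.
#' @param beta Probes x samples beta matrix covering all samples.
#' @param panel A [cell_reference_panel()].
#' @return data.frame with `sample_id`, the five fraction columns and
#'   `source` in `{"measured", "imputed"}`, one row per sample (column
#'   order of `beta`).
#' @export
fill_cell_fractions <- function(measured, beta, panel) {
  cts <- blood_cell_types()
  samples <- colnames(beta)
  known <- intersect(samples, measured$sample_id)
  unknown <- setdiff(samples, known)
  orphan <- setdiff(measured$sample_id, samples)
  if (length(orphan)) {
    stop("measured samples absent from methylome: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", length(samples))
  names(rows) <- samples
  for (s in known) {
    r <- measured[measured$sample_id == s, cts, drop = FALSE]
    f <- as.numeric(r[1, ])
    if (any(f < 0) || abs(sum(f) - 1) > 1e-6) {
      stop("measured fractions for sample ", s, " are not normalized", call. = FALSE)
    }
    rows[[s]] <- data.frame(sample_id = s, as.list(stats::setNames(f, cts)),
                            source = "measured", check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (length(unknown)) {
    est <- estimate_cell_fractions(beta[, unknown, drop = FALSE], panel)
    if (is.null(dim(est))) est <- matrix(est, nrow = 1, dimnames = list(unknown, cts))
    for (s in unknown) {
      rows[[s]] <- data.frame(sample_id = s,
                              as.list(stats::setNames(est[s, ], cts)),
                              source = "imputed", check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[samples])
  rownames(out) <- NULL
  out
}

#' Normalization hook
#'
#' Functional normalization of raw intensities is out of scope (it needs
#' IDAT/control-probe data); this identity hook marks the seam where a
#' normalized beta matrix can be substituted.
#'
#' @param beta Probes x samples beta matrix.
#' @return `beta`, unchanged.
#' @export
normalize_betas <- function(beta) beta
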