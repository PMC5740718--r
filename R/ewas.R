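#' Regression design matrix for the pair-difference model
#'
#' Columns: intercept, the transformed lung-function predictor, pair-level
#' sex and age, and the differenced covariates (BMI, pack-years, smoking
#' status, and four of the five cell-fraction differences). Neutrophils —
#' the most abundant type — are the reference cell type: the five fraction
#' differences sum to zero, so one must be dropped to keep the design full
#' rank.
#'
#' @param design A `pair_design` from [build_pair_design()].
#' @return Numeric matrix, pairs x coefficients, with column names.
#' @export
design_matrix <- function(design) {
  cell_cols <- paste0("d_", setdiff(blood_cell_types(), "neutrophils"))
  cols <- c("predictor", "sex", "age", "d_bmi", "d_pack_years",
            "d_smoking_status", cell_cols)
  miss <- setdiff(cols, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(design)[, cols]))
  rownames(X) <- design$pair_id
  X
}

check_full_rank <- function(qr_x, X) {
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
}

#' Fit the pair-difference regression for one probe
#'
#' Ordinary least squares of the intra-pair M-value difference on the
#' transformed intra-pair lung-function difference and covariates. The
#' reported coefficient is the lung-function predictor's: the expected
#' change in intra-pair M-value difference per unit (possibly
#' log-transformed) intra-pair z-difference. The p-value is two-sided from
#' a t distribution with `n_pairs - rank` degrees of freedom.
#'
#' @param delta_m Numeric vector of intra-pair M differences, aligned with
#'   the rows of `design`.
#' @param design A `pair_design`, or a numeric design matrix as produced by
#'   [design_matrix()] (first column intercept, second the predictor).
#' @return list with `estimate`, `se`, `t`, `p`, `n_pairs`, `df`. A
#'   zero-residual (deterministic) fit returns `se = 0`, `t = Inf` sign-ed
#'   by the estimate and the sentinel `p = 0`, with a warning.
#' @export
fit_probe <- function(delta_m, design) {
  X <- if (is.matrix(design)) design else design_matrix(design)
  if (length(delta_m) != nrow(X)) {
    stop("delta_m length (", length(delta_m), ") does not match design rows (",
         nrow(X), ")", call. = FALSE)
  }
  if (nrow(X) < ncol(X) + 1) {
    stop("need at least ", ncol(X) + 1, " pairs for ", ncol(X), " coefficients",
         call. = FALSE)
  }
  qr_x <- qr(X)
  check_full_rank(qr_x, X)
  coefs <- qr.coef(qr_x, delta_m)
  res <- delta_m - drop(X %*% coefs)
  df <- nrow(X) - qr_x$rank
  rss <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- 2L  # predictor column
  est <- coefs[[j]]
  if (rss < 1e-24 * max(1, sum(delta_m^2))) {
    warning("zero-residual fit: deterministic relationship, returning p = 0 sentinel",
            call. = FALSE)
    return(list(estimate = est, se = 0, t = sign(est) * Inf, p = 0,
                n_pairs = nrow(X), df = df))
  }
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- est / se
  list(estimate = est, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), n_pairs = nrow(X), df = df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort p ascending, set `adj_(i) = min_{j >= i} p_(j) * n / j`
#' capped at 1, return in input order. `n_tests` may exceed the number of
#' supplied p-values, which reproduces published adjusted values for the
#' top-ranked probes of a genome-wide scan from the printed p-values alone.
#'
#' @param p P-values in (0, 1].
#' @param n_tests Total number of tests behind the adjustment (default
#'   `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(1e-4, 0.02, 0.9))
#' # top-probe FDR of a 453,014-probe scan from its two smallest p-values:
#' bh_adjust(c(7.14e-8, 1.36e-7), n_tests = 453014)
bh_adjust <- function(p, n_tests = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (n_tests < length(p)) stop("n_tests must be >= length(p)", call. = FALSE)
  o <- order(p)
  m <- length(p)
  ranked <- p[o] * n_tests / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the observed association chi-square statistics
#' (1-df quantiles of the p-values) divided by the theoretical chi-square
#' median 0.4549...; values near 1 indicate calibrated tests. Diagnostic
#' companion to the Q-Q plot.
#'
#' @param p Non-empty vector of p-values.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p) {
  if (!length(p)) stop("p-values must be non-empty", call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Direction label of the inferior twin's methylation
#'
#' The regression estimate is the superior-minus-inferior M difference per
#' unit predictor. A negative estimate therefore means the inferior twin is
#' relatively hyper-methylated at that probe ("Hyper"); a positive estimate
#' means relatively hypo-methylated ("Hypo"). A zero estimate has no
#' direction and yields NA with a warning.
#'
#' @param estimate Regression estimate(s), M-value units.
#' @return Character vector in `{"Hyper", "Hypo", NA}`.
#' @export
classify_direction <- function(estimate) {
  if (any(estimate == 0, na.rm = TRUE)) {
    warning("zero estimate(s): direction undefined, returning NA", call. = FALSE)
  }
  ifelse(estimate < 0, "Hyper", ifelse(estimate > 0, "Hypo", NA_character_))
}

#' Genome-wide pair-difference EWAS
#'
#' Fits the pair-difference model of [fit_probe()] for every probe, sharing
#' one QR decomposition of the design across probes, then adds BH-adjusted
#' p-values, direction labels and the genomic inflation factor.
#'
#' @param delta_m_matrix Probes x pairs matrix from
#'   [difference_methylation()]; column names must match `design$pair_id`.
#' @param design A `pair_design` from [build_pair_design()].
#' @param significant_p Genome-wide significance threshold (default 1e-6).
#' @param table_p Reporting threshold (default 1e-5).
#' @return An `ewas_run`: list with `results` (data.frame probe, estimate,
#'   se, t, p, fdr, direction, n_pairs, metric, flavour), `n_tests`,
#'   `lambda`, `thresholds`, `metric`, `flavour`.
#' @export
run_ewas <- function(delta_m_matrix, design, significant_p = 1e-6, table_p = 1e-5) {
  X <- design_matrix(design)
  if (is.null(colnames(delta_m_matrix)) ||
      !identical(colnames(delta_m_matrix), rownames(X))) {
    stop("delta_m_matrix columns must align with design pair_ids", call. = FALSE)
  }
  Y <- t(delta_m_matrix)  # pairs x probes
  qr_x <- qr(X)
  check_full_rank(qr_x, X)
  coefs <- qr.coef(qr_x, Y)
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- nrow(X) - qr_x$rank
  rss <- colSums(res^2)
  xtx_inv_22 <- chol2inv(qr.R(qr_x))[2, 2]
  est <- coefs[2, ]
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv_22)
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  degenerate <- rss < 1e-24 * pmax(1, colSums(Y^2))
  if (any(degenerate)) {
    warning(sum(degenerate), " probe(s) with zero residual: p = 0 sentinel",
            call. = FALSE)
    se[degenerate] <- 0
    tval[degenerate] <- sign(est[degenerate]) * Inf
    p[degenerate] <- 0
  }
  p_for_adjust <- pmax(p, .Machine$double.xmin)
  results <- data.frame(
    probe = rownames(delta_m_matrix),
    estimate = unname(est), se = unname(se), t = unname(tval), p = unname(p),
    fdr = unname(bh_adjust(p_for_adjust)),
    direction = suppressWarnings(unname(classify_direction(est))),
    n_pairs = nrow(X),
    metric = attr(design, "metric") %||% NA_character_,
    flavour = attr(design, "flavour") %||% NA_character_,
    stringsAsFactors = FALSE
  )
  structure(list(results = results, n_tests = nrow(results),
                 lambda = genomic_inflation(p_for_adjust),
                 thresholds = c(significant = significant_p, table = table_p),
                 metric = attr(design, "metric"), flavour = attr(design, "flavour")),
            class = "ewas_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ewas_run <- function(x, ...) {
  hits <- select_hits(x)
  cat("ewas_run:", x$n_tests, "probes |", x$metric, "(", x$flavour, ") | lambda",
      sprintf("%.3f", x$lambda), "|", nrow(hits$significant), "significant,",
      nrow(hits$table), "at table threshold\n")
  invisible(x)
}

#' Select significant and table-worthy probes
#'
#' Strict thresholds: significant at `p < 1e-6` (the genome-wide EWAS
#' threshold), presented in tables at `p < 1e-5`. The significant set is a
#' subset of the table set.
#'
#' @param run An `ewas_run`.
#' @return list of data.frames `significant` and `table` (rows of
#'   `run$results`), each sorted by p.
#' @export
select_hits <- function(run) {
  stopifnot(inherits(run, "ewas_run"))
  r <- run$results
  tab <- r[r$p < run$thresholds[["table"]], , drop = FALSE]
  tab <- tab[order(tab$p), , drop = FALSE]
  sig <- tab[tab$p < run$thresholds[["significant"]], , drop = FALSE]
  rownames(tab) <- rownames(sig) <- NULL
  list(significant = sig, table = tab)
}

#' Annotate result rows with the probe manifest
#'
#' Pure join on probe ID adding chromosome, position (hg19 bp), most
#' proximal gene (NA when intergenic) and CpG-island context.
#'
#' @param rows data.frame with a `probe` column.
#' @param manifest Manifest data.frame (`probe_id`, `chromosome`, `bp`,
#'   `gene`, `cgi_feature`).
#' @return `rows` with the four annotation columns appended.
#' @export
annotate_hits <- function(rows, manifest) {
  i <- match(rows$probe, manifest$probe_id)
  if (anyNA(i)) {
    stop("probes absent from manifest: ",
         paste(rows$probe[is.na(i)], collapse = ", "), call. = FALSE)
  }
  for (col in c("chromosome", "bp", "gene", "cgi_feature")) {
    rows[[col]] <- manifest[[col]][i]
  }
  rows
}

#' Manhattan and Q-Q plot data tables
#'
#' @param run An `ewas_run`.
#' @param manifest Probe manifest for genome positions.
#' @return list of data.frames: `manhattan` (probe, chromosome, bp,
#'   neg_log10_p) sorted by genome position, and `qq` (expected vs observed
#'   -log10 p; expected quantiles `-log10((i - 0.5)/n)` for ranks i).
#' @export
manhattan_qq_tables <- function(run, manifest) {
  stopifnot(inherits(run, "ewas_run"))
  ann <- annotate_hits(run$results[, c("probe", "p")], manifest)
  chr_num <- suppressWarnings(as.integer(ann$chromosome))
  chr_ord <- ifelse(is.na(chr_num),
                    23L + match(ann$chromosome, c("X", "Y")), chr_num)
  man <- data.frame(probe = ann$probe, chromosome = ann$chromosome, bp = ann$bp,
                    neg_log10_p = -log10(pmax(ann$p, .Machine$double.xmin)),
                    stringsAsFactors = FALSE)
  man <- man[order(chr_ord, ann$bp), , drop = FALSE]
  rownames(man) <- NULL
  n <- nrow(ann)
  qq <- data.frame(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = sort(-log10(pmax(ann$p, .Machine$double.xmin)), decreasing = TRUE)
  )
  list(manhattan = man, qq = qq)
}
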