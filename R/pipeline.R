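#' Matrix TSV I/O
#'
#' Probes as rows with `probe_id` as first column, sample IDs as header —
#' the interchange format for beta / detection-p / bead-count matrices.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulation configuration defaults
#'
#' @param n_probes Array size of the synthetic methylome.
#' @param n_genes Gene universe size of the synthetic manifest.
#' @param na_fraction Intergenic probe fraction.
#' @param planted list of [planted_effect()]s.
#' @param pair_correlation Within-pair shared fraction of residual M
#'   variance.
#' @param n_blacklist Number of cross-reactive (blacklisted) probe IDs.
#' @param n_missing_cell_counts Subjects without measured differential
#'   counts (imputed from the methylome downstream).
#' @param n_sets,geneset_size_range Random gene-set collection shape.
#' @param spike_genes Optional genes for a spiked set.
#' @param cohort A [cohort_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000, n_genes = 800, na_fraction = 0.2,
                       planted = list(), pair_correlation = 0.5,
                       n_blacklist = 20, n_missing_cell_counts = 6,
                       n_sets = 50, geneset_size_range = c(5, 50),
                       spike_genes = NULL, cohort = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  structure(list(n_probes = n_probes, n_genes = n_genes,
                 na_fraction = na_fraction, planted = planted,
                 pair_correlation = pair_correlation,
                 n_blacklist = n_blacklist,
                 n_missing_cell_counts = n_missing_cell_counts,
                 n_sets = n_sets, geneset_size_range = geneset_size_range,
                 spike_genes = spike_genes, cohort = cohort, seed = seed),
            class = "sim_config")
}

# independent sub-streams from a master seed, kept below 2^31
derive_seed <- function(seed, offset) (as.integer(seed) * 97L + offset * 1009L) %% 2147483587L + 1L

#' Generate a complete synthetic input bundle in memory
#'
#' Runs the full synthetic-data module: cohort, LMS table, manifest, cell
#' reference panel, methylomes with QC metadata, blacklist, measured cell
#' counts with gaps, and a gene-set collection (spiked with the planted
#' probes' proximal genes when requested).
#'
#' @param config A [sim_config()].
#' @return list with `cohort`, `lms`, `manifest`, `panel`, `dataset`,
#'   `cell_fractions` (truth), `measured_counts` (with gaps), `genesets`,
#'   `truth`, `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  lms <- generate_lms_table()
  cohort <- generate_cohort(config$cohort, lms)
  manifest <- generate_manifest(config$n_probes, config$n_genes,
                                config$na_fraction, seed = derive_seed(config$seed, 1L))
  panel <- generate_cell_panel(manifest, seed = derive_seed(config$seed, 2L))

  planted <- config$planted
  # symbolic placement: planted entries may name probes by manifest index
  planted <- lapply(planted, function(e) {
    if (is.numeric(e$probe_id)) e$probe_id <- manifest$probe_id[e$probe_id]
    e
  })
  set.seed(derive_seed(config$seed, 3L))
  planted_ids <- vapply(planted, `[[`, "", "probe_id")
  blacklist <- sample(setdiff(manifest$probe_id, planted_ids),
                      min(config$n_blacklist, config$n_probes - length(planted_ids)))
  meth <- generate_methylomes(cohort, panel, manifest, planted = planted,
                              pair_correlation = config$pair_correlation,
                              blacklist = blacklist,
                              seed = derive_seed(config$seed, 4L))

  set.seed(derive_seed(config$seed, 5L))
  cf <- meth$cell_fractions
  cts <- blood_cell_types()
  noisy <- as.matrix(cf[, cts]) + matrix(stats::rnorm(nrow(cf) * 5, 0, 0.005),
                                         nrow(cf), 5)
  noisy <- pmax(noisy, 1e-4)
  noisy <- noisy / rowSums(noisy)
  measured <- data.frame(sample_id = cf$sample_id, noisy, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (config$n_missing_cell_counts > 0) {
    drop <- sample(nrow(measured), min(config$n_missing_cell_counts, nrow(measured)))
    measured <- measured[-drop, , drop = FALSE]
  }

  spike <- config$spike_genes
  if (is.null(spike) && length(planted)) {
    spike <- unique(stats::na.omit(manifest$gene[match(planted_ids, manifest$probe_id)]))
    if (!length(spike)) spike <- NULL
  }
  genesets <- generate_genesets(unique(stats::na.omit(manifest$gene)),
                                n_sets = config$n_sets,
                                size_range = config$geneset_size_range,
                                spike = spike, seed = derive_seed(config$seed, 6L))
  list(cohort = cohort, lms = lms, manifest = manifest, panel = panel,
       dataset = meth$dataset, cell_fractions = meth$cell_fractions,
       measured_counts = measured, genesets = genesets, truth = meth$truth,
       config = config)
}

#' Write a synthetic input bundle to disk
#'
#' Emits the eight pipeline input files (phenotypes, beta matrix,
#' detection-p matrix, bead-count matrix, manifest, blacklist, LMS table,
#' gene sets) plus the cell-count table, the reference panel and a
#' true-parameter JSON sidecar for tests.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly; the bundle is
#'   returned in attribute `bundle`.
#' @export
twinewas_simulate <- function(config = sim_config(), out_dir) {
  b <- simulate_bundle(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- c(
    phenotypes = p("phenotypes.tsv"), beta = p("beta.tsv"),
    detection_p = p("detection_p.tsv"), bead_count = p("bead_count.tsv"),
    manifest = p("manifest.tsv"), blacklist = p("blacklist.txt"),
    lms = p("lms.tsv"), genesets = p("genesets.gmt"),
    cell_counts = p("cell_counts.tsv"), cell_panel = p("cell_panel.tsv"),
    truth = p("truth.json")
  )
  write_tsv(as.data.frame(b$cohort), files["phenotypes"])
  write_matrix_tsv(b$dataset$beta, files["beta"])
  write_matrix_tsv(b$dataset$detection_p, files["detection_p"])
  write_matrix_tsv(b$dataset$bead_count, files["bead_count"])
  write_tsv(b$manifest, files["manifest"])
  writeLines(b$dataset$blacklist, files["blacklist"])
  write_lms_table(b$lms, files["lms"])
  write_gmt(b$genesets, files["genesets"], attr(b$genesets, "descriptions"))
  write_tsv(b$measured_counts, files["cell_counts"])
  write_matrix_tsv(b$panel$reference_betas, files["cell_panel"])
  jsonlite::write_json(list(seed = b$config$seed, planted = b$truth),
                       files["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  attr(files, "bundle") <- b
  invisible(files)
}

#' Load a pipeline input bundle from disk
#'
#' Inverse of [twinewas_simulate()]: reads the standard file names from a
#' directory into the in-memory bundle structure.
#'
#' @param dir Directory holding the input files.
#' @return list with `cohort`, `lms`, `manifest`, `panel`, `dataset`,
#'   `measured_counts`, `genesets`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- utils::read.delim(p("manifest.tsv"), stringsAsFactors = FALSE,
                                colClasses = c(chromosome = "character"))
  beta <- read_matrix_tsv(p("beta.tsv"))
  blacklist <- if (file.exists(p("blacklist.txt"))) {
    bl <- readLines(p("blacklist.txt")); bl[nzchar(bl)]
  } else character()
  dataset <- methylation_dataset(
    beta = beta,
    detection_p = read_matrix_tsv(p("detection_p.tsv")),
    bead_count = read_matrix_tsv(p("bead_count.tsv")),
    manifest = manifest, blacklist = blacklist)
  panel <- cell_reference_panel(read_matrix_tsv(p("cell_panel.tsv")))
  measured <- if (file.exists(p("cell_counts.tsv"))) {
    utils::read.delim(p("cell_counts.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else NULL
  list(cohort = utils::read.delim(p("phenotypes.tsv"), stringsAsFactors = FALSE),
       lms = read_lms_table(p("lms.tsv")),
       manifest = manifest, panel = panel, dataset = dataset,
       measured_counts = measured,
       genesets = read_gmt(p("genesets.gmt")))
}

sanitize_metric <- function(metric) gsub("[^A-Za-z0-9]+", "_", metric)

#' Run the full six-analysis pipeline
#'
#' Standardization, probe QC, cell-fraction completion, then per metric:
#' pair ordering, design assembly, intra-pair M differencing, genome-wide
#' regression, hit selection and annotation, over-representation analysis
#' on the `p < 1e-5` gene list, and Manhattan/Q-Q tables. All tabular
#' outputs are written under `out_dir` when given, together with a
#' machine-readable run manifest (config hash, per-file MD5 checksums,
#' pair exclusion log).
#'
#' @param bundle In-memory bundle (from [simulate_bundle()] or
#'   [read_bundle()]).
#' @param out_dir Optional output directory.
#' @param metrics Analysis metrics to run (default all six).
#' @param significant_p,table_p EWAS thresholds (strict `<`).
#' @param min_category_size Minimum in-universe gene-set size for
#'   enrichment.
#' @return list of class `twinewas_run`: per-metric list with `design`,
#'   `ewas`, `hits`, `enrichment`, plus `zscores`, `qc_report`,
#'   `cell_fractions`, `universe`.
#' @export
twinewas_run <- function(bundle, out_dir = NULL, metrics = lung_metrics()$metric,
                         significant_p = 1e-6, table_p = 1e-5,
                         min_category_size = 2) {
  zpanel <- standardize_cohort(bundle$cohort, bundle$lms)
  filtered <- qc_filter(bundle$dataset)
  qc_report <- attr(filtered, "qc_report")
  m_matrix <- beta_to_m(filtered$beta)

  measured <- bundle$measured_counts
  if (is.null(measured)) {
    measured <- data.frame(sample_id = character(), stringsAsFactors = FALSE)
    for (ct in blood_cell_types()) measured[[ct]] <- numeric()
  }
  # restrict the reference panel to probes surviving QC before imputation
  panel_sub <- cell_reference_panel(
    bundle$panel$reference_betas[rownames(filtered$beta), , drop = FALSE],
    bundle$panel$cell_types)
  cellfr <- fill_cell_fractions(measured, filtered$beta, panel_sub)

  universe <- sort(unique(stats::na.omit(bundle$manifest$gene)))
  analyses <- list()
  exclusion_log <- list()
  for (metric in metrics) {
    design <- build_pair_design(bundle$cohort, zpanel, cellfr, metric)
    dm <- difference_methylation(m_matrix, design)
    run <- run_ewas(dm, design, significant_p = significant_p, table_p = table_p)
    hits <- select_hits(run)
    hits$significant <- annotate_hits(hits$significant, bundle$manifest)
    hits$table <- annotate_hits(hits$table, bundle$manifest)
    genes <- probes_to_genes(hits$table, bundle$manifest)
    enr <- if (length(genes)) {
      run_enrichment(genes, bundle$genesets, universe,
                     min_size = min_category_size)
    } else {
      suppressWarnings(run_enrichment(character(), bundle$genesets, universe))
    }
    plots <- manhattan_qq_tables(run, bundle$manifest)
    analyses[[metric]] <- list(design = design, ewas = run, hits = hits,
                               hit_genes = genes, enrichment = enr,
                               plots = plots)
    exclusion_log[[metric]] <- attr(design, "exclusions")
  }
  res <- structure(list(analyses = analyses, zscores = zpanel,
                        qc_report = qc_report, cell_fractions = cellfr,
                        universe = universe, exclusions = exclusion_log,
                        thresholds = c(significant = significant_p, table = table_p)),
                   class = "twinewas_run")
  if (!is.null(out_dir)) write_run(res, bundle, out_dir)
  res
}

#' @export
print.twinewas_run <- function(x, ...) {
  cat("twinewas_run:", length(x$analyses), "analyses |",
      x$qc_report$count[x$qc_report$rule == "probes_retained"], "probes after QC\n")
  for (m in names(x$analyses)) {
    a <- x$analyses[[m]]
    cat(sprintf("  %-18s n=%3d pairs, lambda %.3f, %d significant / %d table hits\n",
                m, nrow(a$design), a$ewas$lambda,
                nrow(a$hits$significant), nrow(a$hits$table)))
  }
  invisible(x)
}

write_run <- function(res, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(res$zscores, p("zscores.tsv"))
  write_tsv(res$qc_report, p("qc_report.tsv"))
  write_tsv(res$cell_fractions, p("cell_fractions.tsv"))
  for (m in names(res$analyses)) {
    a <- res$analyses[[m]]
    tag <- sanitize_metric(m)
    write_pair_design(a$design, p(sprintf("design_%s.tsv", tag)))
    results <- annotate_hits(a$ewas$results, bundle$manifest)
    write_tsv(results, p(sprintf("results_%s.tsv", tag)))
    write_tsv(a$hits$table, p(sprintf("hits_%s.tsv", tag)))
    write_tsv(a$enrichment, p(sprintf("enrichment_%s.tsv", tag)))
    write_tsv(a$plots$manhattan, p(sprintf("manhattan_%s.tsv", tag)))
    write_tsv(a$plots$qq, p(sprintf("qq_%s.tsv", tag)))
  }
  excl <- do.call(rbind, lapply(names(res$exclusions), function(m) {
    e <- res$exclusions[[m]]
    if (nrow(e)) cbind(metric = m, e) else NULL
  }))
  if (is.null(excl)) excl <- data.frame(metric = character(), pair_id = character(),
                                        reason = character())
  write_tsv(excl, p("exclusions.tsv"))

  outputs <- setdiff(list.files(out_dir), "run_manifest.json")
  sums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("twinewas")),
    thresholds = as.list(res$thresholds),
    n_analyses = length(res$analyses),
    checksums = as.list(stats::setNames(unname(sums), outputs))
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

fmt_med_range <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x), min(x), max(x))
fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))

#' Summary report of a completed run
#'
#' Demographics per sex (median (min-max), pack-years as mean +/- SD), hit
#' tables in the published column layout (probe, estimate, p, chromosome,
#' bp, gene, CGI feature, direction), and the enrichment tables.
#'
#' @param res A `twinewas_run`.
#' @param bundle The input bundle the run consumed.
#' @return list with `demographics`, `hit_tables` (one data.frame per
#'   metric, possibly header-only) and `enrichment_tables`.
#' @export
twinewas_report <- function(res, bundle) {
  stopifnot(inherits(res, "twinewas_run"))
  coh <- bundle$cohort
  demo <- do.call(rbind, lapply(split(coh, coh$sex), function(d) {
    data.frame(
      sex = d$sex[1],
      n_subjects = nrow(d),
      n_pairs = length(unique(d$pair_id)),
      age_years = fmt_med_range(d$age_followup),
      followup_years = fmt_med_range(d$followup_years),
      height_cm = fmt_med_range(d$height_followup_cm),
      weight_kg = fmt_med_range(d$weight_followup_kg),
      bmi = fmt_med_range(d$bmi_followup),
      pack_years = fmt_mean_sd(d$pack_years_total),
      stringsAsFactors = FALSE)
  }))
  rownames(demo) <- NULL
  hit_cols <- c("probe", "estimate", "p", "chromosome", "bp", "gene",
                "cgi_feature", "direction")
  hits <- lapply(res$analyses, function(a) {
    t <- a$hits$table
    if (!nrow(t)) {
      out <- as.data.frame(stats::setNames(rep(list(character(0)), length(hit_cols)),
                                           hit_cols))
    } else out <- t[, hit_cols]
    out
  })
  enr <- lapply(res$analyses, function(a) a$enrichment)
  list(demographics = demo, hit_tables = hits, enrichment_tables = enr)
}
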