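#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 40), call. = FALSE)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (gene symbols).
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map hit probes to their unique proximal genes
#'
#' Probes passing the reporting threshold are annotated with their most
#' proximal gene; intergenic probes (NA gene) are dropped and duplicate
#' genes collapse to one entry. The resulting list's length is the `k` of
#' the over-representation test.
#'
#' @param hits data.frame of hit rows with a `probe` column (a `gene`
#'   column is used if present, otherwise looked up in `manifest`).
#' @param manifest Probe manifest.
#' @return Character vector of unique gene symbols (possibly empty).
#' @export
probes_to_genes <- function(hits, manifest) {
  if (!nrow(hits)) return(character())
  if (!"gene" %in% names(hits)) hits <- annotate_hits(hits, manifest)
  genes <- hits$gene
  unique(genes[!is.na(genes) & genes != "NA" & nzchar(genes)])
}

#' Hypergeometric over-representation test for one gene set
#'
#' Against a universe of `N` array genes with `C` of them in the category,
#' drawing the `k` hit genes gives an overlap `O`; the test reports the
#' upper tail `rawP = P(X >= O)` of the hypergeometric distribution, the
#' expected overlap `E = k*C/N` and the enrichment ratio `R = O/E`. `O = 0`
#' returns `rawP = 1`.
#'
#' @param hit_genes Character vector of hit gene symbols (all must be in
#'   `universe`).
#' @param category Character vector of the gene set's members (members
#'   outside the universe are ignored).
#' @param universe Character vector of array genes (the reference universe).
#' @return One-row data.frame: `C`, `O`, `E`, `R`, `rawP`, `genes`
#'   (semicolon-joined contributing genes).
#' @export
ora_test <- function(hit_genes, category, universe) {
  N <- length(unique(universe))
  if (N == 0) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  hit_genes <- unique(hit_genes)
  outside <- setdiff(hit_genes, universe)
  if (length(outside)) {
    stop("hit gene(s) outside the universe (misconfigured universe): ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  cat_u <- intersect(unique(category), universe)
  C <- length(cat_u)
  k <- length(hit_genes)
  overlap <- intersect(cat_u, hit_genes)
  O <- length(overlap)
  E <- k * C / N
  R <- if (E > 0) O / E else 0
  rawP <- if (O == 0) 1 else stats::phyper(O - 1, C, N - C, k, lower.tail = FALSE)
  data.frame(C = C, O = O, E = E, R = R, rawP = rawP,
             genes = paste(sort(overlap), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_test()] for every set with at least `min_size` members in the
#' universe, BH-adjusts within the collection (each database is its own
#' multiplicity family) and sorts by rawP. Rows are flagged `reported` at
#' `adjP < 0.1` and `significant` at `adjP < 0.05`, matching the
#' presentation convention for enrichment tables.
#'
#' @param hit_genes Character vector of hit genes (may be empty: returns an
#'   empty table with a warning).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Array gene universe.
#' @param min_size Minimum in-universe category size to test (default 2).
#' @return data.frame: `pathway`, `C`, `O`, `E`, `R`, `rawP`, `adjP`,
#'   `reported`, `significant`, `genes`, sorted by rawP.
#' @export
run_enrichment <- function(hit_genes, collection, universe, min_size = 2) {
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  empty <- data.frame(pathway = character(), C = integer(), O = integer(),
                      E = numeric(), R = numeric(), rawP = numeric(),
                      adjP = numeric(), reported = logical(),
                      significant = logical(), genes = character(),
                      stringsAsFactors = FALSE)
  if (!length(hit_genes)) {
    warning("empty hit-gene list: no enrichment performed", call. = FALSE)
    return(empty)
  }
  universe <- unique(universe)
  sizes <- vapply(collection, function(s) length(intersect(unique(s), universe)),
                  integer(1))
  testable <- names(collection)[sizes >= max(1, min_size)]
  if (!length(testable)) return(empty)
  rows <- lapply(testable, function(nm) {
    cbind(pathway = nm, ora_test(hit_genes, collection[[nm]], universe),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjP <- bh_adjust(out$rawP)
  out$reported <- out$adjP < 0.1
  out$significant <- out$adjP < 0.05
  out <- out[order(out$rawP, out$pathway),
             c("pathway", "C", "O", "E", "R", "rawP", "adjP",
               "reported", "significant", "genes")]
  rownames(out) <- NULL
  out
}
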