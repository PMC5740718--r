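test_that("ora_test equals exhaustive enumeration for all small configurations", {
  for (N in 2:12) {
    universe <- sprintf("g%02d", seq_len(N))
    for (k in 1:min(N, 6)) {
      subsets <- utils::combn(N, k)
      for (C in 0:N) {
        category <- universe[seq_len(C)]
        # three hit configurations: front-loaded, back-loaded, mixed
        hit_sets <- list(
          universe[seq_len(k)],
          universe[(N - k + 1):N],
          if (k == 1) universe[1] else c(universe[1], universe[N:(N - k + 2)])
        )
        for (hits in hit_sets) {
          O <- length(intersect(hits, category))
          row <- ora_test(hits, category, universe)
          expect_equal(row$O, O)
          expect_equal(row$C, C)
          expect_equal(row$E, k * C / N)
          expect_equal(row$rawP, ora_oracle(N, C, k, O), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the N=10, C=4, k=3, O=2 case returns exactly 1/3", {
  universe <- letters[1:10]
  category <- letters[1:4]
  hits <- c("a", "b", "j")  # overlap 2
  row <- ora_test(hits, category, universe)
  expect_equal(row$O, 2)
  expect_equal(row$rawP, 1 / 3, tolerance = 1e-12)
  expect_equal(row$rawP, ora_oracle(10, 4, 3, 2))
})

test_that("ora_test conventions: O = 0, category = universe, R = O/E", {
  universe <- letters[1:10]
  hits <- c("a", "b", "c")
  none <- ora_test(hits, c("x1", "x2"), universe)  # members outside universe
  expect_equal(none$C, 0); expect_equal(none$O, 0)
  expect_equal(none$rawP, 1); expect_equal(none$R, 0)
  all_row <- ora_test(hits, universe, universe)
  expect_equal(all_row$O, 3); expect_equal(all_row$E, 3)
  expect_equal(all_row$R, 1); expect_equal(all_row$rawP, 1)
  mid <- ora_test(hits, letters[1:5], universe)
  expect_equal(mid$R, mid$O / mid$E)
  expect_error(ora_test(c("a", "zz"), letters[1:5], universe), "zz")
})

test_that("rawP is monotone decreasing in O for fixed (N, C, k)", {
  universe <- sprintf("g%02d", 1:12)
  category <- universe[1:6]
  pvals <- sapply(0:4, function(O) {
    hits <- c(universe[seq_len(O)], universe[7:12][seq_len(4 - O)])
    ora_test(hits, category, universe)$rawP
  })
  expect_true(all(diff(pvals) < 0))
})

test_that("run_enrichment adjusts within the collection and flags thresholds", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:5]
  # single set: adjP = rawP
  one <- run_enrichment(hits, list(SET1 = universe[1:10]), universe)
  expect_equal(one$adjP, one$rawP)
  # two disjoint sets partitioning the universe: O values sum to k
  part <- run_enrichment(hits, list(A = universe[1:40], B = universe[41:100]),
                         universe)
  expect_equal(sum(part$O), length(hits))
  # sorted by rawP, BH over tested sets, flags consistent
  set.seed(12)
  sets <- c(list(GOOD = universe[1:6]),
            lapply(1:8, function(i) universe[sample.int(100, 20)]))
  names(sets)[-1] <- paste0("RND", 1:8)
  res <- run_enrichment(hits, sets, universe)
  expect_equal(res$pathway[1], "GOOD")
  expect_true(all(diff(res$rawP) >= 0))
  expect_equal(res$adjP, bh_oracle(res$rawP))
  expect_equal(res$reported, res$adjP < 0.1)
  expect_equal(res$significant, res$adjP < 0.05)
  # min_size filter removes sets with < 2 universe members
  filt <- run_enrichment(hits, list(TINY = universe[1], OK = universe[1:4]),
                         universe)
  expect_equal(filt$pathway, "OK")
  # empty hit list warns and returns empty
  expect_warning(empty <- run_enrichment(character(), sets, universe), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("probes_to_genes drops intergenic probes and deduplicates", {
  man <- data.frame(probe_id = paste0("cg", 1:6), chromosome = "1",
                    bp = 1:6, gene = c("A", NA, "B", "B", NA, "C"),
                    cgi_feature = "Body-shore", stringsAsFactors = FALSE)
  hits <- data.frame(probe = paste0("cg", 1:6), stringsAsFactors = FALSE)
  expect_setequal(probes_to_genes(hits, man), c("A", "B", "C"))
  all_na <- data.frame(probe = c("cg2", "cg5"), stringsAsFactors = FALSE)
  expect_equal(probes_to_genes(all_na, man), character())
  expect_equal(probes_to_genes(hits[0, , drop = FALSE], man), character())
})

test_that("published-scale screen: k=7, C=32, O=2 rawP brackets 7.87e-5", {
  # the real universe size is unprinted; for plausible array universes the
  # hypergeometric tail must bracket the published value
  for (N in c(15000, 18000)) {
    universe <- sprintf("u%05d", seq_len(N))
    category <- universe[1:32]
    hits <- c(universe[1:2], universe[100:104])  # k = 7, O = 2
    row <- ora_test(hits, category, universe)
    expect_equal(row$C, 32); expect_equal(row$O, 2)
    expect_gt(row$rawP, 5e-5)
    expect_lt(row$rawP, 1.2e-4)
  }
})

test_that("GMT round trip preserves sets and members stay in the universe", {
  genes <- sprintf("GENE%03d", 1:60)
  sets <- generate_genesets(genes, n_sets = 10, size_range = c(3, 20), seed = 5)
  expect_length(sets, 10)
  expect_true(all(unlist(sets) %in% genes))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path, attr(sets, "descriptions"))
  back <- read_gmt(path)
  for (nm in names(sets)) expect_equal(back[[nm]], sets[[nm]])
  # empty collection is a valid file
  empty <- generate_genesets(genes, n_sets = 0, seed = 5)
  expect_length(empty, 0)
  p2 <- tempfile(fileext = ".gmt")
  write_gmt(empty, p2)
  expect_length(read_gmt(p2), 0)
  expect_error(generate_genesets(character()), "empty")
  expect_error(generate_genesets(genes, size_range = c(5, 100)), "exceeds")
})
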