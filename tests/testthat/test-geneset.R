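# Gene-set loading, Venn intersections, gene-level p-values and
# Benjamini-Yekutieli adjustment.

test_that("gene sets load with normalisation, dedup and round-trip", {
  path <- withr::local_tempfile()
  writeLines(c("# header comment", "Fto", "FTO", "cat  ", ""), path)
  expect_message(gs <- load_gene_set(path, "toy"), "1 duplicate")
  expect_setequal(gs$symbols, c("FTO", "CAT"))
  out <- withr::local_tempfile()
  write_gene_set(gs, out)
  expect_identical(suppressMessages(load_gene_set(out))$symbols, gs$symbols)
  empty <- withr::local_tempfile()
  writeLines("# only a comment", empty)
  expect_error(load_gene_set(empty), "no symbols")
})

test_that("set intersections produce exact Venn counts", {
  rep <- intersect_sets(gene_set(c("X", "Y", "Z"), "study"),
                        gene_set(c("X", "Y"), "a"),
                        gene_set(c("Y", "W"), "b"))
  expect_equal(rep$n_a, 2)
  expect_equal(rep$n_b, 1)
  expect_equal(rep$in_both, "Y")
  disjoint <- intersect_sets(gene_set("Q"), gene_set("R"), gene_set("S"))
  expect_equal(disjoint$n_a + disjoint$n_b + disjoint$n_triple, 0)

  # brute-force triple-loop oracle on random set triples
  set.seed(41)
  pool <- sprintf("G%03d", 1:40)
  for (i in 1:50) {
    s <- sample(pool, 15); a <- sample(pool, 12); b <- sample(pool, 12)
    rep <- intersect_sets(gene_set(s), gene_set(a), gene_set(b))
    brute <- sum(vapply(pool, function(g)
      (g %in% s) && (g %in% a) && (g %in% b), logical(1)))
    expect_equal(rep$n_triple, brute)
    # symmetry in a,b for the triple overlap
    rep2 <- intersect_sets(gene_set(s), gene_set(b), gene_set(a))
    expect_identical(rep$in_both, rep2$in_both)
  }
})

test_that("the bundled demo sets share the expected ten-gene core", {
  sleep <- suppressMessages(load_gene_set(
    system.file("extdata", "sleep_genes_demo.txt", package = "swagmeth")))
  obesity <- suppressMessages(load_gene_set(
    system.file("extdata", "obesity_genes_demo.txt", package = "swagmeth")))
  core <- c("CDH4", "NR3C2", "ACTG1", "COG5", "CAT", "HDAC4", "FTO",
            "DOK7", "OCLN", "ATXN1")
  rep <- intersect_sets(gene_set(c(core, "SOMETHINGELSE"), "study"),
                        sleep, obesity)
  expect_equal(rep$in_both, sort(core))
})

test_that("Benjamini-Yekutieli matches hand computation and p.adjust", {
  adj <- benjamini_yekutieli(c(0.01, 0.02, 0.03))
  expect_equal(adj, c(0.055, 0.055, 0.055), tolerance = 1e-12)
  expect_equal(benjamini_yekutieli(0.2), 0.2)  # c(1) = 1
  expect_true(all(benjamini_yekutieli(c(0.9, 0.95)) <= 1))
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:40) {
    p <- runif(sample(1:30, 1))
    mine <- benjamini_yekutieli(p)
    expect_equal(mine, p.adjust(p, "BY"), tolerance = 1e-12)
    # dominates BH which dominates raw
    expect_true(all(mine >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(mine >= p - 1e-12))
    # monotone in the sorted order
    expect_true(all(diff(mine[order(p)]) >= -1e-12))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(benjamini_yekutieli(p[perm]), mine[perm], tolerance = 1e-12)
  }
})

test_that("per-gene p-values collapse probe p-values by min or Fisher", {
  res <- structure(data.frame(
    probe_id = c("cg1", "cg2", "cg3"),
    p_value = c(0.01, 0.2, 0.03)), class = c("diff_result", "data.frame"))
  ann <- data.frame(probe_id = c("cg1", "cg2", "cg3"))
  ann$genes <- I(list(c("A", "B"), "A", "B"))
  gp <- gene_level_p(res, ann, method = "min")
  expect_equal(gp[["A"]], 0.01)
  expect_equal(gp[["B"]], 0.01)
  gpf <- gene_level_p(res, ann, method = "fisher")
  expect_equal(gpf[["A"]],
               pchisq(-2 * (log(0.01) + log(0.2)), 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("overlap reports carry BY-adjusted p-values for the shared genes", {
  study <- gene_set(c("A", "B", "C", "D"))
  rep <- intersect_sets(study, gene_set(c("A", "B", "X")),
                        gene_set(c("A", "B", "Y")),
                        gene_pvals = c(A = 0.01, B = 0.02, C = 0.5, D = 0.9))
  expect_equal(rep$triple_pvals$gene, c("A", "B"))
  expect_true(all(rep$triple_pvals$p_by >= rep$triple_pvals$p))
  expect_true(all(rep$triple_pvals$p_by <= 1))
  # widening the family to all study genes cannot shrink adjusted values
  rep_all <- intersect_sets(study, gene_set(c("A", "B", "X")),
                            gene_set(c("A", "B", "Y")),
                            gene_pvals = c(A = 0.01, B = 0.02, C = 0.5, D = 0.9),
                            by_family = "all")
  expect_true(all(rep_all$triple_pvals$p_by >= rep$triple_pvals$p_by - 1e-12))
})
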