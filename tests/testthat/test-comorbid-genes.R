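test_that("gene categorization follows the membership rule table", {
  com <- edge_tbl(list(c("g1", "g2", "g3", "g4")))
  aa <- edge_tbl(list(c("g1", "g3")))
  bb <- edge_tbl(list(c("g2", "g3")))
  out <- categorize_comorbid_genes(com, aa, bb)
  got <- stats::setNames(out$category, out$gene)
  expect_equal(got[["G1"]], "disease_a_specific")
  expect_equal(got[["G2"]], "disease_b_specific")
  expect_equal(got[["G3"]], "shared")
  expect_equal(got[["G4"]], "distinct")
  expect_equal(attr(out, "distinct_fraction"), 0.25)
})

test_that("empty single-disease edge sets make every gene distinct", {
  com <- edge_tbl(list(c("g1", "g2")))
  empty <- com[0, ]
  out <- categorize_comorbid_genes(com, empty, empty)
  expect_true(all(out$category == "distinct"))
  expect_equal(attr(out, "distinct_fraction"), 1.0)
})

test_that("categorization equals the set-algebra oracle on random instances", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      genes <- paste0("G", 1:200)
      U <- sample(genes, 80)
      A <- sample(genes, sample(0:60, 1))
      B <- sample(genes, sample(0:60, 1))
      out <- categorize_comorbid_genes(edge_tbl(list(U)), edge_tbl(list(A)),
                                       edge_tbl(list(B)))
      want <- oracle_categorize(sort(U), A, B)
      expect_identical(stats::setNames(out$category, out$gene), want)
    }
  })
})

test_that("category counts ignore edge and gene ordering", {
  com1 <- dplyr::bind_rows(edge_tbl(list(c("g1", "g2"))),
                           edge_tbl(list(c("g3", "g4")), node_a = "a:k3:1"))
  com2 <- com1[2:1, ]
  com2$shared_genes <- lapply(com2$shared_genes, rev)
  aa <- edge_tbl(list(c("g1", "g3")))
  t1 <- table(categorize_comorbid_genes(com1, aa, com1[0, ])$category)
  t2 <- table(categorize_comorbid_genes(com2, aa, com2[0, ])$category)
  expect_equal(t1, t2)
})

test_that("geometric-mean ranking keeps each gene's strongest edge", {
  universe <- paste0("G", 1:6)
  Wa <- matrix(c(4, 1, 0, 9, 2, 5), ncol = 1,
               dimnames = list(universe, NULL))
  Wb <- matrix(c(9, 100, 3, 4, 0, 5), ncol = 1,
               dimnames = list(universe, NULL))
  sa <- manual_sigset("a", Wa)
  sb <- manual_sigset("b", Wb, disease = "t2d", class = "T2D")
  edges <- edge_tbl(list(c("G1", "G2", "G4", "G5")),
                    node_a = "a:k1:1", node_b = "b:k1:1")
  tab <- rank_genes_for_term(edges, list(sa, sb), universe, top_k = 3)
  # geometric means: G1 sqrt(36)=6, G2 sqrt(100)=10, G4 sqrt(36)=6, G5 0
  expect_equal(tab$gene[1], "G2")
  expect_equal(tab$geometric_mean[1], 10)
  expect_equal(sort(tab$gene[2:3]), c("G1", "G4"))
  expect_equal(tab$geometric_mean[2:3], c(6, 6))

  # zero exposure annihilates the mean and ranks last
  tab4 <- rank_genes_for_term(edges, list(sa, sb), universe, top_k = 10)
  expect_equal(tab4$geometric_mean[tab4$gene == "G5"], 0)
  expect_equal(tab4$gene[nrow(tab4)], "G5")

  # a gene on two edges keeps the larger geometric mean
  edges2 <- dplyr::bind_rows(
    edges,
    edge_tbl(list(c("G1")), node_a = "a:k1:1", node_b = "b:k1:1"))
  tab5 <- rank_genes_for_term(edges2, list(sa, sb), universe, top_k = 10)
  expect_equal(sum(tab5$gene == "G1"), 1)

  expect_warning(empty <- rank_genes_for_term(edges, list(sa, sb), c("ZZZ")),
                 "do not occur")
  expect_equal(nrow(empty), 0)
})

test_that("gwas overlay labels by set membership", {
  out <- gwas_overlay(c("a1", "b1", "ab", "none"),
                      gwas_a = c("A1", "AB"), gwas_b = c("B1", "AB"),
                      label_a = "gwas_scz", label_b = "gwas_t2d")
  expect_equal(out$gwas_label, c("gwas_scz", "gwas_t2d", "gwas_shared", "none"))
})

test_that("gwas overlay equals an independent membership oracle", {
  withr::with_seed(66, {
    for (rep in 1:10) {
      genes <- paste0("G", sample(1:500, 100))
      ga <- paste0("G", sample(1:500, 50))
      gb <- paste0("G", sample(1:500, 50))
      got <- gwas_overlay(genes, ga, gb)$gwas_label
      want <- vapply(genes, function(g) {
        a <- g %in% ga; b <- g %in% gb
        if (a && b) "gwas_shared" else if (a) "gwas_a" else if (b) "gwas_b" else "none"
      }, "")
      expect_identical(got, unname(want))
    }
  })
})

test_that("GWAS gene lists read from plain text and two-column TSV", {
  f1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("brca1", "TP53", "", "tp53"), f1)
  expect_setequal(read_gwas_genes(f1), c("BRCA1", "TP53"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GCK\t12", "KCNJ11\t3"), f2)
  expect_setequal(read_gwas_genes(f2), c("GCK", "KCNJ11"))
})
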