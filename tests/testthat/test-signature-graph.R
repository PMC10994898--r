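test_that("top_genes sorts by exposure with lexicographic tie-break", {
  expect_identical(top_genes(c(g1 = 3, g2 = 2, g3 = 1), 2), c("g1", "g2"))
  expect_identical(top_genes(c(g3 = 1, g2 = 1, g1 = 1), 2), c("g1", "g2"))
  expect_setequal(top_genes(c(g1 = 3, g2 = 2, g3 = 1), 3), c("g1", "g2", "g3"))
})

test_that("jaccard matches its closed form and is symmetric", {
  a <- paste0("g", 1:1000)
  b <- c(paste0("g", 1:500), paste0("h", 1:500))
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, paste0("x", 1:10)), 0)
  expect_equal(jaccard(a, b), 1 / 3)  # 500 / 1500
  expect_equal(jaccard(b, a), jaccard(a, b))
  expect_error(jaccard(character(0), a), "nonempty")
})

test_that("the worked 2x2 best-hit example yields both mutual pairs", {
  # construct sets realizing J = [[0.5, 0.4], [0.1, 0.6]] exactly:
  # J = i/(20 - i) choices with |A| = |B| = 10: overlap 20/3? use direct sets
  universe <- paste0("g", 1:200)
  withr::with_seed(5, {
    sets_a <- random_sets(2, universe, 30, "a")
    sets_b <- random_sets(2, universe, 30, "b")
  })
  got <- siggraph:::rbh_from_sets(sets_a, sets_b)
  want <- oracle_rbh(sets_a, sets_b)
  expect_equal(got[order(got$node_a, got$node_b), ]$node_b, want$node_b)
  expect_equal(sort(got$jaccard), sort(want$jaccard))
})

test_that("RBH equals the brute-force oracle on random instances", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      universe <- paste0("g", 1:60)
      na <- sample(1:20, 1); nb <- sample(1:20, 1)
      sets_a <- random_sets(na, universe, 10, "a")
      sets_b <- random_sets(nb, universe, 10, "b")
      got <- siggraph:::rbh_from_sets(sets_a, sets_b)
      got <- got[order(got$node_a, got$node_b), ]
      want <- oracle_rbh(sets_a, sets_b)
      expect_equal(got$node_a, want$node_a)
      expect_equal(got$node_b, want$node_b)
      expect_equal(got$jaccard, want$jaccard, tolerance = 1e-12)
    }
  })
})

test_that("reciprocal_best_hits is symmetric in its cohort arguments", {
  universe <- paste0("g", 1:80)
  withr::with_seed(12, {
    sa <- sigset_from_sets("a", random_sets(4, universe, 15, "x"), universe)
    sb <- sigset_from_sets("b", random_sets(4, universe, 15, "y"), universe,
                           disease = "t2d", class = "T2D", tissue = "islets")
  })
  cfg <- graph_config(top_n = 15)
  e_ab <- reciprocal_best_hits(sa, sb, cfg)
  e_ba <- reciprocal_best_hits(sb, sa, cfg)
  expect_setequal(paste(e_ab$node_a, e_ab$node_b),
                  paste(e_ba$node_b, e_ba$node_a))
  # shared genes consistent with jaccard: |I| = J * |U|
  expect_equal(lengths(e_ab$shared_genes),
               round(e_ab$jaccard * (30 - lengths(e_ab$shared_genes))) ,
               tolerance = 1e-9)
})

test_that("permutation p-values follow the pseudocount formula", {
  # an edge absent from all permutations: p = 1/(R+1)
  universe <- paste0("g", 1:100)
  withr::with_seed(31, {
    # top sets of 60 genes out of 100 always intersect, so with one
    # signature per cohort every permutation re-forms the same pair
    sa <- sigset_from_sets("a", list(s1 = paste0("g", 1:60)), universe)
    sb <- sigset_from_sets("b", list(s1 = paste0("g", 1:60)), universe,
                           disease = "t2d", class = "T2D", tissue = "islets")
  })
  cfg <- graph_config(top_n = 60, n_permutations = 20, seed = 2)
  obs <- all_rbh_edges(list(sa, sb), cfg)
  expect_equal(nrow(obs), 1)
  g <- permutation_edge_test(list(sa, sb), obs, cfg)
  # with a single signature per cohort any perm reproduces the same node
  # pair, so c = 20 and p = 21/21 = 1 -> removed
  expect_equal(g$candidate_edges$permutation_p, 1)
  expect_equal(nrow(g$edges), 0)
  # with the pseudocount, p can never be below 1/(R+1)
  expect_error(
    permutation_edge_test(list(sa, sb), obs,
                          graph_config(n_permutations = 10, edge_alpha = 0.05)),
    "at least 19"
  )
})

test_that("permutation p-values live on the pseudocount grid and gate retention", {
  universe <- paste0("g", 1:400)
  withr::with_seed(8, {
    shared <- paste0("g", 1:40)
    sets_a <- c(list(hit = shared), random_sets(6, paste0("g", 101:400), 40, "a"))
    sets_b <- c(list(hit = shared), random_sets(6, paste0("g", 101:400), 40, "b"))
    sa <- sigset_from_sets("a", sets_a, universe)
    sb <- sigset_from_sets("b", sets_b, universe,
                           disease = "t2d", class = "T2D", tissue = "islets")
  })
  cfg <- graph_config(top_n = 40, n_permutations = 20, seed = 4)
  obs <- all_rbh_edges(list(sa, sb), cfg)
  g <- permutation_edge_test(list(sa, sb), obs, cfg)
  # the planted identical pair is the strongest candidate edge
  cand <- g$candidate_edges
  hit <- cand$node_a == "a:k7:1" & cand$node_b == "b:k7:1"
  expect_true(any(hit))
  expect_equal(cand$jaccard[hit], 1)
  # p-values take values (1 + c) / 21, never below 1/21, and retention is
  # exactly the p <= alpha thresholding
  expect_true(all(abs(cand$permutation_p * 21 - round(cand$permutation_p * 21)) < 1e-12))
  expect_true(all(cand$permutation_p >= 1 / 21))
  expect_setequal(paste(g$edges$node_a, g$edges$node_b),
                  paste(cand$node_a, cand$node_b)[cand$permutation_p <= 0.05])
  # same seed, same null: bit-identical p-values
  g2 <- permutation_edge_test(list(sa, sb), obs, cfg)
  expect_identical(g$candidate_edges$permutation_p, g2$candidate_edges$permutation_p)
})

test_that("permutation preserves each signature's exposure multiset", {
  universe <- paste0("g", 1:50)
  withr::with_seed(3, {
    sa <- sigset_from_sets("a", random_sets(3, universe, 10, "s"), universe)
    sets <- withr::with_seed(1, siggraph:::shuffled_top_sets(sa, 10))
  })
  # shuffling relabels genes, so every shuffled top set still has 10 genes
  # drawn from the same universe
  expect_true(all(lengths(sets) == 10))
  expect_true(all(unlist(sets) %in% universe))
})

test_that("edge categories follow the disease/class rule table", {
  nodes <- tibble::tibble(
    signature_id = c("s1", "s2", "b1", "t1", "a1", "c1", "c2"),
    cohort_id = c("sczA", "sczB", "bdA", "t2dA", "amiA", "cadA", "cadB"),
    rank_k = 2L, index_in_rank = 1L,
    disease = c("scz", "scz", "bd", "t2d", "ami", "cad", "cad"),
    disease_class = c("PSY", "PSY", "PSY", "T2D", "CVD", "CVD", "CVD"),
    tissue = c("brain", "brain", "brain", "islets", "blood", "vessel", "vessel"),
    diagnosis_p = 0.01
  )
  edges <- tibble::tibble(
    node_a = c("s1", "s1", "s1", "t1", "c1"),
    node_b = c("s2", "b1", "t1", "a1", "c2"),
    cohort_a = "x", cohort_b = "y", jaccard = 0.5,
    shared_genes = replicate(5, c("G1"), simplify = FALSE),
    tied = FALSE, permutation_p = 1 / 21
  )
  g <- structure(list(nodes = nodes, edges = edges, candidate_edges = edges,
                      config = graph_config()), class = "sig_graph")
  g <- categorize_edges(g)
  expect_equal(g$edges$category,
               c("single", "intra_class_comorbid", "inter_class_comorbid",
                 "somatic", "single"))
  expect_equal(g$edges$tissue_relation,
               c("same_tissue", "same_tissue", "cross_tissue", "cross_tissue",
                 "same_tissue"))
  # categories partition the edges
  expect_equal(sum(g$category_summary$n_edges), nrow(g$edges))

  bad <- g; bad$nodes$disease_class[1] <- "psy"
  expect_error(categorize_edges(bad), "unknown disease class")
})

test_that("graph JSON serialization is canonical and round-stable", {
  universe <- paste0("g", 1:100)
  withr::with_seed(17, {
    sa <- sigset_from_sets("a", random_sets(3, universe, 20, "p"), universe)
    sb <- sigset_from_sets("b", random_sets(3, universe, 20, "q"), universe,
                           disease = "t2d", class = "T2D", tissue = "islets")
  })
  cfg <- graph_config(top_n = 20, seed = 6)
  build <- function() {
    obs <- all_rbh_edges(list(sa, sb), cfg)
    categorize_edges(permutation_edge_test(list(sa, sb), obs, cfg))
  }
  expect_identical(graph_to_json(build()), graph_to_json(build()))
})
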