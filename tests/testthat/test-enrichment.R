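test_that("the full-overlap toy has the exact combinatorial p-value", {
  uni <- paste0("g", 1:20)
  tab <- hypergeometric_enrich(uni[1:5], uni, list(t1 = uni[1:5]),
                               min_size = 1)
  # drawing 5 genes from 20, all 5 marked: p = 1 / C(20, 5)
  expect_equal(tab$raw_p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(tab$overlap_size, 5)
  expect_identical(tab$overlap_genes[[1]], sort(toupper(uni[1:5])))
})

test_that("zero overlap gives p = 1", {
  uni <- paste0("g", 1:20)
  tab <- hypergeometric_enrich("g1", uni, list(t1 = "g2"), min_size = 1)
  expect_equal(tab$raw_p, 1)
  expect_equal(tab$adjusted_p, 1)
})

test_that("BH adjustment follows the step-up formula and is monotone", {
  # craft three terms whose raw p are ordered; check adjusted = p * m / rank
  # with monotonicity via the textbook example (0.01, 0.02, 0.03) -> all 0.03
  raw <- c(0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(raw, "BH"), c(0.03, 0.03, 0.03))
  withr::with_seed(14, {
    uni <- paste0("g", 1:100)
    coll <- lapply(1:8, function(i) sample(uni, 20))
    names(coll) <- paste0("t", 1:8)
    tab <- hypergeometric_enrich(sample(uni, 15), uni, coll, min_size = 1)
  })
  expect_true(all(tab$adjusted_p >= tab$raw_p - 1e-15))
  expect_true(all(tab$adjusted_p <= 1))
  ord <- order(tab$raw_p)
  expect_true(all(diff(tab$adjusted_p[ord]) >= -1e-15))
  expect_equal(tab$adjusted_p, stats::p.adjust(tab$raw_p, "BH"))
})

test_that("query genes outside the universe are dropped with a warning", {
  uni <- paste0("g", 1:30)
  expect_warning(
    tab <- hypergeometric_enrich(c(uni[1:5], "alien"), uni,
                                 list(t1 = uni[1:10]), min_size = 1),
    "outside the universe")
  expect_equal(tab$overlap_size, 5)
  expect_error(hypergeometric_enrich("g1", character(0), list(t1 = "g1")),
               "empty universe")
  expect_error(hypergeometric_enrich("g1", uni, list()), "empty gene-set")
})

test_that("null queries are calibrated: ~5% of terms at raw p < 0.05", {
  withr::with_seed(20, {
    uni <- paste0("g", 1:400)
    coll <- lapply(1:40, function(i) sample(uni, 40))
    names(coll) <- paste0("t", 1:40)
    frac <- mean(replicate(50, {
      tab <- hypergeometric_enrich(sample(uni, 40), uni, coll, min_size = 1)
      mean(tab$raw_p < 0.05)
    }))
  })
  # hypergeometric p-values are discrete and conservative, so the observed
  # fraction sits at or below the nominal level
  expect_lt(frac, 0.08)
  expect_gt(frac, 0.005)
})

test_that("GMT files round-trip with size bounds", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("small\tdesc\tg1\tg2",
               "ok\tangiogenesis\tg1\tg2\tg3\tg4",
               "dup\t\tg1\tg1\tg2\tg3"), f)
  coll <- suppressMessages(read_gmt(f, min_size = 3, max_size = 10))
  expect_named(coll, c("ok", "dup"))
  expect_equal(coll$dup, c("G1", "G2", "G3"))  # upper-cased, de-duplicated
  expect_equal(attr(coll, "descriptions")[["ok"]], "angiogenesis")
})

test_that("term_edge_summary counts significant edges per term", {
  tabs <- tibble::tibble(
    edge = c("e1", "e1", "e2", "e3", "e3"),
    term = c("t1", "t2", "t1", "t1", "t2"),
    adjusted_p = c(0.01, 0.2, 0.04, 0.001, 0.03)
  )
  out <- term_edge_summary(tabs, alpha = 0.05)
  expect_equal(out$n_edges[out$term == "t1"], 3)
  expect_equal(out$n_edges[out$term == "t2"], 1)
  # independent recount
  sig_rows <- tabs[tabs$adjusted_p < 0.05, ]
  recount <- vapply(unique(sig_rows$term), function(t) {
    length(unique(sig_rows$edge[sig_rows$term == t]))
  }, integer(1))
  expect_equal(stats::setNames(out$n_edges, out$term)[names(recount)], recount)
  inc <- attr(out, "incidence")
  expect_equal(sum(inc), 4)
  # nothing significant -> empty summary
  expect_equal(nrow(term_edge_summary(tabs, alpha = 1e-6)), 0)
})

test_that("enrich_edges tests each retained edge against the cohort universe", {
  universe <- paste0("g", 1:100)
  withr::with_seed(41, {
    shared <- paste0("g", 1:30)
    sa <- sigset_from_sets("a", c(list(hit = shared),
                                  random_sets(3, paste0("g", 41:100), 30, "a")),
                           universe)
    sb <- sigset_from_sets("b", c(list(hit = shared),
                                  random_sets(3, paste0("g", 41:100), 30, "b")),
                           universe, disease = "t2d", class = "T2D")
  })
  cfg <- graph_config(top_n = 30, seed = 9)
  g <- permutation_edge_test(list(sa, sb), all_rbh_edges(list(sa, sb), cfg), cfg)
  g$edges <- g$candidate_edges  # enrichment plumbing is what is under test
  coll <- list(planted = paste0("G", 1:30), off = paste0("G", 71:100))
  tab <- enrich_edges(g, coll, sigsets = list(sa, sb), min_size = 1)
  planted_rows <- tab[tab$term == "planted", ]
  expect_true(any(planted_rows$significant))
})
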