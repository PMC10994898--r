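#' Graph-building configuration
#'
#' @param top_n Number of top exposed genes per signature used for Jaccard
#'   similarity (default 1000). Only a few genes carry a signature's signal;
#'   the weight of most genes is noise, so similarity is computed on the top
#'   of the exposure ranking.
#' @param n_permutations Number of label-shuffled graphs for the edge null
#'   (default 20).
#' @param edge_alpha Edges with permutation occurrence probability at or
#'   below this are kept (default 0.05; with 20 permutations only edges never
#'   seen under shuffling survive).
#' @param seed Integer seed for the permutations.
#' @param match_on How an observed edge is looked up in a permuted graph:
#'   `"signature_pair"` (default, conservative: the identical node pair must
#'   recur) or `"cohort_pair"` (looser: any edge between the two cohorts
#'   counts).
#' @return A `graph_config` list.
#' @export
graph_config <- function(top_n = 1000L, n_permutations = 20L,
                         edge_alpha = 0.05, seed = 1L,
                         match_on = c("signature_pair", "cohort_pair")) {
  stopifnot(top_n >= 1, n_permutations >= 1, edge_alpha > 0, edge_alpha <= 1)
  structure(list(top_n = as.integer(top_n),
                 n_permutations = as.integer(n_permutations),
                 edge_alpha = edge_alpha, seed = as.integer(seed),
                 match_on = match.arg(match_on)),
            class = "graph_config")
}

#' Top exposed genes of a signature
#'
#' @param gene_exposures Named nonnegative numeric vector (names = gene
#'   identifiers).
#' @param top_n How many genes to return; must not exceed the gene count.
#' @return Character vector of the `top_n` gene identifiers with the largest
#'   exposures, in descending exposure order; exposure ties are broken by
#'   ascending gene label so the selection is deterministic.
#' @export
#' @examples
#' top_genes(c(g1 = 3, g2 = 2, g3 = 1), 2)  # "g1" "g2"
top_genes <- function(gene_exposures, top_n) {
  stopifnot(!is.null(names(gene_exposures)), top_n >= 1,
            top_n <= length(gene_exposures))
  ord <- order(-gene_exposures, names(gene_exposures), method = "radix")
  names(gene_exposures)[ord[seq_len(top_n)]]
}

#' Jaccard similarity of two gene sets
#'
#' @param set_a,set_b Nonempty character vectors (treated as sets).
#' @return `|A intersect B| / |A union B|`, in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))  # 1/3
jaccard <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("jaccard() requires nonempty sets", call. = FALSE)
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  inter <- length(intersect(set_a, set_b))
  inter / (length(set_a) + length(set_b) - inter)
}

# top-N gene sets for all signatures of a set, as a named list
top_sets <- function(sigset, top_n) {
  if (top_n > nrow(sigset$W)) {
    stop(sprintf("top_n = %d exceeds gene count %d in cohort %s",
                 top_n, nrow(sigset$W), sigset$cohort_id), call. = FALSE)
  }
  genes <- rownames(sigset$W)
  ids <- sigset$signatures$signature_id
  stats::setNames(
    lapply(seq_along(ids), function(j) {
      ord <- order(-sigset$W[, j], genes, method = "radix")
      genes[ord[seq_len(top_n)]]
    }),
    ids
  )
}

# pairwise Jaccard matrix between two lists of equal-size gene sets,
# computed through binary membership matrices over the union universe
jaccard_matrix <- function(sets_a, sets_b) {
  universe <- unique(c(unlist(sets_a, use.names = FALSE),
                       unlist(sets_b, use.names = FALSE)))
  Ma <- vapply(sets_a, function(s) universe %in% s, logical(length(universe)))
  Mb <- vapply(sets_b, function(s) universe %in% s, logical(length(universe)))
  Ma <- matrix(as.numeric(Ma), ncol = length(sets_a))
  Mb <- matrix(as.numeric(Mb), ncol = length(sets_b))
  inter <- crossprod(Ma, Mb)
  sizes_a <- colSums(Ma); sizes_b <- colSums(Mb)
  un <- outer(sizes_a, sizes_b, "+") - inter
  J <- inter / un
  dimnames(J) <- list(names(sets_a), names(sets_b))
  J
}

# RBH edges between two named lists of top-N gene sets; ties kept
rbh_from_sets <- function(sets_a, sets_b) {
  J <- jaccard_matrix(sets_a, sets_b)
  J[J == 0] <- NA  # zero similarity carries no information
  if (all(is.na(J))) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          jaccard = numeric()))
  }
  # a row/column that is all-NA (no nonzero similarity) yields -Inf here and
  # is masked to NA below
  row_best <- suppressWarnings(apply(J, 1, max, na.rm = TRUE))
  col_best <- suppressWarnings(apply(J, 2, max, na.rm = TRUE))
  row_best[!is.finite(row_best)] <- NA
  col_best[!is.finite(col_best)] <- NA
  hit <- which(!is.na(J) &
                 J == rep(row_best, times = ncol(J)) &
                 J == rep(col_best, each = nrow(J)),
               arr.ind = TRUE)
  tibble::tibble(
    node_a = rownames(J)[hit[, 1]],
    node_b = colnames(J)[hit[, 2]],
    jaccard = J[hit]
  )
}

#' Reciprocal best hits between two cohorts' signatures
#'
#' For every signature in cohort A, its best match in cohort B is the
#' signature with the highest Jaccard similarity between top-`top_n` gene
#' sets (and vice versa); an edge is emitted exactly when the choice is
#' mutual. Zero-similarity candidates are discarded before matching. Exact
#' Jaccard ties are all kept (and flagged), so a tie cannot silently drop a
#' legitimate match.
#'
#' @param sigs_a,sigs_b `sig_set` objects from distinct cohorts (typically
#'   after [filter_signatures()]).
#' @param cfg A [graph_config()].
#' @return Tibble of candidate edges: `node_a`, `node_b`, `cohort_a`,
#'   `cohort_b`, `jaccard`, `shared_genes` (list-column: intersection of the
#'   two top-N sets), `tied` (TRUE when the node participates in a tied
#'   multiple best hit).
#' @export
reciprocal_best_hits <- function(sigs_a, sigs_b, cfg = graph_config()) {
  stopifnot(inherits(sigs_a, "sig_set"), inherits(sigs_b, "sig_set"))
  if (sigs_a$cohort_id == sigs_b$cohort_id) {
    stop("reciprocal best hits require two distinct cohorts", call. = FALSE)
  }
  if (nrow(sigs_a$signatures) == 0 || nrow(sigs_b$signatures) == 0) {
    return(empty_edge_tbl())
  }
  sets_a <- top_sets(sigs_a, cfg$top_n)
  sets_b <- top_sets(sigs_b, cfg$top_n)
  edges <- rbh_from_sets(sets_a, sets_b)
  if (nrow(edges) == 0) return(empty_edge_tbl())
  edges$cohort_a <- sigs_a$cohort_id
  edges$cohort_b <- sigs_b$cohort_id
  edges$shared_genes <- purrr::map2(edges$node_a, edges$node_b, function(a, b) {
    sort(intersect(sets_a[[a]], sets_b[[b]]))
  })
  edges$tied <- duplicated(edges$node_a) | duplicated(edges$node_a, fromLast = TRUE) |
    duplicated(edges$node_b) | duplicated(edges$node_b, fromLast = TRUE)
  edges[, c("node_a", "node_b", "cohort_a", "cohort_b", "jaccard",
            "shared_genes", "tied")]
}

empty_edge_tbl <- function() {
  tibble::tibble(node_a = character(), node_b = character(),
                 cohort_a = character(), cohort_b = character(),
                 jaccard = numeric(), shared_genes = list(), tied = logical())
}

#' Observed RBH edges across all cohort pairs
#'
#' @param cohort_sets List of `sig_set` objects (one per cohort).
#' @param cfg A [graph_config()].
#' @return Tibble of candidate edges over all unordered cohort pairs.
#' @export
all_rbh_edges <- function(cohort_sets, cfg = graph_config()) {
  n <- length(cohort_sets)
  if (n < 2) return(empty_edge_tbl())
  pairs <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    reciprocal_best_hits(cohort_sets[[pairs[1, p]]], cohort_sets[[pairs[2, p]]], cfg)
  })
}

#' Permutation test of candidate edges
#'
#' Builds `n_permutations` null graphs: within every signature, the
#' assignment of exposure values to gene labels is shuffled (the exposure
#' multiset is preserved), top-N sets are recomputed and reciprocal best
#' hits are rebuilt. An observed edge's occurrence probability is
#' \deqn{p = (1 + c) / (1 + R)} where `c` counts the permutations in which
#' the same signature pair (or, with `match_on = "cohort_pair"`, any edge
#' between the two cohorts) is again an RBH edge, and `R` is the number of
#' permutations. Edges with `p <= edge_alpha` are retained; with the default
#' 20 permutations this keeps exactly the edges never re-formed under
#' shuffling (p = 1/21).
#'
#' @param cohort_sets List of filtered `sig_set` objects, the same ones the
#'   observed edges were computed from.
#' @param observed_edges Candidate edge tibble from [all_rbh_edges()].
#' @param cfg A [graph_config()].
#' @return A `sig_graph` object: `nodes` tibble (signature and cohort
#'   annotation), `edges` (retained), `candidate_edges` (all observed with
#'   `permutation_p`), and the `config`.
#' @export
permutation_edge_test <- function(cohort_sets, observed_edges,
                                  cfg = graph_config()) {
  if (1 / (1 + cfg$n_permutations) > cfg$edge_alpha) {
    stop(sprintf(
      "n_permutations = %d cannot reach edge_alpha = %g; need at least %d permutations",
      cfg$n_permutations, cfg$edge_alpha, ceiling(1 / cfg$edge_alpha - 1)),
      call. = FALSE)
  }
  observed_edges <- tibble::as_tibble(observed_edges)
  counts <- integer(nrow(observed_edges))
  if (nrow(observed_edges) > 0) {
    key_obs <- paste(observed_edges$node_a, observed_edges$node_b)
    cohort_key_obs <- paste(observed_edges$cohort_a, observed_edges$cohort_b)
    active_pairs <- unique(observed_edges[, c("cohort_a", "cohort_b")])
    by_cohort <- stats::setNames(cohort_sets,
                                 vapply(cohort_sets, `[[`, "", "cohort_id"))
    withr::with_seed(cfg$seed, {
      for (r in seq_len(cfg$n_permutations)) {
        shuffled <- lapply(by_cohort, shuffled_top_sets, top_n = cfg$top_n)
        perm_edges <- purrr::map_dfr(seq_len(nrow(active_pairs)), function(p) {
          a <- active_pairs$cohort_a[p]; b <- active_pairs$cohort_b[p]
          e <- rbh_from_sets(shuffled[[a]], shuffled[[b]])
          if (nrow(e) > 0) { e$cohort_a <- a; e$cohort_b <- b }
          e
        })
        if (nrow(perm_edges) == 0) next
        if (cfg$match_on == "signature_pair") {
          hit <- key_obs %in% paste(perm_edges$node_a, perm_edges$node_b)
        } else {
          hit <- cohort_key_obs %in% paste(perm_edges$cohort_a, perm_edges$cohort_b)
        }
        counts <- counts + hit
      }
    })
  }
  observed_edges$permutation_p <- (1 + counts) / (1 + cfg$n_permutations)
  retained <- observed_edges[observed_edges$permutation_p <= cfg$edge_alpha, ,
                             drop = FALSE]
  nodes <- purrr::map_dfr(cohort_sets, function(s) {
    tibble::tibble(
      signature_id = s$signatures$signature_id,
      cohort_id = s$cohort_id,
      rank_k = s$signatures$rank_k,
      index_in_rank = s$signatures$index_in_rank,
      disease = s$metadata$disease[1],
      disease_class = s$metadata$disease_class[1],
      tissue = s$metadata$tissue[1],
      diagnosis_p = if ("diagnosis_p" %in% names(s$signatures))
        s$signatures$diagnosis_p else NA_real_
    )
  })
  structure(list(nodes = nodes, edges = retained,
                 candidate_edges = observed_edges, config = cfg),
            class = "sig_graph")
}

# shuffle, within each signature, the assignment of exposure values to gene
# labels; returns the resulting top-N gene sets
shuffled_top_sets <- function(sigset, top_n) {
  genes <- rownames(sigset$W)
  sets <- lapply(seq_len(ncol(sigset$W)), function(j) {
    relabeled <- sample(genes)
    ord <- order(-sigset$W[, j], relabeled, method = "radix")
    relabeled[ord[seq_len(top_n)]]
  })
  stats::setNames(sets, sigset$signatures$signature_id)
}

#' Categorize graph edges by disease relationship
#'
#' Labels every edge with one of four categories: `single` (both endpoints
#' from the same disease), `intra_class_comorbid` (different diseases, same
#' disease class), `inter_class_comorbid` (different classes with a
#' psychiatric endpoint), and `somatic` (different diseases, no psychiatric
#' endpoint); and with `same_tissue`/`cross_tissue`.
#'
#' @param graph A `sig_graph`.
#' @param psy_class The disease-class code denoting psychiatric disorders
#'   (default `"PSY"`).
#' @return The graph with `category` and `tissue_relation` edge columns and a
#'   `category_summary` tibble (counts per category x tissue relation).
#' @export
categorize_edges <- function(graph, psy_class = "PSY") {
  stopifnot(inherits(graph, "sig_graph"))
  nd <- graph$nodes
  if (any(is.na(nd$disease_class) | nd$disease_class == "" |
            nd$disease_class != toupper(nd$disease_class))) {
    bad <- unique(nd$disease_class[is.na(nd$disease_class) |
                                     nd$disease_class == "" |
                                     nd$disease_class != toupper(nd$disease_class)])
    stop("unknown disease class code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  annotate <- function(edges) {
    if (nrow(edges) == 0) {
      edges$category <- character(0); edges$tissue_relation <- character(0)
      return(edges)
    }
    ia <- match(edges$node_a, nd$signature_id)
    ib <- match(edges$node_b, nd$signature_id)
    da <- nd$disease[ia]; db <- nd$disease[ib]
    ca <- nd$disease_class[ia]; cb <- nd$disease_class[ib]
    n_psy <- (ca == psy_class) + (cb == psy_class)
    edges$category <- dplyr::case_when(
      da == db ~ "single",
      ca == cb ~ "intra_class_comorbid",
      n_psy == 1 ~ "inter_class_comorbid",
      TRUE ~ "somatic"
    )
    edges$tissue_relation <- ifelse(nd$tissue[ia] == nd$tissue[ib],
                                    "same_tissue", "cross_tissue")
    edges
  }
  graph$edges <- annotate(graph$edges)
  graph$candidate_edges <- annotate(graph$candidate_edges)
  graph$category_summary <- dplyr::count(
    graph$edges, .data$category, .data$tissue_relation, name = "n_edges"
  )
  graph
}

#' @export
print.sig_graph <- function(x, ...) {
  cat(sprintf("<sig_graph> %d nodes, %d retained edges (%d candidates)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$candidate_edges)))
  if (!is.null(x$category_summary) && nrow(x$category_summary) > 0) {
    print(x$category_summary)
  }
  invisible(x)
}

#' Tidy a signature graph
#'
#' @param x A `sig_graph`.
#' @param ... Unused.
#' @return The retained edge tibble with endpoint annotation joined in and
#'   `shared_genes` summarized as `n_shared_genes`.
#' @export
tidy.sig_graph <- function(x, ...) {
  e <- x$edges
  e$n_shared_genes <- lengths(e$shared_genes)
  e$shared_genes <- NULL
  nd <- x$nodes[, c("signature_id", "disease", "disease_class", "tissue")]
  e <- dplyr::left_join(e, dplyr::rename_with(nd, ~ paste0(.x, "_a")),
                        by = c(node_a = "signature_id_a"))
  dplyr::left_join(e, dplyr::rename_with(nd, ~ paste0(.x, "_b")),
                   by = c(node_b = "signature_id_b"))
}

#' One-row graph summary
#'
#' @param x A `sig_graph`.
#' @param ... Unused.
#' @return Tibble with node, candidate-edge and retained-edge counts.
#' @export
glance.sig_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_candidate_edges = nrow(x$candidate_edges),
    n_edges = nrow(x$edges),
    n_cohorts = length(unique(x$nodes$cohort_id))
  )
}

#' Convert a signature graph to an igraph object
#'
#' @param graph A `sig_graph`.
#' @return An undirected `igraph` graph; node attributes cohort, disease,
#'   class, tissue, rank; edge attributes jaccard, permutation p, category,
#'   shared gene count. Isolated signatures are kept as vertices.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "sig_graph"))
  e <- graph$edges
  edf <- data.frame(from = e$node_a, to = e$node_b,
                    jaccard = e$jaccard,
                    permutation_p = e$permutation_p,
                    category = if ("category" %in% names(e)) e$category else NA,
                    n_shared_genes = lengths(e$shared_genes))
  vdf <- as.data.frame(graph$nodes[, c("signature_id", "cohort_id", "disease",
                                       "disease_class", "tissue", "rank_k")])
  names(vdf)[1] <- "name"
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Serialize a signature graph to canonical JSON
#'
#' Nodes and edges are sorted on their identifiers before writing, so two
#' runs with the same inputs and seed produce byte-identical JSON.
#'
#' @param graph A `sig_graph`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
graph_to_json <- function(graph, path = NULL) {
  nodes <- dplyr::arrange(graph$nodes, .data$signature_id)
  edges <- dplyr::arrange(graph$edges, .data$node_a, .data$node_b)
  json <- jsonlite::toJSON(
    list(nodes = nodes, edges = edges,
         config = graph$config[c("top_n", "n_permutations", "edge_alpha",
                                 "seed", "match_on")]),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Write the edge table as TSV
#'
#' @param graph A `sig_graph`.
#' @param path Output file.
#' @return The flattened edge tibble, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  tab <- tidy(graph)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Run the full signature-graph pipeline
#'
#' Chains normalization, multi-rank NMF, diagnosis filtering, reciprocal
#' best hits, the permutation edge test and edge categorization over a list
#' of cohorts.
#'
#' @param cohorts List of [new_cohort()] objects (raw scale; row-mean
#'   normalization is applied here).
#' @param kmin,kmax Rank range for [mrnmf()].
#' @param alpha Diagnosis-association threshold for [filter_signatures()].
#' @param covariate_names Covariates to adjust for (default: all available).
#' @param cfg A [graph_config()].
#' @param seed Integer seed for the NMF stage (the permutation stage uses
#'   `cfg$seed`).
#' @param max_iter,tol Passed to [nmf_decompose()].
#' @return A categorized `sig_graph`; the filtered signature sets are
#'   attached as attribute `signature_sets`.
#' @export
build_signature_graph <- function(cohorts, kmin = 2L, kmax = 20L,
                                  alpha = 0.05, covariate_names = NULL,
                                  cfg = graph_config(), seed = 1L,
                                  max_iter = 500L, tol = 1e-5) {
  filtered <- lapply(cohorts, function(coh) {
    coh <- normalize_cohort(coh)
    ss <- mrnmf(coh, kmin = kmin, kmax = kmax, seed = seed,
                max_iter = max_iter, tol = tol)
    filter_signatures(ss, alpha = alpha, covariate_names = covariate_names)
  })
  observed <- all_rbh_edges(filtered, cfg)
  graph <- permutation_edge_test(filtered, observed, cfg)
  graph <- categorize_edges(graph)
  attr(graph, "signature_sets") <- filtered
  graph
}
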