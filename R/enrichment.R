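#' Read a gene-set collection in GMT format
#'
#' One term per line: term id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @param min_size,max_size Term-size bounds applied after reading (defaults
#'   10 and 2000, standard over-representation hygiene); set to `0` and `Inf`
#'   to keep everything.
#' @return Named list of upper-cased gene vectors; term descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path, min_size = 10L, max_size = 2000L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  sets <- lapply(parts, function(p) unique(toupper(p[-c(1, 2)])))
  names(sets) <- ids
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    message(sprintf("read_gmt: %d term(s) outside size bounds [%d, %d] dropped",
                    sum(!keep), min_size, max_size))
  }
  out <- sets[keep]
  attr(out, "descriptions") <- stats::setNames(desc[keep], ids[keep])
  out
}

#' Hypergeometric over-representation of a gene set
#'
#' For each term of the collection, tests whether the overlap between the
#' query and the term is larger than expected when drawing `|query|` genes
#' from the universe without replacement (one-sided hypergeometric upper
#' tail), then applies Benjamini-Hochberg adjustment across all tested
#' terms.
#'
#' @param query Gene set of interest (e.g. an edge's shared genes). Genes
#'   outside the universe are dropped with a warning.
#' @param universe Background gene set (e.g. the union of the two cohorts'
#'   measured genes).
#' @param collection Named list of term gene sets (see [read_gmt()]); terms
#'   are intersected with the universe before testing.
#' @param alpha Significance threshold on the adjusted p-value used for the
#'   `significant` column (default 0.05); the full table is always returned.
#' @param min_size,max_size Term-size bounds (after universe intersection).
#' @return An `enrichment_tbl` tibble: `term`, `description`, `term_size`,
#'   `overlap_size`, `overlap_genes` (list-column), `raw_p`, `adjusted_p`,
#'   `significant`; sorted by `raw_p`.
#' @export
#' @examples
#' uni <- paste0("g", 1:20)
#' hypergeometric_enrich(uni[1:5], uni, list(term1 = uni[1:5]),
#'                       min_size = 1)
hypergeometric_enrich <- function(query, universe, collection, alpha = 0.05,
                                  min_size = 10L, max_size = 2000L) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(collection) == 0) stop("empty gene-set collection", call. = FALSE)
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  desc <- attr(collection, "descriptions")
  terms <- lapply(collection, function(s) intersect(unique(toupper(s)), universe))
  sizes <- lengths(terms)
  keep <- sizes >= min_size & sizes <= max_size
  terms <- terms[keep]
  N <- length(universe)
  q <- length(query)
  rows <- purrr::imap_dfr(terms, function(tg, id) {
    ov <- intersect(query, tg)
    m <- length(tg)
    # upper tail P(overlap >= observed) drawing q genes from N with m marked
    p <- stats::phyper(length(ov) - 1, m, N - m, q, lower.tail = FALSE)
    tibble::tibble(term = id,
                   description = if (!is.null(desc) && id %in% names(desc))
                     unname(desc[id]) else "",
                   term_size = m, overlap_size = length(ov),
                   overlap_genes = list(sort(ov)), raw_p = p)
  })
  if (nrow(rows) == 0) {
    out <- tibble::tibble(term = character(), description = character(),
                          term_size = integer(), overlap_size = integer(),
                          overlap_genes = list(), raw_p = numeric(),
                          adjusted_p = numeric(), significant = logical())
    class(out) <- c("enrichment_tbl", class(out))
    return(out)
  }
  rows$adjusted_p <- stats::p.adjust(rows$raw_p, method = "BH")
  rows$significant <- rows$adjusted_p < alpha
  rows <- dplyr::arrange(rows, .data$raw_p, .data$term)
  class(rows) <- c("enrichment_tbl", class(rows))
  rows
}

#' Enrich every edge of a signature graph
#'
#' Runs [hypergeometric_enrich()] on each retained edge's shared genes.
#'
#' @param graph A `sig_graph`.
#' @param collection Gene-set collection ([read_gmt()]).
#' @param universe Background gene set; default is the union of genes ever
#'   seen in the edges' endpoint cohorts, supplied via `sigsets`.
#' @param sigsets Named list of `sig_set` objects (needed only when
#'   `universe` is `NULL`).
#' @param alpha Adjusted-p threshold (default 0.05; correction is per edge).
#' @param ... Passed to [hypergeometric_enrich()].
#' @return Tibble concatenating the per-edge tables with an `edge` id column.
#' @export
enrich_edges <- function(graph, collection, universe = NULL, sigsets = NULL,
                         alpha = 0.05, ...) {
  stopifnot(inherits(graph, "sig_graph"))
  if (is.null(universe)) {
    if (is.null(sigsets)) sigsets <- attr(graph, "signature_sets")
    if (is.null(sigsets)) {
      stop("supply `universe` or `sigsets` to define the background", call. = FALSE)
    }
    universe <- unique(toupper(unlist(lapply(sigsets, function(s) rownames(s$W)),
                                      use.names = FALSE)))
  }
  e <- graph$edges
  purrr::map_dfr(seq_len(nrow(e)), function(i) {
    tab <- hypergeometric_enrich(e$shared_genes[[i]], universe, collection,
                                 alpha = alpha, ...)
    if (nrow(tab) == 0) return(NULL)
    tab$edge <- paste(e$node_a[i], e$node_b[i], sep = "--")
    dplyr::relocate(tab, "edge")
  })
}

#' Summarize a term's recurrence across edges
#'
#' @param tables Per-edge enrichment tibble(s) as returned by
#'   [enrich_edges()] (or a list of such tables, concatenated).
#' @param alpha Adjusted-p threshold defining "enriched in an edge".
#' @return Tibble `term`, `n_edges` (number of edges in which the term is
#'   significant), sorted descending; the binary term x edge incidence
#'   matrix is attached as attribute `incidence`.
#' @export
term_edge_summary <- function(tables, alpha = 0.05) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- dplyr::bind_rows(tables)
  }
  sig <- tables[tables$adjusted_p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- tibble::tibble(term = character(), n_edges = integer())
    attr(out, "incidence") <- matrix(0L, 0, 0)
    return(out)
  }
  out <- sig |>
    dplyr::distinct(.data$term, .data$edge) |>
    dplyr::count(.data$term, name = "n_edges") |>
    dplyr::arrange(dplyr::desc(.data$n_edges), .data$term)
  inc <- table(sig$term, sig$edge) > 0
  attr(out, "incidence") <- matrix(as.integer(inc), nrow = nrow(inc),
                                   dimnames = dimnames(inc))
  out
}
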