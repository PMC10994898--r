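#' Categorize the genes of comorbid edges
#'
#' Compares the union of shared genes over a set of comorbid (disease A -
#' disease B) edges against the shared genes of each disease's
#' single-disease (A-A and B-B) edges. A comorbid gene found only among the
#' A-A edge genes is `disease_a_specific`, only among B-B `disease_b_specific`,
#' in both `shared`, and in neither `distinct` — the distinct genes are the
#' candidate novel comorbidity genes that single-disease analyses cannot
#' see. Gene symbols are upper-cased before any set operation.
#'
#' @param comorbid_edges Edge tibble (rows with a `shared_genes` list-column)
#'   connecting disease A to disease B.
#' @param disease_a_edges,disease_b_edges Single-disease edge tibbles (may be
#'   empty).
#' @param disease_a,disease_b Optional disease code labels for the output.
#' @return A tibble with columns `gene` and `category` (one of
#'   `disease_a_specific`, `disease_b_specific`, `shared`, `distinct`), one
#'   row per gene in the comorbid union; the fraction of distinct genes is
#'   attached as attribute `distinct_fraction`.
#' @export
categorize_comorbid_genes <- function(comorbid_edges, disease_a_edges,
                                      disease_b_edges,
                                      disease_a = "a", disease_b = "b") {
  edge_genes <- function(edges) {
    if (is.null(edges) || nrow(edges) == 0) return(character(0))
    toupper(unique(unlist(edges$shared_genes, use.names = FALSE)))
  }
  U <- edge_genes(comorbid_edges)
  if (length(U) == 0) {
    warning("no shared genes on the comorbid edges; empty categorization",
            call. = FALSE)
    out <- tibble::tibble(gene = character(), category = character())
    attr(out, "distinct_fraction") <- NA_real_
    return(out)
  }
  A <- edge_genes(disease_a_edges)
  B <- edge_genes(disease_b_edges)
  in_a <- U %in% A
  in_b <- U %in% B
  category <- dplyr::case_when(
    in_a & in_b ~ "shared",
    in_a & !in_b ~ "disease_a_specific",
    !in_a & in_b ~ "disease_b_specific",
    TRUE ~ "distinct"
  )
  out <- tibble::tibble(gene = U, category = category,
                        disease_a = disease_a, disease_b = disease_b)
  out <- dplyr::arrange(out, .data$gene)
  attr(out, "distinct_fraction") <- mean(out$category == "distinct")
  out
}

#' Rank a term's genes by geometric-mean exposure across an edge set
#'
#' For every gene of `term_genes` found in an edge's shared genes, the gene's
#' exposure in each endpoint signature gives one point (x = exposure in the
#' disease-A signature, y = exposure in the disease-B signature); genes are
#' ranked by the geometric mean `sqrt(x * y)`. A gene occurring in several
#' edges keeps its maximum geometric mean (and the corresponding exposure
#' pair), preserving its strongest joint response.
#'
#' @param edges Edge tibble whose rows carry `node_a`, `node_b` and
#'   `shared_genes`.
#' @param sigsets Named list of `sig_set` objects covering the edge
#'   endpoints' cohorts (source of the gene exposures).
#' @param term_genes Gene set of interest (e.g. the genes annotated to an
#'   enriched process).
#' @param top_k Number of rows returned (default 30).
#' @return A `ranked_genes` tibble sorted by descending `geometric_mean`,
#'   with columns `gene`, `exposure_a`, `exposure_b`, `geometric_mean`,
#'   `edge` (the edge the maximum came from).
#' @export
rank_genes_for_term <- function(edges, sigsets, term_genes, top_k = 30L) {
  term_genes <- toupper(term_genes)
  by_cohort <- stats::setNames(sigsets,
                               vapply(sigsets, `[[`, "", "cohort_id"))
  node_cohort <- function(id) sub(":k[0-9]+:[0-9]+$", "", id)
  rows <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    genes <- toupper(edges$shared_genes[[i]])
    hit <- intersect(genes, term_genes)
    if (length(hit) == 0) return(NULL)
    sa <- by_cohort[[node_cohort(edges$node_a[i])]]
    sb <- by_cohort[[node_cohort(edges$node_b[i])]]
    ga <- stats::setNames(sa$W[, edges$node_a[i]], toupper(rownames(sa$W)))
    gb <- stats::setNames(sb$W[, edges$node_b[i]], toupper(rownames(sb$W)))
    tibble::tibble(
      gene = hit,
      exposure_a = unname(ga[hit]),
      exposure_b = unname(gb[hit]),
      edge = paste(edges$node_a[i], edges$node_b[i], sep = "--")
    )
  })
  if (nrow(rows) == 0) {
    warning("term genes do not occur in any edge's shared genes", call. = FALSE)
    out <- tibble::tibble(gene = character(), exposure_a = numeric(),
                          exposure_b = numeric(), geometric_mean = numeric(),
                          edge = character())
    class(out) <- c("ranked_genes", class(out))
    return(out)
  }
  rows$geometric_mean <- sqrt(rows$exposure_a * rows$exposure_b)
  out <- rows |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$geometric_mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$geometric_mean), .data$gene) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::relocate("gene", "exposure_a", "exposure_b", "geometric_mean", "edge")
  class(out) <- c("ranked_genes", class(out))
  out
}

#' Overlay GWAS gene lists on a gene list
#'
#' @param genes Character vector of gene symbols.
#' @param gwas_a,gwas_b GWAS risk-gene sets for the two diseases (e.g. genes
#'   mapped from GWAS-catalog associations). Symbols are upper-cased before
#'   comparison.
#' @param label_a,label_b Category labels (defaults `"gwas_a"`, `"gwas_b"`;
#'   use e.g. `"gwas_scz"`, `"gwas_t2d"`).
#' @return Tibble with columns `gene` and `gwas_label` (one of `label_a`,
#'   `label_b`, `"gwas_shared"`, `"none"`).
#' @export
gwas_overlay <- function(genes, gwas_a, gwas_b,
                         label_a = "gwas_a", label_b = "gwas_b") {
  g <- toupper(genes)
  in_a <- g %in% toupper(gwas_a)
  in_b <- g %in% toupper(gwas_b)
  tibble::tibble(
    gene = g,
    gwas_label = dplyr::case_when(
      in_a & in_b ~ "gwas_shared",
      in_a ~ label_a,
      in_b ~ label_b,
      TRUE ~ "none"
    )
  )
}

#' Read a GWAS gene list
#'
#' Accepts plain text with one gene symbol per line, or a two-column TSV
#' (gene, study count) whose second column is ignored.
#'
#' @param path Input file.
#' @return Character vector of upper-cased unique gene symbols.
#' @export
read_gwas_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  genes <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  unique(toupper(trimws(genes)))
}
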