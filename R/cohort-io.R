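#' Cohort container
#'
#' A `sig_cohort` bundles one case-control cohort: a nonnegative gene-by-sample
#' expression matrix and a sample metadata tibble. Gene identifiers are the
#' matrix row names, sample identifiers the column names; the metadata is keyed
#' by `sample_id` and must carry `diagnosis` (`"case"`/`"control"`), a
#' lower-case `disease` code (e.g. `"scz"`, `"t2d"`), an upper-case
#' `disease_class` code (e.g. `"PSY"`, `"CVD"`), and `tissue`. Any further
#' metadata columns are treated as covariates.
#'
#' @param cohort_id Single string naming the cohort.
#' @param expression Numeric matrix, genes in rows and samples in columns, all
#'   values finite and `>= 0`, with unique row names and column names.
#' @param metadata Data frame with one row per sample; must contain columns
#'   `sample_id`, `diagnosis`, `disease`, `disease_class`, `tissue`. The
#'   `sample_id` set must equal the expression column names.
#'
#' @return A `sig_cohort` object: a list with elements `cohort_id`,
#'   `expression`, `metadata` (tibble, covariate columns preserved).
#' @export
#' @examples
#' expr <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'                dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
#' md <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                  diagnosis = c("case", "case", "control"),
#'                  disease = "scz", disease_class = "PSY", tissue = "brain")
#' coh <- new_cohort("demo", expr, md)
new_cohort <- function(cohort_id, expression, metadata) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("`expression` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` needs gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(expression))) {
    dups <- unique(rownames(expression)[duplicated(rownames(expression))])
    stop("duplicate gene identifiers: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(expression) | expression < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "expression must be finite and nonnegative; first offending value %s at gene %s, sample %s",
      format(expression[i, j]), rownames(expression)[i], colnames(expression)[j]),
      call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  required <- c("sample_id", "diagnosis", "disease", "disease_class", "tissue")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    stop("missing required column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  md_ids <- as.character(metadata$sample_id)
  ex_ids <- colnames(expression)
  if (!setequal(md_ids, ex_ids) || anyDuplicated(md_ids)) {
    only_md <- setdiff(md_ids, ex_ids)
    only_ex <- setdiff(ex_ids, md_ids)
    stop("sample identifiers differ between metadata and expression; ",
         "only in metadata: {", paste(only_md, collapse = ", "), "}; ",
         "only in expression: {", paste(only_ex, collapse = ", "), "}",
         call. = FALSE)
  }
  metadata <- metadata[match(ex_ids, md_ids), , drop = FALSE]
  if (!all(metadata$diagnosis %in% c("case", "control"))) {
    stop("`diagnosis` must be 'case' or 'control'", call. = FALSE)
  }
  n_case <- sum(metadata$diagnosis == "case")
  n_ctrl <- sum(metadata$diagnosis == "control")
  if (n_case < 2 || n_ctrl < 2) {
    stop(sprintf("cohort %s needs >= 2 cases and >= 2 controls (got %d/%d)",
                 cohort_id, n_case, n_ctrl), call. = FALSE)
  }
  structure(
    list(cohort_id = cohort_id, expression = expression, metadata = metadata),
    class = "sig_cohort"
  )
}

#' @export
print.sig_cohort <- function(x, ...) {
  cat(sprintf("<sig_cohort> %s: %d genes x %d samples (%d case / %d control), disease %s [%s], tissue %s\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression),
              sum(x$metadata$diagnosis == "case"),
              sum(x$metadata$diagnosis == "control"),
              x$metadata$disease[1], x$metadata$disease_class[1],
              x$metadata$tissue[1]))
  invisible(x)
}

#' Covariate column names of a cohort
#'
#' @param cohort A `sig_cohort`.
#' @return Character vector of metadata columns other than the required ones.
#' @export
cohort_covariates <- function(cohort) {
  setdiff(names(cohort$metadata),
          c("sample_id", "diagnosis", "disease", "disease_class", "tissue"))
}

#' Read one cohort from expression and metadata TSV files
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column and a header row of sample identifiers; the metadata file is
#' tab-separated with a header containing at least `sample_id`, `diagnosis`,
#' `disease`, `disease_class` and `tissue`. Gene rows containing missing
#' values are dropped first, then sample columns still containing missing
#' values; both counts are reported. When the same gene identifier occurs more
#' than once (e.g. after upstream probe collapsing), the row with the highest
#' mean is kept.
#'
#' @param expression_path Path to the gene-by-sample TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param cohort_id Cohort name; defaults to the expression file stem.
#' @return A validated [new_cohort()] object.
#' @export
load_cohort <- function(expression_path, metadata_path,
                        cohort_id = sub("\\.[^.]*$", "", basename(expression_path))) {
  expr_df <- utils::read.delim(expression_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (ncol(expr_df) < 2) stop("expression file has no sample columns", call. = FALSE)
  genes <- as.character(expr_df[[1]])
  mat <- as.matrix(expr_df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes

  # missing-value policy: gene rows first, then sample columns
  na_rows <- rowSums(is.na(mat)) > 0
  if (any(na_rows)) {
    message(sprintf("load_cohort(%s): dropped %d gene rows with missing values",
                    cohort_id, sum(na_rows)))
    mat <- mat[!na_rows, , drop = FALSE]
  }
  na_cols <- colSums(is.na(mat)) > 0
  if (any(na_cols)) {
    message(sprintf("load_cohort(%s): dropped %d sample columns with missing values",
                    cohort_id, sum(na_cols)))
    mat <- mat[, !na_cols, drop = FALSE]
  }

  if (anyDuplicated(rownames(mat))) {
    means <- rowMeans(mat)
    ord <- order(rownames(mat), -means)
    mat <- mat[ord, , drop = FALSE]
    keep <- !duplicated(rownames(mat))
    message(sprintf("load_cohort(%s): collapsed %d duplicate gene rows (kept highest mean)",
                    cohort_id, sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }

  metadata <- utils::read.delim(metadata_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    names(metadata)[1] <- "sample_id"
  }
  metadata <- metadata[metadata$sample_id %in% colnames(mat), , drop = FALSE]
  new_cohort(cohort_id, mat, metadata)
}

#' Write a cohort to expression and metadata TSV files
#'
#' @param cohort A `sig_cohort`.
#' @param expression_path,metadata_path Output paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, expression_path, metadata_path) {
  df <- data.frame(gene = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}

#' Row-mean normalization
#'
#' Scales every gene row of a nonnegative expression matrix so that its mean
#' is exactly 1, the standard preprocessing step before NMF decomposition so
#' that genes contribute on a comparable scale. Genes whose row mean is at or
#' below `epsilon` cannot be rescaled and are dropped with a warning.
#'
#' @param expression Nonnegative numeric matrix (genes x samples).
#' @param epsilon Row means at or below this are treated as zero (dropped).
#' @return The rescaled matrix, possibly with fewer rows. The number of
#'   dropped genes is attached as attribute `dropped_genes`.
#' @export
#' @examples
#' m <- matrix(c(2, 4, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' rowmean_normalize(m)  # row a becomes (2/3, 4/3)
rowmean_normalize <- function(expression, epsilon = 1e-12) {
  if (!is.matrix(expression) || length(expression) == 0) {
    stop("`expression` must be a non-empty matrix", call. = FALSE)
  }
  if (any(!is.finite(expression)) || any(expression < 0)) {
    stop("`expression` must be finite and nonnegative", call. = FALSE)
  }
  mu <- rowMeans(expression)
  drop <- mu <= epsilon
  if (any(drop)) {
    warning(sprintf("rowmean_normalize: dropped %d gene(s) with (near-)zero mean: %s",
                    sum(drop),
                    paste(utils::head(rownames(expression)[drop], 5), collapse = ", ")),
            call. = FALSE)
    expression <- expression[!drop, , drop = FALSE]
    mu <- mu[!drop]
  }
  if (nrow(expression) == 0) stop("all gene rows had zero mean", call. = FALSE)
  out <- expression / mu
  attr(out, "dropped_genes") <- sum(drop)
  out
}

#' Row-mean normalize a cohort in place
#'
#' @param cohort A `sig_cohort`.
#' @inheritParams rowmean_normalize
#' @return The cohort with normalized expression.
#' @export
normalize_cohort <- function(cohort, epsilon = 1e-12) {
  cohort$expression <- rowmean_normalize(cohort$expression, epsilon = epsilon)
  cohort
}

#' Read a cohort manifest
#'
#' A manifest lists the cohorts of a batch run, one per row, with columns
#' `cohort_id`, `expression_path`, `metadata_path`. Paths are resolved
#' relative to the manifest file. Both TSV and YAML (a list of records with
#' the same fields) are accepted.
#'
#' @param path Manifest file (`.tsv`/`.txt` or `.yaml`/`.yml`).
#' @return A list of [new_cohort()] objects, named by `cohort_id`.
#' @export
load_manifest <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML manifests requires the 'yaml' package", call. = FALSE)
    }
    recs <- yaml::read_yaml(path)
    tab <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    tab <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  required <- c("cohort_id", "expression_path", "metadata_path")
  if (!all(required %in% names(tab))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cohorts <- purrr::pmap(
    list(tab$cohort_id, resolve(tab$expression_path), resolve(tab$metadata_path)),
    function(id, ep, mp) load_cohort(ep, mp, cohort_id = id)
  )
  stats::setNames(cohorts, tab$cohort_id)
}
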