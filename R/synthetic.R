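#' Specify a synthetic multi-cohort design
#'
#' Describes the generative model used to validate the pipeline: each cohort's
#' expression is a nonnegative latent factor model
#' \deqn{X = B + \sum_f w_f h_f^T,} multiplied entrywise by lognormal noise,
#' where each planted factor `f` loads strongly on its signature genes and is
#' expressed only in the samples of its active group. Planted factors that are
#' active in several cohorts are the ground-truth cross-cohort edges the
#' pipeline should recover.
#'
#' @param n_genes Number of genes; gene identifiers are `g0001`, `g0002`, ...
#' @param cohorts Data frame with columns `cohort_id`, `disease`,
#'   `disease_class`, `tissue`, `n_cases`, `n_controls`.
#' @param factors Data frame with columns `factor_id`, `genes` (list-column of
#'   integer gene indices in `1..n_genes`), and `active_in` (list-column of
#'   data frames with columns `cohort_id`, `group` where group is `"case"`,
#'   `"control"` or `"all"`). Optional numeric column `exposure_scale`
#'   overrides the design-level default per factor.
#' @param exposure_scale Mean gene loading of a signature gene (design
#'   default, 1).
#' @param noise_scale Standard deviation (log scale) of the multiplicative
#'   lognormal noise; 0.1 corresponds to ~10% intensity noise.
#' @param off_signature_frac Scale of the small positive loadings given to
#'   non-signature genes, as a fraction of `exposure_scale` (default 0.01) so
#'   that top-gene selection is a real inference problem rather than reading
#'   off exact zeros.
#' @param covariates Optional list of covariate specs, each a list with
#'   `name`, `kind` (`"uniform"` or `"bernoulli"`), and parameters `min`/`max`
#'   or `prob`. Generated independently of the factors.
#' @param seed Integer seed; the same design generates bit-identical data.
#' @return A `sig_design` object.
#' @export
synthetic_design <- function(n_genes, cohorts, factors,
                             exposure_scale = 1, noise_scale = 0.1,
                             off_signature_frac = 0.01,
                             covariates = list(), seed = 1L) {
  cohorts <- tibble::as_tibble(cohorts)
  factors <- tibble::as_tibble(factors)
  stopifnot(
    all(c("cohort_id", "disease", "disease_class", "tissue",
          "n_cases", "n_controls") %in% names(cohorts)),
    all(c("factor_id", "genes", "active_in") %in% names(factors)),
    n_genes >= 1, exposure_scale > 0, noise_scale >= 0
  )
  if (any(cohorts$n_cases < 2 | cohorts$n_controls < 2)) {
    stop("every cohort needs >= 2 cases and >= 2 controls", call. = FALSE)
  }
  for (i in seq_len(nrow(factors))) {
    g <- factors$genes[[i]]
    if (length(g) == 0 || any(g < 1 | g > n_genes)) {
      stop("factor ", factors$factor_id[i],
           ": signature gene indices must be a nonempty subset of 1..n_genes",
           call. = FALSE)
    }
    act <- factors$active_in[[i]]
    if (!all(act$cohort_id %in% cohorts$cohort_id)) {
      stop("factor ", factors$factor_id[i], " is active in unknown cohort(s): ",
           paste(setdiff(act$cohort_id, cohorts$cohort_id), collapse = ", "),
           call. = FALSE)
    }
    if (!all(act$group %in% c("case", "control", "all"))) {
      stop("active_in group must be 'case', 'control' or 'all'", call. = FALSE)
    }
  }
  if (!"exposure_scale" %in% names(factors)) {
    factors$exposure_scale <- exposure_scale
  }
  structure(
    list(n_genes = n_genes, cohorts = cohorts, factors = factors,
         exposure_scale = exposure_scale, noise_scale = noise_scale,
         off_signature_frac = off_signature_frac,
         covariates = covariates, seed = as.integer(seed)),
    class = "sig_design"
  )
}

#' Helper: one active-group record
#' @param cohort_id Cohort the factor is expressed in.
#' @param group `"case"`, `"control"` or `"all"`.
#' @return One-row tibble for use in a design's `active_in` list-column.
#' @export
active_in <- function(cohort_id, group = "case") {
  tibble::tibble(cohort_id = cohort_id, group = group)
}

#' Generate synthetic cohorts with known ground truth
#'
#' @param design A [synthetic_design()].
#' @return A list with `cohorts` (named list of [new_cohort()] objects) and
#'   `truth`, a list holding per-factor signature gene identifier sets
#'   (`factor_genes`), per-cohort true loading/exposure matrices (`W`, `H`),
#'   and `expected_edges`: a tibble of cross-cohort pairs
#'   `(cohort_a, cohort_b, factor_id)` for every planted factor active in
#'   two distinct cohorts (cohort_a < cohort_b, no self-pairs).
#' @export
generate_cohorts <- function(design) {
  stopifnot(inherits(design, "sig_design"))
  gene_ids <- sprintf("g%0*d", max(4, nchar(design$n_genes)),
                      seq_len(design$n_genes))
  withr::with_seed(design$seed, {
    cohorts <- vector("list", nrow(design$cohorts))
    names(cohorts) <- design$cohorts$cohort_id
    W_true <- H_true <- stats::setNames(vector("list", nrow(design$cohorts)),
                                        design$cohorts$cohort_id)
    for (ci in seq_len(nrow(design$cohorts))) {
      spec <- design$cohorts[ci, ]
      n <- spec$n_cases + spec$n_controls
      sample_ids <- sprintf("%s_s%03d", spec$cohort_id, seq_len(n))
      diagnosis <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))

      # per-gene positive baseline, constant across samples
      baseline <- stats::runif(design$n_genes, 0.5, 1.5)
      X <- matrix(baseline, nrow = design$n_genes, ncol = n)

      nf <- nrow(design$factors)
      W <- matrix(0, design$n_genes, nf,
                  dimnames = list(gene_ids, design$factors$factor_id))
      H <- matrix(0, nf, n,
                  dimnames = list(design$factors$factor_id, sample_ids))
      for (fi in seq_len(nf)) {
        act <- design$factors$active_in[[fi]]
        act <- act[act$cohort_id == spec$cohort_id, , drop = FALSE]
        if (nrow(act) == 0) next
        es <- design$factors$exposure_scale[fi]
        sig_genes <- design$factors$genes[[fi]]
        w <- stats::rgamma(design$n_genes, shape = 4, rate = 4) *
          (design$off_signature_frac * es)
        w[sig_genes] <- stats::rgamma(length(sig_genes), shape = 4, rate = 4) * es
        active_samples <- rep(FALSE, n)
        for (g in act$group) {
          active_samples <- active_samples |
            (if (g == "all") rep(TRUE, n) else diagnosis == g)
        }
        h <- ifelse(active_samples, stats::runif(n, 0.5, 1.5), 0)
        W[, fi] <- w
        H[fi, ] <- h
        X <- X + w %o% h
      }
      if (design$noise_scale > 0) {
        X <- X * matrix(stats::rlnorm(length(X), 0, design$noise_scale),
                        nrow = nrow(X))
      }
      X <- pmax(X, 0)
      dimnames(X) <- list(gene_ids, sample_ids)

      metadata <- tibble::tibble(
        sample_id = sample_ids, diagnosis = diagnosis,
        disease = spec$disease, disease_class = spec$disease_class,
        tissue = spec$tissue
      )
      for (cv in design$covariates) {
        metadata[[cv$name]] <- switch(
          cv$kind,
          uniform = stats::runif(n, cv$min, cv$max),
          bernoulli = ifelse(stats::rbinom(n, 1, cv$prob) == 1, "a", "b"),
          stop("unknown covariate kind: ", cv$kind)
        )
      }
      cohorts[[ci]] <- new_cohort(spec$cohort_id, X, metadata)
      W_true[[ci]] <- W
      H_true[[ci]] <- H
    }

    expected <- purrr::map_dfr(seq_len(nrow(design$factors)), function(fi) {
      ids <- sort(unique(design$factors$active_in[[fi]]$cohort_id))
      if (length(ids) < 2) return(NULL)
      pairs <- utils::combn(ids, 2)
      tibble::tibble(cohort_a = pairs[1, ], cohort_b = pairs[2, ],
                     factor_id = design$factors$factor_id[fi])
    })
    factor_genes <- stats::setNames(
      lapply(design$factors$genes, function(i) gene_ids[i]),
      design$factors$factor_id
    )
    list(cohorts = cohorts,
         truth = list(factor_genes = factor_genes, W = W_true, H = H_true,
                      expected_edges = expected))
  })
}

#' Canned validation design: one planted cross-disease factor
#'
#' Four cohorts (two schizophrenia brain cohorts, two type-2-diabetes islet
#' cohorts), each with 20 cases and 20 controls over `n_genes` genes, and a
#' single case-active factor of `n_signature_genes` genes shared by one
#' cohort of each disease. The pipeline should recover the planted scz-t2d
#' inter-class comorbid edge.
#'
#' @param seed Integer seed.
#' @param n_genes,n_signature_genes Problem size (defaults 2000 and 150).
#' @param exposure_scale,noise_scale Signal and noise levels; the default
#'   ratio of 10 is the strong-signal regime.
#' @return A `sig_design`.
#' @export
design_planted_edge <- function(seed = 1L, n_genes = 2000,
                                n_signature_genes = 150,
                                exposure_scale = 1, noise_scale = 0.1) {
  cohorts <- tibble::tibble(
    cohort_id = c("scz1", "scz2", "t2d1", "t2d2"),
    disease = c("scz", "scz", "t2d", "t2d"),
    disease_class = c("PSY", "PSY", "T2D", "T2D"),
    tissue = c("brain", "brain", "islets", "islets"),
    n_cases = 20L, n_controls = 20L
  )
  shared_genes <- seq_len(n_signature_genes)
  # cohort-private background factors active in everyone keep the
  # decomposition honest: the shared factor must be singled out
  rest <- setdiff(seq_len(n_genes), shared_genes)
  block <- min(150L, length(rest) %/% 4L)
  if (block < 10L) stop("n_genes too small for the canned design", call. = FALSE)
  bg <- split(rest[seq_len(4L * block)], rep(1:4, each = block))
  factors <- tibble::tibble(
    factor_id = c("shared_case", "bg_scz1", "bg_scz2", "bg_t2d1", "bg_t2d2"),
    genes = c(list(shared_genes), unname(bg)),
    active_in = list(
      dplyr::bind_rows(active_in("scz1", "case"), active_in("t2d1", "case")),
      active_in("scz1", "all"),
      active_in("scz2", "all"),
      active_in("t2d1", "all"),
      active_in("t2d2", "all")
    )
  )
  synthetic_design(n_genes, cohorts, factors,
                   exposure_scale = exposure_scale, noise_scale = noise_scale,
                   seed = seed)
}

#' Canned null design: no diagnosis-linked, no shared factors
#'
#' The same four cohorts as [design_planted_edge()] but every planted factor
#' is cohort-private and active in all samples, so no signature should be
#' diagnosis-associated and no cross-cohort edge should survive the
#' permutation test beyond chance.
#'
#' @inheritParams design_planted_edge
#' @return A `sig_design`.
#' @export
design_null <- function(seed = 1L, n_genes = 2000, noise_scale = 0.1) {
  cohorts <- tibble::tibble(
    cohort_id = c("scz1", "scz2", "t2d1", "t2d2"),
    disease = c("scz", "scz", "t2d", "t2d"),
    disease_class = c("PSY", "PSY", "T2D", "T2D"),
    tissue = c("brain", "brain", "islets", "islets"),
    n_cases = 20L, n_controls = 20L
  )
  block <- min(150L, n_genes %/% 4L)
  if (block < 10L) stop("n_genes too small for the canned design", call. = FALSE)
  factors <- tibble::tibble(
    factor_id = paste0("bg_", cohorts$cohort_id),
    genes = unname(split(seq_len(4L * block), rep(1:4, each = block))),
    active_in = purrr::map(cohorts$cohort_id, active_in, group = "all")
  )
  synthetic_design(n_genes, cohorts, factors, noise_scale = noise_scale,
                   seed = seed)
}

#' Write a generated design to disk
#'
#' Writes per-cohort `<id>_expression.tsv` / `<id>_metadata.tsv`, a
#' `manifest.tsv`, and `ground_truth.json` under `dir`.
#'
#' @param generated Result of [generate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(generated$cohorts, function(coh) {
    ep <- paste0(coh$cohort_id, "_expression.tsv")
    mp <- paste0(coh$cohort_id, "_metadata.tsv")
    write_cohort(coh, file.path(dir, ep), file.path(dir, mp))
    tibble::tibble(cohort_id = coh$cohort_id,
                   expression_path = ep, metadata_path = mp)
  })
  utils::write.table(rows, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    factor_genes = generated$truth$factor_genes,
    expected_edges = generated$truth$expected_edges
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
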