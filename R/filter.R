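#' Test one signature's exposures for diagnosis association
#'
#' Fits the linear model `exposure ~ diagnosis + covariates` and returns the
#' two-sided t-test p-value of the diagnosis coefficient. For a single
#' signature this is the covariate-adjusted two-group comparison of exposure
#' levels between cases and controls. Zero-variance exposures carry no
#' evidence and return p = 1 with a degenerate flag; rows with missing
#' covariates are dropped (count reported); covariates made collinear by the
#' remaining data are dropped by the fit and reported.
#'
#' @param sample_exposures Nonnegative numeric vector, one value per sample.
#' @param diagnosis Character/factor vector of `"case"`/`"control"` labels.
#' @param covariates Optional data frame of covariates (numeric or
#'   categorical; categorical are dummy-coded with the lexicographically
#'   first level as reference).
#' @return List with `p_value`, `estimate` (case-minus-control adjusted
#'   effect), and `degenerate` flag.
#' @export
#' @examples
#' expo <- c(rnorm(10, 5), rnorm(10, 1))
#' diag <- rep(c("case", "control"), each = 10)
#' associate_signature(expo, diag)$p_value
associate_signature <- function(sample_exposures, diagnosis, covariates = NULL) {
  stopifnot(length(sample_exposures) == length(diagnosis))
  diagnosis <- factor(as.character(diagnosis), levels = c("control", "case"))
  if (any(is.na(diagnosis))) {
    stop("`diagnosis` must be 'case' or 'control'", call. = FALSE)
  }
  df <- data.frame(.exposure = sample_exposures, .diagnosis = diagnosis)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cov_df <- as.data.frame(covariates)
    cov_df[] <- lapply(cov_df, function(v) {
      if (is.character(v) || is.logical(v)) factor(v, levels = sort(unique(v[!is.na(v)])))
      else v
    })
    df <- cbind(df, cov_df)
    complete <- stats::complete.cases(df)
    if (any(!complete)) {
      message(sprintf("associate_signature: dropped %d sample(s) with missing covariates",
                      sum(!complete)))
      df <- df[complete, , drop = FALSE]
    }
  }
  if (min(table(df$.diagnosis)) < 2) {
    stop("need >= 2 samples in each diagnosis group", call. = FALSE)
  }
  if (stats::var(df$.exposure) == 0) {
    return(list(p_value = 1, estimate = 0, degenerate = TRUE))
  }
  fit <- stats::lm(.exposure ~ ., data = df)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  if (length(aliased) > 0) {
    warning("collinear covariate term(s) dropped: ",
            paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- stats::coef(summary(fit))
  row <- ".diagnosiscase"
  if (!row %in% rownames(sm)) {
    # diagnosis aliased by a covariate: no testable effect
    return(list(p_value = 1, estimate = 0, degenerate = TRUE))
  }
  list(p_value = unname(sm[row, "Pr(>|t|)"]),
       estimate = unname(sm[row, "Estimate"]),
       degenerate = FALSE)
}

#' Filter a signature set to diagnosis-associated signatures
#'
#' Tests each signature's sample exposures with [associate_signature()] and
#' keeps exactly those with p strictly below `alpha` (raw p-values; no
#' multiple-testing correction at this stage — the downstream permutation
#' test on edges controls for chance matching, and under the null the
#' retained fraction is calibrated at `alpha` by construction).
#'
#' @param sigset A `sig_set` from [mrnmf()].
#' @param alpha Retention threshold on the raw p-value (strict `<`, default
#'   0.05).
#' @param covariate_names Metadata columns to adjust for (default: all
#'   non-required columns, i.e. every covariate the cohort carries).
#' @return The `sig_set` restricted to retained signatures; the signature
#'   tibble gains `diagnosis_p`, `estimate` and `degenerate` columns. All
#'   p-values (including removed ones) are kept in attribute `all_p`.
#' @export
filter_signatures <- function(sigset, alpha = 0.05, covariate_names = NULL) {
  stopifnot(inherits(sigset, "sig_set"))
  md <- sigset$metadata
  if (is.null(covariate_names)) {
    covariate_names <- setdiff(names(md), c("sample_id", "diagnosis", "disease",
                                            "disease_class", "tissue"))
  }
  cov_df <- if (length(covariate_names) > 0) md[, covariate_names, drop = FALSE] else NULL
  res <- purrr::map(seq_len(nrow(sigset$signatures)), function(i) {
    associate_signature(sigset$H[i, ], md$diagnosis, cov_df)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  sigset$signatures$diagnosis_p <- p
  sigset$signatures$estimate <- vapply(res, `[[`, numeric(1), "estimate")
  sigset$signatures$degenerate <- sigset$signatures$degenerate |
    vapply(res, `[[`, logical(1), "degenerate")
  keep <- p < alpha
  if (!any(keep)) {
    warning(sprintf("cohort %s: no diagnosis-associated signatures at alpha = %g; cohort contributes no graph nodes",
                    sigset$cohort_id, alpha), call. = FALSE)
  }
  all_p <- sigset$signatures
  sigset$signatures <- sigset$signatures[keep, , drop = FALSE]
  sigset$W <- sigset$W[, keep, drop = FALSE]
  sigset$H <- sigset$H[keep, , drop = FALSE]
  attr(sigset, "all_p") <- all_p
  sigset
}
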