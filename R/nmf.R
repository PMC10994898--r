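#' Nonnegative double SVD initialization
#'
#' Deterministic NMF initialization from the truncated SVD of `X`: each SVD
#' component contributes the dominant nonnegative parts of its singular
#' vectors. Zeros left by the sign split are filled with a small positive
#' constant (the matrix mean scaled down) so that multiplicative updates,
#' which cannot leave zero, can still adjust every entry.
#'
#' @param X Nonnegative matrix.
#' @param k Rank.
#' @return List with `W` (nrow(X) x k) and `H` (k x ncol(X)), both positive.
#' @keywords internal
nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        scale <- sqrt(sv$d[j] * n_up * n_vp)
        if (n_up > 0) W[, j] <- scale * up / n_up
        if (n_vp > 0) H[j, ] <- scale * vp / n_vp
      } else {
        scale <- sqrt(sv$d[j] * n_un * n_vn)
        if (n_un > 0) W[, j] <- scale * un / n_un
        if (n_vn > 0) H[j, ] <- scale * vn / n_vn
      }
    }
  }
  fill <- mean(X) * 1e-4 + 1e-12
  W[W <= 0] <- fill
  H[H <= 0] <- fill
  list(W = W, H = H)
}

#' Single-rank NMF by multiplicative updates
#'
#' Minimizes the squared Frobenius reconstruction loss
#' \deqn{\min_{W \ge 0, H \ge 0} \|X - WH\|_F^2}
#' with Lee-Seung multiplicative updates, which never increase the loss.
#' Initialization is the deterministic nonnegative double SVD
#' ([nndsvd_init()]) by default, so repeated runs give identical results;
#' `init = "random"` draws a seeded uniform start instead.
#'
#' @param X Nonnegative numeric matrix (genes x samples).
#' @param k Factorization rank, `1 <= k <= min(dim(X))`.
#' @param seed Integer seed (used by random initialization only).
#' @param max_iter Iteration budget (default 500).
#' @param tol Stop when the relative loss decrease falls below this
#'   (default 1e-5).
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @return List with `W` (genes x k), `H` (k x samples), `loss` (final
#'   squared Frobenius loss), `loss_trace` (per-iteration losses, starting at
#'   the initial point), `iterations`, and `converged`.
#' @export
#' @examples
#' set.seed(1)
#' w <- runif(30); h <- runif(10)
#' fit <- nmf_decompose(w %o% h, k = 2)
#' fit$loss / sum((w %o% h)^2)  # near 0: rank-1 matrix is reconstructed
nmf_decompose <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                          init = c("nndsvd", "random")) {
  init <- match.arg(init)
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("`X` must be finite and nonnegative", call. = FALSE)
  }
  if (k < 1 || k > min(dim(X))) {
    stop(sprintf("rank k = %d must be in 1..min(dim(X)) = %d", k, min(dim(X))),
         call. = FALSE)
  }
  if (all(X == 0)) {
    return(list(W = matrix(0, nrow(X), k), H = matrix(0, k, ncol(X)),
                loss = 0, loss_trace = 0, iterations = 0L, converged = TRUE))
  }
  if (init == "nndsvd") {
    st <- nndsvd_init(X, k)
    W <- st$W; H <- st$H
  } else {
    withr::with_seed(seed, {
      W <- matrix(stats::runif(nrow(X) * k, 0, sqrt(mean(X))), nrow(X), k)
      H <- matrix(stats::runif(k * ncol(X), 0, sqrt(mean(X))), k, ncol(X))
    })
  }
  eps <- .Machine$double.eps
  x_ss <- sum(X^2)
  frob <- function(W, H) {
    # ||X - WH||^2 = ||X||^2 - 2<X, WH> + ||WH||^2, accumulated in k-space
    wtx <- crossprod(W, X)
    x_ss - 2 * sum(wtx * H) + sum(crossprod(W) * tcrossprod(H))
  }
  loss_trace <- numeric(max_iter + 1L)
  loss_trace[1] <- frob(W, H)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    loss_trace[it + 1L] <- frob(W, H)
    prev <- loss_trace[it]
    if (prev > 0 && (prev - loss_trace[it + 1L]) / prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("NMF did not reach tol = %g in %d iterations (k = %d); returning best iterate",
                    tol, max_iter, k), call. = FALSE)
  }
  loss_trace <- loss_trace[seq_len(it + 1L)]
  dimnames(W) <- list(rownames(X), NULL)
  dimnames(H) <- list(NULL, colnames(X))
  list(W = W, H = H, loss = loss_trace[it + 1L], loss_trace = loss_trace,
       iterations = it, converged = converged)
}

#' Multi-rank NMF of one cohort
#'
#' Runs an independent NMF decomposition of the cohort's (row-mean
#' normalized) expression matrix at every rank `k` in `kmin..kmax` and pools
#' all resulting signatures: every column of every `W_(k)` together with its
#' matching row of `H_(k)`. Pooling all ranks sidesteps rank selection —
#' coarse signatures from small `k` coexist with fine-grained ones from large
#' `k` — at the cost of redundancy, which the downstream diagnosis filter and
#' reciprocal-best-hit matching absorb. The number of pooled signatures is
#' `sum(kmin:kmax)` (209 for the default 2..20).
#'
#' @param cohort A [new_cohort()] object whose expression is row-mean
#'   normalized (see [normalize_cohort()]; a matrix whose row means are not 1
#'   is accepted with a warning).
#' @param kmin,kmax Rank range (defaults 2 and 20).
#' @param seed Integer seed; per-rank seeds are derived as `seed + k`.
#' @param max_iter,tol,init Passed to [nmf_decompose()].
#' @return A `sig_set` object: list with `cohort_id`, `signatures` (tibble
#'   with columns `signature_id`, `rank_k`, `index_in_rank`, `degenerate`,
#'   and once filtered `diagnosis_p`), `W` (genes x signatures matrix of gene
#'   exposures), `H` (signatures x samples matrix of sample exposures),
#'   `losses` (tibble rank/loss), and the cohort `metadata`.
#' @export
mrnmf <- function(cohort, kmin = 2L, kmax = 20L, seed = 1L,
                  max_iter = 500L, tol = 1e-5, init = "nndsvd") {
  stopifnot(inherits(cohort, "sig_cohort"), kmin >= 1, kmax >= kmin)
  X <- cohort$expression
  if (kmax > min(dim(X))) {
    stop(sprintf("kmax = %d exceeds min(genes, samples) = %d for cohort %s; choose kmax <= %d",
                 kmax, min(dim(X)), cohort$cohort_id, min(dim(X))), call. = FALSE)
  }
  if (abs(mean(rowMeans(X)) - 1) > 1e-6) {
    warning("cohort expression does not look row-mean normalized; consider normalize_cohort()",
            call. = FALSE)
  }
  ranks <- seq.int(kmin, kmax)
  fits <- lapply(ranks, function(k) {
    nmf_decompose(X, k, seed = seed + k, max_iter = max_iter, tol = tol,
                  init = init)
  })
  W <- do.call(cbind, lapply(fits, `[[`, "W"))
  H <- do.call(rbind, lapply(fits, `[[`, "H"))
  sig_tab <- purrr::map2_dfr(ranks, fits, function(k, f) {
    tibble::tibble(
      rank_k = k,
      index_in_rank = seq_len(k),
      degenerate = colSums(f$W) == 0 | rowSums(f$H) == 0
    )
  })
  sig_tab <- dplyr::mutate(
    sig_tab,
    signature_id = paste0(cohort$cohort_id, ":k", .data$rank_k, ":", .data$index_in_rank),
    .before = 1
  )
  colnames(W) <- sig_tab$signature_id
  rownames(H) <- sig_tab$signature_id
  structure(
    list(cohort_id = cohort$cohort_id,
         signatures = sig_tab,
         W = W, H = H,
         losses = tibble::tibble(rank = ranks,
                                 loss = vapply(fits, `[[`, numeric(1), "loss")),
         metadata = cohort$metadata),
    class = "sig_set"
  )
}

#' @export
print.sig_set <- function(x, ...) {
  cat(sprintf("<sig_set> cohort %s: %d signatures (ranks %d..%d), %d genes x %d samples\n",
              x$cohort_id, nrow(x$signatures), min(x$losses$rank),
              max(x$losses$rank), nrow(x$W), ncol(x$H)))
  if ("diagnosis_p" %in% names(x$signatures)) {
    cat(sprintf("  diagnosis-filtered: %d retained\n", nrow(x$signatures)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature set
#'
#' @param x A `sig_set`.
#' @param ... Unused.
#' @return The signature tibble (one row per signature), with per-rank
#'   reconstruction loss joined in.
#' @export
tidy.sig_set <- function(x, ...) {
  dplyr::left_join(x$signatures,
                   dplyr::rename(x$losses, rank_k = "rank", rank_loss = "loss"),
                   by = "rank_k")
}

#' One-row summary of a signature set
#'
#' @param x A `sig_set`.
#' @param ... Unused.
#' @return Tibble with cohort id, signature count, rank range, and the loss
#'   at the largest rank.
#' @export
glance.sig_set <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id,
    n_signatures = nrow(x$signatures),
    kmin = min(x$losses$rank), kmax = max(x$losses$rank),
    loss_at_kmax = x$losses$loss[which.max(x$losses$rank)]
  )
}
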