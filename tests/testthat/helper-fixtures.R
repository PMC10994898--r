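# small in-code fixtures shared across test files

tiny_expression <- function(n_genes = 3, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_genes * n_samples, 0.5, 2), n_genes, n_samples,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("s", seq_len(n_samples))))
    m
  })
}

tiny_metadata <- function(n_samples = 4, disease = "scz", class = "PSY",
                          tissue = "brain") {
  data.frame(
    sample_id = paste0("s", seq_len(n_samples)),
    diagnosis = rep(c("case", "control"), length.out = n_samples),
    disease = disease, disease_class = class, tissue = tissue,
    stringsAsFactors = FALSE
  )
}

tiny_cohort <- function(n_genes = 3, n_samples = 4, seed = 1, ...) {
  new_cohort("tiny", tiny_expression(n_genes, n_samples, seed),
             tiny_metadata(n_samples, ...))
}

# signature set built directly from given W / H matrices (bypasses NMF),
# for graph-level unit tests with controlled exposures
manual_sigset <- function(cohort_id, W, H = NULL, disease = "scz",
                          class = "PSY", tissue = "brain") {
  n_sig <- ncol(W)
  if (is.null(H)) H <- matrix(1, n_sig, 4)
  ids <- paste0(cohort_id, ":k", n_sig, ":", seq_len(n_sig))
  colnames(W) <- ids
  rownames(H) <- ids
  colnames(H) <- paste0(cohort_id, "_s", seq_len(ncol(H)))
  structure(
    list(cohort_id = cohort_id,
         signatures = tibble::tibble(
           signature_id = ids, rank_k = n_sig,
           index_in_rank = seq_len(n_sig), degenerate = FALSE),
         W = W, H = H,
         losses = tibble::tibble(rank = n_sig, loss = 0),
         metadata = tibble::tibble(
           sample_id = colnames(H),
           diagnosis = rep(c("case", "control"), length.out = ncol(H)),
           disease = disease, disease_class = class, tissue = tissue)),
    class = "sig_set"
  )
}

# signature set whose signatures have prescribed top-gene sets
sigset_from_sets <- function(cohort_id, sets, universe, ...) {
  W <- vapply(sets, function(s) {
    w <- runif(length(universe), 0, 0.1)
    names(w) <- universe
    w[s] <- runif(length(s), 1, 2)
    w
  }, numeric(length(universe)))
  rownames(W) <- universe
  manual_sigset(cohort_id, W, ...)
}

# minimal edge tibble with shared_genes list-column
edge_tbl <- function(shared, node_a = "a:k2:1", node_b = "b:k2:1") {
  tibble::tibble(node_a = node_a, node_b = node_b,
                 cohort_a = "a", cohort_b = "b",
                 jaccard = 0.5, shared_genes = if (is.list(shared)) shared else list(shared),
                 tied = FALSE)
}
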