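# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and set algebra only.

# Jaccard of two character sets, scalar arithmetic
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

# reciprocal best hits by explicit double loops; ties all kept
oracle_rbh <- function(sets_a, sets_b) {
  na <- length(sets_a); nb <- length(sets_b)
  J <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    J[i, j] <- oracle_jaccard(sets_a[[i]], sets_b[[j]])
  }
  out <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (J[i, j] <= 0) next
    best_for_i <- max(J[i, ])
    best_for_j <- max(J[, j])
    if (J[i, j] == best_for_i && J[i, j] == best_for_j) {
      out <- rbind(out, data.frame(node_a = names(sets_a)[i],
                                   node_b = names(sets_b)[j],
                                   jaccard = J[i, j]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(node_a = character(), node_b = character(),
                      jaccard = numeric())
  }
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

# BFS over an edge list (two-column character matrix), returning all nodes
# within max_depth hops of any seed
oracle_bfs <- function(edge_list, nodes, seeds, max_depth) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[seeds] <- 0
  frontier <- seeds
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    depth <- depth + 1
    nxt <- character(0)
    for (v in frontier) {
      nbrs <- c(edge_list[edge_list[, 1] == v, 2],
                edge_list[edge_list[, 2] == v, 1])
      for (u in nbrs) {
        if (dist[u] > depth) { dist[u] <- depth; nxt <- c(nxt, u) }
      }
    }
    frontier <- unique(nxt)
  }
  sort(names(dist)[is.finite(dist)])
}

# all nodes on any shortest path between s and t, by exhaustive path
# enumeration up to the BFS distance
oracle_shortest_path_nodes <- function(edge_list, nodes, s, t) {
  # BFS distance from s to everything
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      nbrs <- c(edge_list[edge_list[, 1] == v, 2],
                edge_list[edge_list[, 2] == v, 1])
      for (u in nbrs) {
        if (dist[u] > dist[v] + 1) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
      }
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t])) return(character(0))
  # enumerate all shortest paths recursively
  on_path <- character(0)
  recurse <- function(v, path) {
    if (v == t) { on_path <<- unique(c(on_path, path)); return(invisible()) }
    nbrs <- unique(c(edge_list[edge_list[, 1] == v, 2],
                     edge_list[edge_list[, 2] == v, 1]))
    for (u in nbrs) {
      if (dist[u] == dist[v] + 1 && dist[u] <= dist[t]) recurse(u, c(path, u))
    }
  }
  recurse(s, s)
  sort(on_path)
}

# set-algebra gene categorization oracle
oracle_categorize <- function(U, A, B) {
  out <- character(length(U))
  for (i in seq_along(U)) {
    g <- U[i]
    a <- g %in% A; b <- g %in% B
    out[i] <- if (a && b) "shared"
    else if (a) "disease_a_specific"
    else if (b) "disease_b_specific"
    else "distinct"
  }
  stats::setNames(out, U)
}

# random gene-set fixture
random_sets <- function(n_sets, universe, size, prefix = "s") {
  stats::setNames(
    lapply(seq_len(n_sets), function(i) sample(universe, size)),
    paste0(prefix, seq_len(n_sets))
  )
}
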