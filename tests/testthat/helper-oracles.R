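# Independent brute-force oracles used by the property tests. These are
# deliberately naive (explicit path enumeration, explicit set construction,
# matrix-power walk counting) and share no code with the implementation.

# small named graph from an explicit edge matrix
toy_graph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(matrix(match(edges, nodes),
                                                 ncol = 2))))
  }
  g
}

# seeded G(n, p) with letter names
random_named_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  rownames(A) <- colnames(A) <- sprintf("v%02d", seq_len(n))
  graph_from_dense(A)
}

graph_from_dense <- function(A) {
  g <- igraph::make_empty_graph(nrow(A), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(A))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) g <- igraph::add_edges(g, as.vector(t(idx)))
  g
}

dense_adjacency <- function(g) {
  A <- matrix(0L, igraph::vcount(g), igraph::vcount(g))
  rownames(A) <- colnames(A) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  for (k in seq_len(nrow(el))) {
    A[el[k, 1], el[k, 2]] <- 1L
    A[el[k, 2], el[k, 1]] <- 1L
  }
  A
}

# --- betweenness oracle: enumerate every simple path between every pair,
# keep the shortest ones, accumulate fractional interior-node credit.
bf_betweenness <- function(g) {
  A <- dense_adjacency(g)
  n <- nrow(A)
  bc <- stats::setNames(numeric(n), rownames(A))
  if (n < 3) return(bc)
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      tail_ <- path[length(path)]
      if (tail_ == t) {
        found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (nb in which(A[tail_, ] == 1L)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(s)
    found
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        for (v in interior) bc[v] <- bc[v] + 1 / sigma
      }
    }
  }
  bc
}

# --- subgraph-centrality oracle: truncated closed-walk series via
# repeated adjacency multiplication, sum_{k<=kmax} diag(A^k)/k!.
# kmax = 30 keeps the neglected tail below 1e-9 relative for the spectral
# radii (< 8) reachable by the 12-node test graphs.
bf_subgraph_centrality <- function(g, kmax = 30) {
  A <- dense_adjacency(g)
  n <- nrow(A)
  sc <- rep(1, n) # k = 0 term
  P <- diag(n)
  for (k in seq_len(kmax)) {
    P <- P %*% A
    sc <- sc + diag(P) / factorial(k)
  }
  stats::setNames(sc, rownames(A))
}

# --- density oracle: explicit ball construction + edge counting
bf_ball_density <- function(g, order) {
  A <- dense_adjacency(g)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    ball <- v
    for (step in seq_len(order)) {
      ball <- union(ball, which(rowSums(A[, ball, drop = FALSE]) > 0))
    }
    m <- length(ball)
    if (m <= 1) return(0)
    e <- sum(A[ball, ball]) / 2
    2 * e / (m * (m - 1))
  }, numeric(1)) |> stats::setNames(rownames(A))
}

# relabel vertices by a permutation of their names (same topology)
permute_names <- function(g, perm) {
  igraph::set_vertex_attr(g, "name",
                          value = perm[igraph::V(g)$name])
}
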