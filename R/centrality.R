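# The six baseline node centralities (DC, BC, SC, EC, LAC, NC) and the
# local clustering coefficient LCC. Every function maps an igraph PPI
# network to a named numeric vector over all vertices; all are pure
# functions of the graph (no randomness, no tie noise).

#' Degree centrality
#'
#' `DC(v)`: the number of neighbours of `v`.
#'
#' @param net An igraph PPI network with named vertices.
#' @return Named numeric vector of degrees.
#' @export
degree_centrality <- function(net) {
  check_network(net)
  as.numeric_scores(degree(net, loops = FALSE))
}

#' Betweenness centrality
#'
#' `BC(v)`: the sum over unordered node pairs \eqn{\{s,t\}}, \eqn{s \ne t \ne
#' v}, of the fraction of shortest \eqn{s}-\eqn{t} paths passing through `v`.
#' Unnormalized, endpoints excluded; pairs in different components contribute
#' nothing. Computed by Brandes dependency accumulation (via igraph).
#'
#' @inheritParams degree_centrality
#' @param ordered_pairs Count each pair in both orientations (doubles every
#'   value). Off by default; exposed because published tables built with
#'   other tools occasionally use the ordered-pairs convention.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net, ordered_pairs = FALSE) {
  check_network(net)
  bc <- betweenness(net, directed = FALSE, normalized = FALSE)
  if (ordered_pairs) bc <- 2 * bc
  as.numeric_scores(bc)
}

#' Subgraph centrality
#'
#' `SC(v)` counts the closed walks of every length `k` rooted at `v`,
#' weighted by \eqn{1/k!}: \eqn{SC(v) = \sum_k \mu_k(v)/k!}. Evaluated in
#' closed form from the eigendecomposition of the adjacency matrix,
#' \eqn{SC(v) = \sum_j u_j(v)^2 e^{\lambda_j}}; an isolated node scores 1
#' (the length-0 walk only).
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector, all values >= 1.
#' @export
subgraph_centrality <- function(net) {
  check_network(net)
  n <- vcount(net)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  A <- as.matrix(as_adjacency_matrix(net, type = "both", sparse = TRUE))
  es <- eigen(A, symmetric = TRUE)
  # rows of U^2 weighted by exp(lambda); lambda_max << 700 at PPI scale
  sc <- as.vector((es$vectors^2) %*% exp(es$values))
  as.numeric_scores(stats::setNames(sc, igraph::V(net)$name))
}

#' Eigenvector centrality
#'
#' `EC(v)`: the `v`-th component of the principal eigenvector of the
#' adjacency matrix, taken entrywise non-negative and L2-normalized.
#' Dense symmetric eigensolve up to 3000 nodes; power iteration
#' (tolerance 1e-12, at most 10000 iterations) above that.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(net) {
  check_network(net)
  if (ecount(net) == 0L) {
    stop("eigenvector_centrality: network has no edges; ",
         "the principal eigenvector is degenerate", call. = FALSE)
  }
  n <- vcount(net)
  A <- as_adjacency_matrix(net, type = "both", sparse = TRUE)
  if (n <= 3000L) {
    es <- eigen(as.matrix(A), symmetric = TRUE)
    v <- es$vectors[, 1L]
  } else {
    v <- rep(1 / sqrt(n), n)
    for (i in seq_len(10000L)) {
      w <- as.vector(A %*% v)
      w <- w / sqrt(sum(w^2))
      if (max(abs(w - v)) < 1e-12) { v <- w; break }
      v <- w
    }
  }
  # Perron vector: fix the sign so entries are non-negative
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  v <- v / sqrt(sum(v^2))
  as.numeric_scores(stats::setNames(v, igraph::V(net)$name))
}

#' Local average connectivity (LAC)
#'
#' `LAC(v)`: the mean, over the neighbours `u` of `v`, of `u`'s degree
#' within the subgraph induced by the open neighbourhood `N(v)` (with `v`
#' itself removed). Isolated nodes score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
lac <- function(net) {
  check_network(net)
  nbrs <- igraph::adjacent_vertices(net, igraph::V(net))
  vals <- vapply(seq_len(vcount(net)), function(i) {
    nv <- nbrs[[i]]
    if (length(nv) == 0L) return(0)
    sub <- induced_subgraph(net, nv)
    # mean in-neighbourhood degree = 2 * edges among neighbours / |N(v)|
    2 * ecount(sub) / length(nv)
  }, numeric(1))
  as.numeric_scores(stats::setNames(vals, igraph::V(net)$name))
}

#' Network centrality (NC): sum of edge clustering coefficients
#'
#' For each edge `(u, v)` the edge clustering coefficient is
#' \eqn{ECC(u,v) = z(u,v) / \min(deg(u)-1, deg(v)-1)}, with `z` the number
#' of common neighbours of `u` and `v` (triangles through the edge), and
#' 0 whenever the denominator is 0. `NC(v)` sums ECC over `v`'s incident
#' edges; on a triangle-free graph NC is identically 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
nc <- function(net) {
  check_network(net)
  deg <- degree(net)
  vals <- stats::setNames(numeric(vcount(net)), igraph::V(net)$name)
  el <- as_edgelist(net, names = FALSE)
  if (nrow(el) > 0L) {
    nbr <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
    for (k in seq_len(nrow(el))) {
      u <- el[k, 1L]; v <- el[k, 2L]
      den <- min(deg[u] - 1L, deg[v] - 1L)
      if (den <= 0L) next
      z <- length(intersect(nbr[[u]], nbr[[v]]))
      ecc <- z / den
      vals[u] <- vals[u] + ecc
      vals[v] <- vals[v] + ecc
    }
  }
  as.numeric_scores(vals)
}

#' Local clustering coefficient (LCC)
#'
#' \eqn{LCC(v) = 2(|E(H)| - |N_v|) / (|N_v|(|N_v|-1))} where `H` is the
#' subgraph induced by the closed neighbourhood of `v`; equivalently the
#' fraction of neighbour pairs that are themselves connected. Nodes of
#' degree <= 1 score 0 (the formula's denominator vanishes).
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
lcc <- function(net) {
  check_network(net)
  nbrs <- igraph::adjacent_vertices(net, igraph::V(net))
  vals <- vapply(seq_len(vcount(net)), function(i) {
    nv <- nbrs[[i]]
    d <- length(nv)
    if (d <= 1L) return(0)
    eh <- ecount(induced_subgraph(net, c(as.integer(nv), i))) # |E(H)|
    2 * (eh - d) / (d * (d - 1))
  }, numeric(1))
  as.numeric_scores(stats::setNames(vals, igraph::V(net)$name))
}

# ---- shared internals ----

check_network <- function(net) {
  if (!is_igraph(net)) {
    stop("expected an igraph PPI network", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("PPI networks must be undirected", call. = FALSE)
  }
  if (vcount(net) > 0L && is.null(igraph::V(net)$name)) {
    stop("network vertices must be named with protein identifiers",
         call. = FALSE)
  }
  invisible(TRUE)
}

# coerce igraph's numeric vectors to plain named doubles
as.numeric_scores <- function(x) {
  stats::setNames(as.numeric(x), names(x))
}
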