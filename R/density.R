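# Den1 and Den2: the two local-density node measures at the core of the
# LBCC score. Both are edge densities of induced subgraphs around a node —
# Den1 on the closed neighbourhood (radius 1), Den2 on the closed ball of
# radius 2. Balls are built by breadth-first expansion, which is equivalent
# to unioning neighbour sets but easier to reason about.

#' Closed-neighbourhood density Den1
#'
#' For `H` the subgraph induced by \eqn{N_v \cup \{v\}},
#' \deqn{Den_1(v) = \frac{2|E(H)|}{|V(H)|(|V(H)|-1)}.}
#' A degree-1 node has `H = K2`, hence `Den1 = 1`; an isolated node scores 0
#' (the formula is 0/0 there). Values lie in `[0, 1]`, and `Den1(v) = 1`
#' exactly when the closed neighbourhood induces a clique.
#'
#' Den1 is a reparametrisation of the local clustering coefficient: for
#' degree >= 2, \eqn{Den_1(v) = ((|N_v|-1)\,LCC(v) + 2) / (|N_v|+1)}.
#'
#' @param net An igraph PPI network with named vertices.
#' @return Named numeric vector in `[0, 1]`.
#' @export
den1 <- function(net) {
  ball_density(net, order = 1L)
}

#' Radius-2 ball density Den2
#'
#' Same density formula as [den1()], but `H` is the subgraph induced by `v`
#' together with every node at distance 1 or 2 from `v` (the closed ball of
#' radius 2). Isolated nodes score 0. When the radius-2 ball coincides with
#' the closed neighbourhood (no node at distance exactly 2), `Den2 = Den1`.
#'
#' @inheritParams den1
#' @return Named numeric vector in `[0, 1]`.
#' @export
den2 <- function(net) {
  ball_density(net, order = 2L)
}

# density of the induced closed ball of the given radius around each node
ball_density <- function(net, order) {
  check_network(net)
  n <- vcount(net)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  balls <- ego(net, order = order, nodes = igraph::V(net), mode = "all")
  vals <- vapply(seq_len(n), function(i) {
    b <- balls[[i]]
    nv <- length(b)
    if (nv <= 1L) return(0) # isolated node: 0/0 -> 0
    e <- ecount(induced_subgraph(net, b))
    2 * e / (nv * (nv - 1))
  }, numeric(1))
  as.numeric_scores(stats::setNames(vals, igraph::V(net)$name))
}
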