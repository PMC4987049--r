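# IDC (in-degree centrality of complex), the LBCC combination score, and
# deterministic ranking.

#' LBCC weight set
#'
#' Bundles the four scaling weights of the LBCC combination with the zero
#' floor and log base. Defaults are the published operating point:
#' `a = 1` (Den1), `b = 4` (Den2), `c = 3` (IDC), `d = 1` (BC), floor
#' `0.001`, natural log. Weights must lie in `[0, 10]`.
#'
#' The ranking produced by LBCC does not depend on `log_base` (changing
#' base rescales every term by the same positive constant); only absolute
#' score values differ.
#'
#' @param a,b,c,d Non-negative weights in `[0, 10]` for the Den1, Den2, IDC
#'   and BC terms respectively.
#' @param floor_value Positive value substituted for any factor below it
#'   before taking logs (keeps `log` finite for proteins outside all
#'   complexes, BC-zero leaves, and isolated nodes).
#' @param log_base Positive base != 1 for the logarithms.
#' @return An object of class `lbcc_weights`.
#' @export
lbcc_weights <- function(a = 1, b = 4, c = 3, d = 1,
                         floor_value = 0.001, log_base = exp(1)) {
  w <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 10)) {
    stop("lbcc_weights: a, b, c, d must be finite values in [0, 10]",
         call. = FALSE)
  }
  if (!is.finite(floor_value) || floor_value <= 0) {
    stop("lbcc_weights: floor_value must be > 0", call. = FALSE)
  }
  if (!is.finite(log_base) || log_base <= 0 || log_base == 1) {
    stop("lbcc_weights: log_base must be positive and != 1", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d,
                 floor_value = floor_value, log_base = log_base),
            class = "lbcc_weights")
}

#' @export
print.lbcc_weights <- function(x, ...) {
  cat(sprintf(
    "LBCC weights: a=%g (Den1)  b=%g (Den2)  c=%g (IDC)  d=%g (BC)\n",
    x$a, x$b, x$c, x$d))
  cat(sprintf("  floor=%g  log base=%g\n", x$floor_value, x$log_base))
  invisible(x)
}

#' In-degree centrality of complex (IDC)
#'
#' For each protein `v`, sums over the complexes containing `v` the degree
#' of `v` within the PPI subgraph induced by that complex's members:
#' \deqn{IDC(v) = \sum_{i \in ComplexSet(v)} IN\!-\!Degree(v)_i.}
#' Complex members absent from the network contribute nothing. Proteins in
#' no complex take the floor value (0.001 by default); a computed in-complex
#' degree of 0 (a protein annotated to complexes but with no in-complex
#' interaction) is floored the same way, so IDC is always positive and
#' log-safe.
#'
#' @param net An igraph PPI network with named vertices.
#' @param complexes Named list of character vectors (complex id -> members),
#'   as returned by [load_complexes()].
#' @param floor_value Value assigned when the sum is 0 (default 0.001).
#' @return Named numeric vector over the network's proteins.
#' @export
idc <- function(net, complexes, floor_value = 0.001) {
  check_network(net)
  stopifnot(is.list(complexes))
  ids <- igraph::V(net)$name
  vals <- stats::setNames(numeric(length(ids)), ids)
  for (members in complexes) {
    present <- intersect(unique(members), ids)
    if (length(present) < 2L) next # no in-complex edge possible
    sub <- induced_subgraph(net, present)
    dsub <- degree(sub)
    vals[names(dsub)] <- vals[names(dsub)] + as.numeric(dsub)
  }
  vals[vals == 0] <- floor_value
  vals
}

#' Combine Den1, Den2, IDC and BC into the LBCC score
#'
#' \deqn{LBCC(v) = a \log Den_1'(v) + b \log Den_2'(v) + c \log IDC'(v) +
#'   d \log BC'(v)}
#' where \eqn{x' = \max(x, floor)} for every factor, so the score is finite
#' for BC-zero leaves and isolated nodes as well as for proteins outside
#' all complexes. All four vectors must cover the same protein set and be
#' non-negative.
#'
#' @param den1,den2,idc,bc Named numeric score vectors over the same
#'   proteins (see [den1()], [den2()], [idc()],
#'   [betweenness_centrality()]).
#' @param weights An [lbcc_weights()] object.
#' @return Named numeric vector of LBCC scores.
#' @export
lbcc_combine <- function(den1, den2, idc, bc, weights = lbcc_weights()) {
  stopifnot(inherits(weights, "lbcc_weights"))
  vecs <- list(Den1 = den1, Den2 = den2, IDC = idc, BC = bc)
  ids <- names(vecs[[1L]])
  if (is.null(ids)) stop("lbcc_combine: score vectors must be named",
                         call. = FALSE)
  for (m in names(vecs)) {
    v <- vecs[[m]]
    if (is.null(names(v)) || !setequal(names(v), ids) ||
        length(v) != length(ids)) {
      stop("lbcc_combine: ", m,
           " does not cover the same protein set as Den1", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("lbcc_combine: ", m, " contains negative or non-finite scores",
           call. = FALSE)
    }
  }
  fl <- function(x) pmax(x[ids], weights$floor_value)
  lb <- log(weights$log_base)
  out <- (weights$a * log(fl(den1)) + weights$b * log(fl(den2)) +
          weights$c * log(fl(idc)) + weights$d * log(fl(bc))) / lb
  stats::setNames(as.numeric(out), ids)
}

#' Score a network with LBCC in one call
#'
#' Convenience wrapper: computes Den1, Den2, IDC and BC on the network and
#' combines them with [lbcc_combine()].
#'
#' @inheritParams idc
#' @param weights An [lbcc_weights()] object.
#' @return Named numeric vector of LBCC scores.
#' @export
lbcc_score <- function(net, complexes, weights = lbcc_weights()) {
  lbcc_combine(den1(net), den2(net),
               idc(net, complexes, floor_value = weights$floor_value),
               betweenness_centrality(net), weights = weights)
}

#' Rank proteins by descending score
#'
#' Produces the total, reproducible ordering every evaluation routine
#' consumes: descending score, ties broken by ascending protein identifier
#' (C-locale byte order, so the order is platform-independent).
#'
#' @param scores Named numeric vector.
#' @return A data frame with columns `protein` and `score`, one row per
#'   protein, in rank order.
#' @export
rank_proteins <- function(scores) {
  stopifnot(is.numeric(scores))
  if (length(scores) == 0L) {
    return(data.frame(protein = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(scores)) || anyNA(scores)) {
    stop("rank_proteins: scores must be a named vector without NAs",
         call. = FALSE)
  }
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(protein = names(scores)[ord], score = as.numeric(scores)[ord],
             stringsAsFactors = FALSE)
}
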