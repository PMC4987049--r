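# Dispatcher over the fixed measure vocabulary, used by the CLI and the
# benchmark driver.

#' The measure names understood by [score_network()]
#' @export
MEASURES <- c("DC", "BC", "SC", "EC", "LAC", "NC", "LCC",
              "DEN1", "DEN2", "IDC", "LBCC")

#' Compute one or more node measures on a PPI network
#'
#' @param net An igraph PPI network with named vertices.
#' @param measures Character vector drawn from
#'   `DC, BC, SC, EC, LAC, NC, LCC, DEN1, DEN2, IDC, LBCC`
#'   (case-insensitive).
#' @param complexes Complex collection, required for `IDC` and `LBCC`.
#' @param weights An [lbcc_weights()] object, used by `LBCC` (and supplying
#'   the `IDC` floor).
#' @return Named list of named numeric score vectors, one per measure.
#' @export
score_network <- function(net, measures = "LBCC", complexes = NULL,
                          weights = lbcc_weights()) {
  check_network(net)
  measures <- toupper(measures)
  unknown <- setdiff(measures, MEASURES)
  if (length(unknown) > 0L) {
    stop("score_network: unknown measure(s): ",
         paste(unknown, collapse = ", "),
         " (expected one of ", paste(MEASURES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(measures %in% c("IDC", "LBCC")) && is.null(complexes)) {
    stop("score_network: IDC and LBCC require a complex collection",
         call. = FALSE)
  }
  # compute shared ingredients once
  need <- function(m) m %in% measures
  cache <- list()
  if (need("BC") || need("LBCC")) {
    cache$BC <- betweenness_centrality(net)
  }
  if (need("DEN1") || need("LBCC")) cache$DEN1 <- den1(net)
  if (need("DEN2") || need("LBCC")) cache$DEN2 <- den2(net)
  if (need("IDC") || need("LBCC")) {
    cache$IDC <- idc(net, complexes, floor_value = weights$floor_value)
  }
  out <- lapply(stats::setNames(measures, measures), function(m) {
    switch(m,
      DC = degree_centrality(net),
      BC = cache$BC,
      SC = subgraph_centrality(net),
      EC = eigenvector_centrality(net),
      LAC = lac(net),
      NC = nc(net),
      LCC = lcc(net),
      DEN1 = cache$DEN1,
      DEN2 = cache$DEN2,
      IDC = cache$IDC,
      LBCC = lbcc_combine(cache$DEN1, cache$DEN2, cache$IDC, cache$BC,
                          weights = weights)
    )
  })
  out
}
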