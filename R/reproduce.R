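# End-to-end benchmark driver: given the three input files of one dataset,
# score every measure, rank, and emit the full evaluation battery. This is
# the machinery behind the `reproduce` CLI subcommand; pointed at the
# published yeast datasets (YMIPS etc.) it regenerates the corresponding
# benchmark tables, and it runs identically on synthetic fixtures.

#' Run the full scoring and evaluation chain on one dataset
#'
#' Loads a PPI edge list, an essential-protein list and a complex
#' collection; scores every requested measure; ranks each; and computes
#' top-k true-essential counts, the six statistics at the top-`fraction`
#' cutoff, and the difference analysis of LBCC against every other
#' measure at depth `diff_k`. If `out_dir` is given, writes
#' `scores.tsv`, `topk.tsv`, `statistics.tsv`, `differences.tsv` and
#' per-measure `curve_<measure>.tsv` (rank, tp, precision, recall), each
#' with a provenance header.
#'
#' @param network_path,essentials_path,complexes_path Input files in the
#'   formats read by [load_ppi_network()], [load_essentials()],
#'   [load_complexes()].
#' @param measures Measures to run (default all of [MEASURES]).
#' @param weights An [lbcc_weights()] object.
#' @param ks Ranks for the top-k counts.
#' @param fraction Top-fraction cutoff for the confusion statistics.
#' @param diff_k Depth for the pairwise difference analysis.
#' @param out_dir Optional output directory (created if missing).
#' @return A list: `network_summary` (proteins, interactions, average
#'   degree, essentials in network), `scores`, `rankings`, `top_k`
#'   (matrix measure x k), `statistics` (matrix measure x statistic),
#'   `differences` (LBCC vs each other measure), `curves`.
#' @export
reproduce_benchmarks <- function(network_path, essentials_path,
                                 complexes_path,
                                 measures = MEASURES,
                                 weights = lbcc_weights(),
                                 ks = seq(100L, 600L, by = 100L),
                                 fraction = 0.2, diff_k = 100L,
                                 out_dir = NULL) {
  net <- load_ppi_network(network_path)
  essentials <- load_essentials(essentials_path)
  complexes <- load_complexes(complexes_path)
  run_benchmarks(net, essentials, complexes, measures = measures,
                 weights = weights, ks = ks, fraction = fraction,
                 diff_k = diff_k, out_dir = out_dir,
                 provenance = c(
                   network = network_path,
                   essentials = essentials_path,
                   complexes = complexes_path))
}

#' Run the benchmark battery on in-memory objects
#'
#' Same protocol as [reproduce_benchmarks()], starting from an igraph
#' network, an essential-id vector and a complex list (e.g. a
#' [generate_fixture()] result).
#'
#' @param net igraph PPI network.
#' @param essentials Character vector of essential ids.
#' @param complexes Named list of complexes.
#' @inheritParams reproduce_benchmarks
#' @param provenance Optional named character vector recorded in output
#'   headers.
#' @return See [reproduce_benchmarks()].
#' @export
run_benchmarks <- function(net, essentials, complexes,
                           measures = MEASURES,
                           weights = lbcc_weights(),
                           ks = seq(100L, 600L, by = 100L),
                           fraction = 0.2, diff_k = 100L,
                           out_dir = NULL, provenance = character(0)) {
  check_network(net)
  n_nodes <- vcount(net)
  ess_in_net <- intersect(essentials, igraph::V(net)$name)
  n_outside <- length(essentials) - length(ess_in_net)
  if (n_outside > 0L) {
    message("run_benchmarks: ", n_outside,
            " essential id(s) not present in the network (ignored)")
  }
  network_summary <- c(
    proteins = n_nodes,
    interactions = ecount(net),
    average_degree = if (n_nodes > 0L) 2 * ecount(net) / n_nodes else 0,
    essential_proteins = length(ess_in_net)
  )

  scores <- score_network(net, measures = measures, complexes = complexes,
                          weights = weights)
  rankings <- lapply(scores, rank_proteins)
  ks <- ks[ks <= n_nodes]
  if (length(ks) == 0L) ks <- n_nodes

  top_k <- do.call(rbind, lapply(rankings, function(r) {
    as.numeric(top_k_true(r, ess_in_net, ks))
  }))
  colnames(top_k) <- ks

  stats_tab <- t(vapply(rankings, function(r) {
    confusion_statistics(confusion_at_fraction(r, ess_in_net, fraction))
  }, numeric(6)))

  others <- setdiff(names(rankings), "LBCC")
  differences <- NULL
  if ("LBCC" %in% names(rankings) && length(others) > 0L &&
      diff_k <= n_nodes) {
    differences <- lapply(stats::setNames(others, others), function(m) {
      method_difference(rankings[["LBCC"]], rankings[[m]], ess_in_net,
                        k = diff_k)
    })
  }

  curves <- lapply(rankings, function(r) {
    if (length(ess_in_net) > 0L) pr_curve(r, ess_in_net)
    else jackknife_curve(r, ess_in_net)
  })

  result <- list(network_summary = network_summary, scores = scores,
                 rankings = rankings, top_k = top_k,
                 statistics = stats_tab, differences = differences,
                 curves = curves)
  if (!is.null(out_dir)) {
    write_benchmark_reports(result, out_dir, weights = weights,
                            provenance = provenance)
  }
  result
}

write_benchmark_reports <- function(result, out_dir, weights,
                                    provenance = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(weights, provenance)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
  }
  emit(cbind(data.frame(protein = names(result$scores[[1L]][
    order(names(result$scores[[1L]]), method = "radix")])),
    as.data.frame(lapply(result$scores, function(s) {
      s[order(names(s), method = "radix")]
    }))), "scores.tsv")
  emit(data.frame(measure = rownames(result$top_k),
                  result$top_k, check.names = FALSE), "topk.tsv")
  emit(data.frame(measure = rownames(result$statistics),
                  result$statistics, check.names = FALSE), "statistics.tsv")
  if (!is.null(result$differences)) {
    emit(do.call(rbind, lapply(names(result$differences), function(m) {
      d <- result$differences[[m]]
      data.frame(measure = m, k = d$k,
                 intersection = d$intersection_size,
                 lbcc_only = d$a_only_size,
                 essential_in_lbcc_only = d$essential_in_a_only,
                 essential_in_other_only = d$essential_in_b_only)
    })), "differences.tsv")
  }
  for (m in names(result$curves)) {
    emit(result$curves[[m]], paste0("curve_", m, ".tsv"))
  }
  invisible(out_dir)
}

provenance_header <- function(weights, provenance = character(0)) {
  lines <- c(
    paste0("# lbcc ", as.character(utils::packageVersion("lbcc"))),
    sprintf("# weights: a=%g b=%g c=%g d=%g floor=%g log_base=%g",
            weights$a, weights$b, weights$c, weights$d,
            weights$floor_value, weights$log_base)
  )
  if (length(provenance) > 0L) {
    sums <- vapply(provenance, function(p) {
      if (file.exists(p)) unname(tools::md5sum(p)) else "NA"
    }, character(1))
    lines <- c(lines, sprintf("# input %s: %s md5=%s",
                              names(provenance), provenance, sums))
  }
  lines
}
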