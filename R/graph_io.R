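# Readers and writers for the three plain-text input formats (PPI edge
# lists, essential-protein lists, complex collections) and for score tables.
# Identifiers are opaque case-sensitive strings, stripped of surrounding
# whitespace and never remapped.

#' Read a PPI network from a two-column edge list
#'
#' Reads a whitespace-delimited protein-pair file into an undirected simple
#' igraph graph. Lines starting with `#` and blank lines are ignored; columns
#' beyond the first two (e.g. confidence scores) are ignored. Self-loops are
#' dropped and duplicate pairs (in either orientation) collapsed; both counts
#' are reported via `message()`. Proteins that appear only in dropped
#' self-loops are kept as isolated nodes.
#'
#' @param path Path to the edge-list file.
#' @param delim Regular expression splitting fields; default any run of
#'   whitespace (covers tab- and space-delimited dumps).
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   protein identifiers.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "C C"), f)
#' g <- load_ppi_network(f)
#' igraph::vcount(g) # 3 (C kept, isolated)
#' igraph::ecount(g) # 1
#' @export
load_ppi_network <- function(path, delim = "[[:space:]]+") {
  lines <- read_clean_lines(path)
  if (nrow(lines) == 0L) {
    return(make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines$text), delim)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- lines$lineno[which(nf < 2L)[1L]]
    stop("edge-list parse error: line ", bad, " of '", path,
         "' has fewer than 2 fields", call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  build_network(a, b)
}

# Shared constructor: vectors of endpoint ids -> simple undirected igraph.
build_network <- function(a, b) {
  stopifnot(length(a) == length(b))
  nodes <- sort(unique(c(a, b)))
  loop <- a == b
  if (any(loop)) {
    message("load_ppi_network: dropped ", sum(loop), " self-loop(s)")
  }
  a2 <- a[!loop]
  b2 <- b[!loop]
  # canonical orientation so {u,v} and {v,u} collapse together
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("load_ppi_network: collapsed ", sum(dup), " duplicate edge(s)")
  }
  g <- make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (any(!dup)) {
    idx <- rbind(match(lo[!dup], nodes), match(hi[!dup], nodes))
    g <- add_edges(g, as.vector(idx))
  }
  g
}

#' Read an essential-protein list
#'
#' Accepts either one identifier per line, or a two-column id/flag table
#' with flag in `{essential, nonessential}` (case-insensitive); rows flagged
#' nonessential are excluded from the returned set. Duplicates are removed
#' with a reported count.
#'
#' @param path Path to the file.
#' @return Character vector of unique essential-protein identifiers.
#' @export
load_essentials <- function(path) {
  lines <- read_clean_lines(path)
  if (nrow(lines) == 0L) return(character(0))
  fields <- strsplit(trimws(lines$text), "[[:space:]]+")
  ids <- character(0)
  for (f in fields) {
    if (length(f) >= 2L && tolower(f[2L]) %in% c("essential", "nonessential")) {
      if (tolower(f[2L]) == "essential") ids <- c(ids, f[1L])
    } else {
      ids <- c(ids, f[1L])
    }
  }
  ndup <- sum(duplicated(ids))
  if (ndup > 0L) {
    message("load_essentials: removed ", ndup, " duplicate identifier(s)")
  }
  unique(ids)
}

#' Read a protein-complex collection
#'
#' Wide format (default): one complex per line, first token the complex id,
#' remaining tokens the member proteins. Long format: two columns
#' `complex_id member`, one membership per line. Members are deduplicated
#' within each complex; row order of first appearance is preserved.
#'
#' @param path Path to the file.
#' @param format `"wide"` or `"long"`.
#' @return Named list of character vectors (complex id -> member ids).
#' @export
load_complexes <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  lines <- read_clean_lines(path)
  if (nrow(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(trimws(lines$text), "[[:space:]]+")
  if (format == "wide") {
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      bad <- lines$lineno[which(nf < 2L)[1L]]
      stop("complex parse error: row at line ", bad, " of '", path,
           "' has no member proteins", call. = FALSE)
    }
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids)) {
      stop("complex parse error: duplicate complex id '",
           ids[duplicated(ids)][1L], "'", call. = FALSE)
    }
    members <- lapply(fields, function(f) unique(f[-1L]))
    names(members) <- ids
    members
  } else {
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      bad <- lines$lineno[which(nf < 2L)[1L]]
      stop("complex parse error: line ", bad, " of '", path,
           "' needs two columns (complex_id, member)", call. = FALSE)
    }
    cid <- vapply(fields, `[[`, character(1), 1L)
    mem <- vapply(fields, `[[`, character(1), 2L)
    lapply(split(mem, factor(cid, levels = unique(cid))), unique)
  }
}

#' Write one or more score vectors as a TSV table
#'
#' @param scores Named numeric vector (one measure) or a named list of named
#'   numeric vectors (several measures over the same proteins). List names
#'   become column headers; a single unnamed vector is written as `score`.
#' @param path Output path.
#' @return Invisibly, the data frame written. Rows are in ascending
#'   identifier order; columns are `protein` then one per measure.
#' @export
write_scores <- function(scores, path) {
  if (is.numeric(scores)) scores <- list(score = scores)
  stopifnot(is.list(scores), length(scores) >= 1L)
  if (is.null(names(scores))) {
    names(scores) <- paste0("score", seq_along(scores))
  }
  ref <- sort(names(scores[[1L]]))
  for (m in names(scores)) {
    ids <- names(scores[[m]])
    if (is.null(ids) || !identical(sort(ids), ref)) {
      stop("write_scores: measure '", m,
           "' does not cover the same protein set as the first measure",
           call. = FALSE)
    }
  }
  df <- data.frame(protein = ref, stringsAsFactors = FALSE)
  for (m in names(scores)) df[[m]] <- unname(scores[[m]][ref])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a network back out as a two-column edge list
#'
#' Edges are written in canonical orientation (lexicographically smaller
#' endpoint first) and sorted, so output is deterministic. Isolated nodes
#' are written as `id<TAB>id` self-loop lines: [load_ppi_network()] drops
#' the loop but keeps the node, so the node set round-trips exactly.
#'
#' @param net An igraph PPI network.
#' @param path Output path.
#' @param keep_isolated Preserve isolated nodes via the self-loop
#'   convention (default TRUE).
#' @export
write_edge_list <- function(net, path, keep_isolated = TRUE) {
  stopifnot(is_igraph(net))
  el <- as_edgelist(net, names = TRUE)
  out <- character(0)
  if (nrow(el) > 0L) {
    lo <- pmin(el[, 1L], el[, 2L])
    hi <- pmax(el[, 1L], el[, 2L])
    out <- sort(paste(lo, hi, sep = "\t"))
  }
  if (keep_isolated) {
    iso <- names(which(degree(net) == 0L))
    if (length(iso) > 0L) {
      out <- c(paste(sort(iso), sort(iso), sep = "\t"), out)
    }
  }
  writeLines(out, path)
  invisible(path)
}

# readLines with comment/blank stripping; keeps original line numbers for
# error messages. Returns data.frame(text, lineno) or zero-row equivalent.
read_clean_lines <- function(path) {
  if (!file.exists(path)) {
    stop("input error: file not found: '", path, "'", call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", raw)
  out <- data.frame(text = raw[keep], lineno = which(keep),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out[0, ])
  out
}
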