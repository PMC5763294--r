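#' Construct an undirected PPI network
#'
#' Stores a simple undirected graph: self-loops are dropped (with a message),
#' duplicate and reversed-duplicate edges collapse to one, and node degrees
#' are computed once at construction. Degrees are frozen: every downstream
#' quantity (descent direction, coefficient variation, orientation) reads
#' them from this map, and diffusion never recomputes them after edges are
#' consumed.
#'
#' @param from,to character vectors of interacting protein ids.
#' @return An object of class `ppi_network`: list with `nodes` (character),
#'   `edges` (data.frame `from`/`to`, lexicographically ordered within and
#'   across rows) and `degree` (named integer).
#' @export
ppi_network <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
  }
  if (!length(from)) stop("network has no edges")
  a <- pmin(from, to); b <- pmax(from, to)
  edges <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  degree <- table(factor(c(edges$from, edges$to), levels = nodes))
  structure(list(
    nodes = nodes,
    edges = edges,
    degree = stats::setNames(as.integer(degree), nodes)
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "proteins,", nrow(x$edges), "interactions",
      sprintf("(degree %d-%d)\n", min(x$degree), max(x$degree)))
  invisible(x)
}

#' Read an undirected PPI edge list from TSV
#'
#' Headerless, two tab-separated columns of protein ids per row; an optional
#' numeric third column is interpreted as an interaction confidence score and
#' rows below `min_confidence` are dropped before the network is built (the
#' score plays no further role). Extra columns are ignored. Duplicate rows,
#' reversed duplicates and self-loops collapse or drop as in [ppi_network()].
#'
#' @param x path to the TSV, or a character vector of its lines.
#' @param min_confidence optional numeric threshold on the third column.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(x, min_confidence = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty edge list")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("edge list line ", bad[[1L]], " has fewer than 2 tab-separated columns")
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  if (!is.null(min_confidence)) {
    conf <- vapply(fields, function(f) {
      if (length(f) >= 3L) suppressWarnings(as.numeric(f[[3L]])) else NA_real_
    }, 0)
    keep <- is.na(conf) | conf >= min_confidence
    from <- from[keep]; to <- to[keep]
  }
  ppi_network(from, to)
}

check_node <- function(net, v) {
  if (length(v) != 1L || !v %in% net$nodes) stop("unknown protein: ", v)
  invisible(v)
}

#' Descent direction of functional specificity
#'
#' Compares the degrees of two proteins: `1` if `d(vi) < d(vj)` (vi is the
#' proactive, more functionally specific endpoint), `0` if equal, `-1` if
#' `d(vi) > d(vj)`. Functional specificity is read as descending along the
#' +1 direction, from the low-degree protein toward the high-degree hub.
#'
#' @param net a [ppi_network()].
#' @param vi,vj protein ids (need not be an interacting pair).
#' @return integer in `{-1, 0, 1}`.
#' @export
descent_direction <- function(net, vi, vj) {
  check_node(net, vi); check_node(net, vj)
  di <- net$degree[[vi]]; dj <- net$degree[[vj]]
  if (di < dj) 1L else if (di > dj) -1L else 0L
}

#' Coefficient variation between two proteins
#'
#' `CV(vi, vj) = |1/d(vi) - 1/d(vj)|`: the package's measure of functional
#' difference between interacting proteins. Symmetric; zero exactly when the
#' degrees are equal; always in `[0, 1)` for degrees >= 1.
#'
#' @inheritParams descent_direction
#' @return non-negative real.
#' @export
coefficient_variation <- function(net, vi, vj) {
  check_node(net, vi); check_node(net, vj)
  abs(1 / net$degree[[vi]] - 1 / net$degree[[vj]])
}

#' Orient a PPI network by degree
#'
#' Each undirected interaction becomes one oriented arch from its low-degree
#' (proactive) endpoint to its high-degree (reactive) endpoint; equal-degree
#' pairs become a single bidirectional arch with lexicographic endpoint
#' order. The descent direction `o_value = O(source, target)` and coefficient
#' variation `cv` are precomputed per arch.
#'
#' @param net a [ppi_network()].
#' @return data.frame with columns `source`, `target`, `bidirectional`,
#'   `o_value`, `cv`; one row per undirected edge.
#' @export
orient_network <- function(net) {
  d_from <- net$degree[net$edges$from]
  d_to <- net$degree[net$edges$to]
  swap <- d_to < d_from
  source <- ifelse(swap, net$edges$to, net$edges$from)
  target <- ifelse(swap, net$edges$from, net$edges$to)
  bidirectional <- d_from == d_to
  out <- data.frame(
    source = source,
    target = target,
    bidirectional = bidirectional,
    o_value = ifelse(bidirectional, 0L, 1L),
    cv = abs(1 / d_from - 1 / d_to),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
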