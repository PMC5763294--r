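#' Construct a GO DAG object
#'
#' Builds the in-memory term hierarchy used throughout the package. Terms are
#' arranged per sub-ontology (namespace) as a rooted directed acyclic graph
#' through their `is_a` parents; each namespace must contain exactly one root
#' (a term without parents) and every term must be reachable from it.
#'
#' @param ids character vector of term accessions (unique).
#' @param parents named list mapping each term id to a character vector of its
#'   parent ids (possibly empty). Terms absent from the list are parentless.
#' @param namespace named character vector mapping term id to its
#'   sub-ontology, or a single string recycled for all terms.
#' @param term_names optional named character vector of human-readable names.
#' @param alt optional named character vector mapping alternate ids to
#'   canonical ids.
#' @return An object of class `go_dag` with fields `id`, `name`, `namespace`,
#'   `parents`, `children`, `roots`, `g_total`, `alt`.
#' @export
go_dag <- function(ids, parents = list(), namespace = "biological_process",
                   term_names = NULL, alt = character()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(namespace) == 1L && is.null(names(namespace))) {
    namespace <- stats::setNames(rep(namespace, length(ids)), ids)
  }
  namespace <- namespace[ids]
  if (anyNA(namespace)) stop("namespace missing for some terms")

  full_parents <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    p <- unique(as.character(parents[[id]]))
    if (length(p)) {
      missing <- setdiff(p, ids)
      if (length(missing)) {
        stop("term ", id, " has unknown parent(s): ", paste(missing, collapse = ", "))
      }
      if (any(namespace[p] != namespace[[id]])) {
        stop("term ", id, " has parent(s) in a different namespace")
      }
      if (id %in% p) stop("term ", id, " is its own parent")
    }
    full_parents[[id]] <- p
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in full_parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  roots <- character()
  for (ns in unique(namespace)) {
    ns_ids <- ids[namespace == ns]
    parentless <- ns_ids[vapply(full_parents[ns_ids], length, 1L) == 0L]
    if (length(parentless) != 1L) {
      stop("namespace ", ns, " must have exactly one root, found: ",
           paste(parentless, collapse = ", "))
    }
    roots[[ns]] <- parentless
  }

  dag <- structure(list(
    id = ids,
    name = if (is.null(term_names)) stats::setNames(ids, ids) else term_names[ids],
    namespace = namespace,
    parents = full_parents,
    children = lapply(children, function(x) sort(unique(x))),
    roots = roots,
    g_total = vapply(split(ids, namespace[ids]), length, 1L),
    alt = alt,
    cache = new.env(parent = emptyenv())
  ), class = "go_dag")

  order <- topo_order(dag)  # errors on cycles
  unreachable <- setdiff(ids, c(reachable_from_roots(dag), roots))
  if (length(unreachable)) {
    stop("term(s) not reachable from their namespace root: ",
         paste(unreachable, collapse = ", "))
  }
  dag$cache$topo <- order
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$id), "terms in", length(x$roots), "namespace(s)\n")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": ", x$g_total[[ns]], " terms, root ", x$roots[[ns]], "\n", sep = "")
  }
  invisible(x)
}

# Kahn topological order over the whole DAG; stops naming a cycle member.
topo_order <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in dag$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(dag$id)) {
    cyc <- setdiff(dag$id, out)
    stop("cycle detected in is_a hierarchy involving term ", cyc[[1L]])
  }
  out
}

reachable_from_roots <- function(dag) {
  seen <- character(0)
  frontier <- unname(dag$roots)
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

check_term <- function(dag, term_id) {
  if (length(term_id) != 1L || !term_id %in% dag$id) {
    stop("unknown term: ", term_id)
  }
  invisible(term_id)
}

# Resolve possibly-alternate ids to canonical ones; unknown ids become NA.
resolve_term <- function(dag, ids) {
  out <- ifelse(ids %in% dag$id, ids,
                ifelse(ids %in% names(dag$alt), unname(dag$alt[ids]), NA_character_))
  as.character(out)
}

#' Term depth in the GO hierarchy
#'
#' Depth is the number of nodes on the longest `is_a` path from the namespace
#' root down to the term, the root itself counting as depth 1. With multiple
#' parents the maximum over parents applies.
#'
#' @param dag a [go_dag()].
#' @param term_id a term accession.
#' @return positive integer depth.
#' @export
term_depth <- function(dag, term_id) {
  check_term(dag, term_id)
  depth_map(dag)[[term_id]]
}

depth_map <- function(dag) {
  if (!is.null(dag$cache$depth)) return(dag$cache$depth)
  depth <- stats::setNames(rep(1L, length(dag$id)), dag$id)
  for (v in dag$cache$topo) {
    ps <- dag$parents[[v]]
    if (length(ps)) depth[[v]] <- 1L + max(depth[ps])
  }
  dag$cache$depth <- depth
  depth
}

#' Number of transitive descendants of a term
#'
#' Counts distinct terms below `term_id` through `is_a` (the term itself is
#' excluded; terms reachable by several paths count once).
#'
#' @inheritParams term_depth
#' @return non-negative integer.
#' @export
descendant_count <- function(dag, term_id) {
  check_term(dag, term_id)
  length(descendant_sets(dag)[[term_id]])
}

descendant_sets <- function(dag) {
  if (!is.null(dag$cache$desc)) return(dag$cache$desc)
  desc <- stats::setNames(vector("list", length(dag$id)), dag$id)
  for (v in rev(dag$cache$topo)) {
    ch <- dag$children[[v]]
    desc[[v]] <- if (length(ch)) {
      unique(c(ch, unlist(desc[ch], use.names = FALSE)))
    } else character(0)
  }
  dag$cache$desc <- desc
  desc
}

#' Transitive ancestors of a term
#'
#' All terms reachable upward through `is_a`, including the namespace root and
#' excluding the term itself. This is the closure used by the True Path Rule:
#' a protein annotated with a term is implicitly annotated with every
#' ancestor.
#'
#' @inheritParams term_depth
#' @return character vector of term ids (possibly empty), sorted.
#' @export
ancestors <- function(dag, term_id) {
  check_term(dag, term_id)
  anc <- ancestor_sets(dag)
  anc[[term_id]]
}

ancestor_sets <- function(dag) {
  if (!is.null(dag$cache$anc)) return(dag$cache$anc)
  anc <- stats::setNames(vector("list", length(dag$id)), dag$id)
  for (v in dag$cache$topo) {
    ps <- dag$parents[[v]]
    anc[[v]] <- if (length(ps)) {
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    } else character(0)
  }
  dag$cache$anc <- anc
  anc
}

#' Semantic value of a GO term
#'
#' `S(g) = dep(g) * (1 - log(desc(g) + 1) / log(G_total))`, where `dep` is the
#' longest-path depth (root = 1), `desc` the number of transitive descendants
#' and `G_total` the number of terms in the term's sub-ontology. The value is
#' large for deep terms with few descendants — i.e. specific functions; the
#' namespace root scores exactly 0. The logarithm base cancels in the ratio.
#'
#' @inheritParams term_depth
#' @return non-negative real.
#' @export
semantic_value <- function(dag, term_id) {
  check_term(dag, term_id)
  semantic_index(dag)$sem_value[[term_id]]
}

#' Precompute depth, descendant counts and semantic values
#'
#' @param dag a [go_dag()].
#' @param override optional named numeric vector of semantic values replacing
#'   the computed ones for the named terms (used by fixtures that posit
#'   semantic values directly).
#' @return An object of class `semantic_index`: list with named numeric
#'   vectors `depth`, `desc_count`, `sem_value`.
#' @export
semantic_index <- function(dag, override = NULL) {
  idx <- dag$cache$sem_index
  if (is.null(idx)) {
    if (any(dag$g_total < 2L)) {
      stop("semantic values need at least 2 terms per namespace (log(G_total) = 0 otherwise)")
    }
    depth <- depth_map(dag)
    desc <- vapply(descendant_sets(dag), length, 1L)
    g_tot <- dag$g_total[dag$namespace[dag$id]]
    sem <- depth * (1 - log(desc[dag$id] + 1) / log(g_tot))
    sem <- pmax(stats::setNames(as.numeric(sem), dag$id), 0)
    idx <- structure(list(depth = depth, desc_count = desc, sem_value = sem),
                     class = "semantic_index")
    dag$cache$sem_index <- idx
  }
  if (!is.null(override)) {
    idx$sem_value[names(override)] <- override
    idx <- structure(idx, class = "semantic_index")
  }
  idx
}

#' Relatives of a GO term
#'
#' The candidate terms that may replace a known term when it crosses an
#' interaction: parents, grandparents, children, grandchildren and siblings
#' (terms sharing at least one parent). The term itself is excluded; all
#' relatives live in the term's namespace by construction.
#'
#' @inheritParams term_depth
#' @return sorted character vector of term ids (possibly empty).
#' @export
relatives <- function(dag, term_id) {
  check_term(dag, term_id)
  cache <- dag$cache
  if (is.null(cache$relatives)) cache$relatives <- new.env(parent = emptyenv())
  hit <- cache$relatives[[term_id]]
  if (!is.null(hit)) return(hit)
  parents <- dag$parents[[term_id]]
  grandparents <- unlist(dag$parents[parents], use.names = FALSE)
  children <- dag$children[[term_id]]
  grandchildren <- unlist(dag$children[children], use.names = FALSE)
  siblings <- unlist(dag$children[parents], use.names = FALSE)
  out <- sort(setdiff(unique(c(parents, grandparents, children,
                               grandchildren, siblings)), term_id))
  cache$relatives[[term_id]] <- out
  out
}
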