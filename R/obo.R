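#' Parse a GO ontology in OBO 1.2 flat-file format
#'
#' Reads `[Term]` stanzas, honouring `id`, `name`, `namespace`, `is_a`,
#' `alt_id` and `is_obsolete`; `relationship: part_of` lines are used as
#' additional parent links only when `include_part_of = TRUE`. Obsolete terms
#' are dropped entirely (they carry no parents and never enter the indexes);
#' alternate ids resolve to their canonical term.
#'
#' @param x path to an OBO file, or a character vector of its lines.
#' @param include_part_of also treat `part_of` relationships as parent links.
#' @return a [go_dag()].
#' @export
parse_obo <- function(x, include_part_of = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) { if (!is.null(cur)) terms[[length(terms) + 1L]] <<- cur }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush(cur); cur <- NULL
      in_term <- identical(line, "[Term]")
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) != 3L) {
      stop("malformed OBO stanza line ", i, ": ", line)
    }
    key <- m[[2L]]; val <- m[[3L]]
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (is.null(cur)) cur <- list(is_a = character(), alt_id = character(),
                                  part_of = character(), obsolete = FALSE)
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (key == "relationship") {
      rel <- strsplit(val, "\\s+")[[1L]]
      if (length(rel) >= 2L && rel[[1L]] == "part_of") {
        cur$part_of <- c(cur$part_of, rel[[2L]])
      }
    }
  }
  flush(cur)

  terms <- Filter(function(t) !is.null(t$id), terms)
  live <- Filter(function(t) !isTRUE(t$obsolete), terms)
  if (!length(live)) stop("no non-obsolete [Term] stanzas found")

  ids <- vapply(live, `[[`, "", "id")
  ns <- vapply(live, function(t) t$namespace %||% "biological_process", "")
  nm <- stats::setNames(vapply(live, function(t) t$name %||% t$id, ""), ids)
  parents <- stats::setNames(lapply(live, function(t) {
    p <- t$is_a
    if (include_part_of) p <- c(p, t$part_of)
    p
  }), ids)
  # parents referencing obsolete/unknown terms are dropped, not errors
  parents <- lapply(parents, function(p) intersect(p, ids))

  alt <- character()
  for (t in live) {
    if (length(t$alt_id)) alt[t$alt_id] <- t$id
  }

  go_dag(ids, parents = parents, namespace = stats::setNames(ns, ids),
         term_names = nm, alt = alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a go_dag back out as a minimal OBO 1.2 document
#'
#' Emits only the fields the package itself consumes (`id`, `name`,
#' `namespace`, `is_a`), which is enough to round-trip synthetic ontologies.
#'
#' @param dag a [go_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (id in dag$id) {
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$name[[id]]),
             paste0("namespace: ", dag$namespace[[id]]),
             paste0("is_a: ", dag$parents[[id]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
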