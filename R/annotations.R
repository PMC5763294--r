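#' Evidence codes excluded from prediction inputs
#'
#' The default exclusion set removes electronically inferred and
#' curator-derived annotations (IEA, NR, ND, IC). The extended set used for
#' the interaction annotation-group analyses additionally removes IPI and IGI
#' annotations, which are themselves derived from interactions and would make
#' the degree/annotation comparison circular.
#'
#' @name evidence_exclusions
#' @export
default_excluded_codes <- c("IEA", "NR", "ND", "IC")

#' @rdname evidence_exclusions
#' @export
analysis_excluded_codes <- c("IEA", "NR", "ND", "IC", "IPI", "IGI")

#' Construct an annotation set
#'
#' @param protein character vector of protein ids.
#' @param term character vector of term ids (same length), resolved against
#'   `dag` (alternate ids map to their canonical term).
#' @param dag the companion [go_dag()].
#' @param evidence optional character vector of evidence codes (default "NA").
#' @return An object of class `annotation_set`: list with a `records`
#'   data.frame (protein, term, evidence, namespace) and the companion dag's
#'   namespaces.
#' @export
annotation_set <- function(protein, term, dag, evidence = NULL) {
  stopifnot(length(protein) == length(term))
  if (is.null(evidence)) evidence <- rep("NA", length(protein))
  term <- resolve_term(dag, as.character(term))
  keep <- !is.na(term)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " annotation record(s) referenced terms absent from the ontology and were dropped")
  }
  records <- unique(data.frame(
    protein = as.character(protein)[keep],
    term = term[keep],
    evidence = as.character(evidence)[keep],
    namespace = unname(dag$namespace[term[keep]]),
    stringsAsFactors = FALSE
  ))
  records <- records[order(records$protein, records$term), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$records), "records,",
      length(unique(x$records$protein)), "proteins\n")
  print(table(x$records$namespace))
  invisible(x)
}

#' Protein-to-term index of an annotation set
#'
#' @param aset an [annotation_set()].
#' @param namespace restrict to one sub-ontology (default: all).
#' @return named list mapping protein id to a sorted character vector of
#'   term ids.
#' @export
annotation_index <- function(aset, namespace = NULL) {
  rec <- aset$records
  if (!is.null(namespace)) rec <- rec[rec$namespace == namespace, , drop = FALSE]
  lapply(split(rec$term, rec$protein), function(x) sort(unique(x)))
}

#' Parse protein annotations (GAF 2.x or two-column TSV)
#'
#' GAF columns 2 (DB object id), 4 (qualifier), 5 (GO id), 7 (evidence code)
#' are used; comment lines starting with `!` are skipped; rows whose
#' qualifier contains `NOT` are dropped; rows with excluded evidence codes
#' are dropped; term ids are resolved through alternate ids and rows whose
#' term is absent from the ontology are dropped with a message. A headerless
#' two-column `protein<TAB>term` file is accepted as a fallback dialect, in
#' which case the evidence code is recorded as `"NA"` and no evidence filter
#' applies.
#'
#' @param x path to the annotation file, or a character vector of its lines.
#' @param dag the companion [go_dag()].
#' @param excluded_codes evidence codes to drop (see [default_excluded_codes]).
#' @return an [annotation_set()].
#' @export
parse_annotations <- function(x, dag, excluded_codes = default_excluded_codes) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) {
    warning("no annotation rows found")
    return(annotation_set(character(), character(), dag))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))

  if (ncol_min >= 7L) {  # GAF dialect
    protein <- vapply(fields, `[[`, "", 2L)
    qualifier <- vapply(fields, `[[`, "", 4L)
    term <- vapply(fields, `[[`, "", 5L)
    evidence <- vapply(fields, `[[`, "", 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier) & !(evidence %in% excluded_codes)
    aset <- annotation_set(protein[keep], term[keep], dag, evidence[keep])
  } else if (ncol_min >= 2L) {  # minimal protein<TAB>term dialect
    protein <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
    aset <- annotation_set(protein, term, dag)
  } else {
    stop("annotation rows need at least 2 tab-separated columns")
  }
  if (nrow(aset$records) == 0L) {
    warning("no annotation records survived evidence/term filtering")
  }
  aset
}
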