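#' CAFA-style precision of a prediction map
#'
#' Average over the `m` proteins carrying at least one predicted term of
#' `|K(x) ∩ P(x)| / |P(x)|`, where `K(x)` are the known and `P(x)` the
#' predicted terms of protein `x`.
#'
#' @param known named list mapping protein id to known term ids.
#' @param predicted named list mapping protein id to predicted term ids.
#' @return real in `[0, 1]`; 0 (with a warning) if nothing was predicted.
#' @export
precision <- function(known, predicted) {
  predicted <- predicted[vapply(predicted, length, 1L) > 0L]
  if (!length(predicted)) {
    warning("no protein has predictions; precision undefined, returning 0")
    return(0)
  }
  ratios <- vapply(names(predicted), function(x) {
    k <- known[[x]]
    length(intersect(k, predicted[[x]])) / length(predicted[[x]])
  }, 0)
  mean(ratios)
}

#' CAFA-style recall over a target set
#'
#' Average over all target proteins of `|K(x) ∩ P(x)| / |K(x)|`; targets
#' without predictions contribute 0, targets with no known terms are
#' excluded with a warning (the ratio is undefined for them).
#'
#' @inheritParams precision
#' @param targets character vector of target protein ids.
#' @return real in `[0, 1]`.
#' @export
recall <- function(known, predicted, targets) {
  k_len <- vapply(targets, function(x) length(known[[x]]), 1L)
  if (any(k_len == 0L)) {
    warning(sum(k_len == 0L), " target(s) with no known terms excluded from recall")
    targets <- targets[k_len > 0L]
  }
  if (!length(targets)) return(0)
  ratios <- vapply(targets, function(x) {
    p <- predicted[[x]]
    if (!length(p)) 0 else length(intersect(known[[x]], p)) / length(known[[x]])
  }, 0)
  mean(ratios)
}

#' Harmonic mean of precision and recall
#'
#' @param p,r precision and recall in `[0, 1]`.
#' @return `2pr/(p + r)`, or 0 when both are 0.
#' @export
f_measure <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

eval_result <- function(p, r, n_predicted, n_targets) {
  structure(list(precision = p, recall = r, f_measure = f_measure(p, r),
                 n_predicted = n_predicted, n_targets = n_targets),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F %.4f  (m = %d of %d targets predicted)\n",
              x$precision, x$recall, x$f_measure, x$n_predicted, x$n_targets))
  invisible(x)
}

# Close each protein's term set upward over ancestors.
tpr_close <- function(index, dag) {
  anc <- ancestor_sets(dag)
  lapply(index, function(terms) {
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
}

#' Hide-and-recover evaluation of diffusion
#'
#' Hides the complete annotation sets of a random fraction of the annotated
#' proteins, diffuses from the remaining ones, and scores the hidden
#' proteins as targets.
#'
#' @param net a [ppi_network()].
#' @param dag a [go_dag()].
#' @param annotations an [annotation_set()] or named list of term vectors.
#' @param fraction_hidden fraction in (0, 1) of annotated proteins to hide.
#' @param rng_seed integer seed making the holdout split reproducible.
#' @param config a [diffusion_config()].
#' @param sem optional [semantic_index()].
#' @param tpr_closure close both known and predicted sets over ancestors
#'   before scoring (default: compare the sets as-is).
#' @return an `eval_result` (precision, recall, F, counts).
#' @export
holdout_evaluate <- function(net, dag, annotations, fraction_hidden = 0.3,
                             rng_seed = 1L, config = diffusion_config(),
                             sem = NULL, tpr_closure = FALSE) {
  stopifnot(fraction_hidden > 0, fraction_hidden < 1)
  ns <- config$namespace
  if (is.null(ns) && length(dag$roots) == 1L) ns <- names(dag$roots)
  known <- if (inherits(annotations, "annotation_set")) {
    annotation_index(annotations, namespace = ns)
  } else {
    lapply(annotations, function(x) sort(unique(as.character(x))))
  }
  known <- known[names(known) %in% net$nodes]
  known <- known[vapply(known, length, 1L) > 0L]
  annotated <- names(known)
  n_hide <- round(fraction_hidden * length(annotated))
  if (n_hide < 1L || n_hide >= length(annotated)) {
    stop("fraction_hidden leaves no targets or no seeds (",
         length(annotated), " annotated proteins)")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  hidden <- sort(sample(annotated, n_hide))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  visible <- known[setdiff(annotated, hidden)]
  state <- diffuse(net, dag, visible, config = config, sem = sem)
  predicted <- state$annotations[names(state$annotations) %in% hidden]
  predicted <- predicted[vapply(predicted, length, 1L) > 0L]

  k <- known[hidden]
  p <- predicted
  if (tpr_closure) {
    k <- tpr_close(k, dag)
    p <- tpr_close(p, dag)
  }
  eval_result(precision(k, p), recall(k, p, hidden),
              n_predicted = length(p), n_targets = length(hidden))
}

#' Classify one interaction by the annotations of its endpoints
#'
#' `same` if the two proteins share at least one term; otherwise `similar`
#' if both carry terms of at least one common sub-ontology; otherwise
#' `related` if both are annotated but only in disjoint sub-ontologies;
#' `unanalyzable` if either protein has no annotation.
#'
#' @param terms_i,terms_j character vectors of term ids for each endpoint.
#' @param term_namespace named character vector mapping term id to
#'   sub-ontology (e.g. `dag$namespace`).
#' @return one of `"same"`, `"similar"`, `"related"`, `"unanalyzable"`.
#' @export
classify_interaction <- function(terms_i, terms_j, term_namespace) {
  if (!length(terms_i) || !length(terms_j)) return("unanalyzable")
  if (length(intersect(terms_i, terms_j))) return("same")
  if (length(intersect(unique(term_namespace[terms_i]),
                       unique(term_namespace[terms_j])))) return("similar")
  "related"
}

#' Group every interaction of a network by endpoint annotations
#'
#' Applies [classify_interaction()] to each edge; annotations should already
#' be filtered with the extended evidence exclusions
#' ([analysis_excluded_codes]) to avoid judging interactions by
#' interaction-derived annotations.
#'
#' @param net a [ppi_network()].
#' @param annotations an [annotation_set()] or named list of term vectors.
#' @param dag the companion [go_dag()].
#' @return data.frame: one row per edge with `from`, `to`, `group`.
#' @export
classify_interactions <- function(net, annotations, dag) {
  index <- if (inherits(annotations, "annotation_set")) {
    annotation_index(annotations)
  } else {
    annotations
  }
  group <- vapply(seq_len(nrow(net$edges)), function(i) {
    classify_interaction(index[[net$edges$from[[i]]]],
                         index[[net$edges$to[[i]]]],
                         dag$namespace)
  }, "")
  cbind(net$edges, data.frame(group = group, stringsAsFactors = FALSE))
}

#' Annotation-group report for a network
#'
#' Counts interactions in the same/similar/related annotation groups;
#' percentages are taken over the analyzable interactions only (both
#' endpoints annotated), with unanalyzable interactions reported separately.
#'
#' @inheritParams classify_interactions
#' @return list of class `interaction_group_report` with `n_total`,
#'   `n_same`, `n_similar`, `n_related`, `n_unanalyzable` and `pct_same`,
#'   `pct_similar`, `pct_related`.
#' @export
interaction_group_report <- function(net, annotations, dag) {
  cls <- classify_interactions(net, annotations, dag)
  n_un <- sum(cls$group == "unanalyzable")
  n_same <- sum(cls$group == "same")
  n_similar <- sum(cls$group == "similar")
  n_related <- sum(cls$group == "related")
  n_total <- n_same + n_similar + n_related
  pct <- function(n) if (n_total == 0L) NA_real_ else 100 * n / n_total
  structure(list(n_total = n_total, n_same = n_same, n_similar = n_similar,
                 n_related = n_related, n_unanalyzable = n_un,
                 pct_same = pct(n_same), pct_similar = pct(n_similar),
                 pct_related = pct(n_related)),
            class = "interaction_group_report")
}

#' @export
print.interaction_group_report <- function(x, ...) {
  cat(sprintf("interactions analyzable: %d (unanalyzable: %d)\n", x$n_total, x$n_unanalyzable))
  cat(sprintf("  same:    %6d (%5.1f%%)\n", x$n_same, x$pct_same))
  cat(sprintf("  similar: %6d (%5.1f%%)\n", x$n_similar, x$pct_similar))
  cat(sprintf("  related: %6d (%5.1f%%)\n", x$n_related, x$pct_related))
  invisible(x)
}

#' Degree concordance within an annotation group
#'
#' Splits the interactions of one annotation group by whether the two
#' endpoints have equal degree in the network.
#'
#' @inheritParams classify_interactions
#' @param group `"same"` or `"similar"`.
#' @return list with `n_total`, `n_same_degree`, `n_diff_degree`,
#'   `pct_same_degree`, `pct_diff_degree`.
#' @export
degree_concordance <- function(net, annotations, dag, group = c("same", "similar")) {
  group <- match.arg(group)
  cls <- classify_interactions(net, annotations, dag)
  cls <- cls[cls$group == group, , drop = FALSE]
  n <- nrow(cls)
  if (n == 0L) {
    warning("annotation group '", group, "' is empty")
    return(list(n_total = 0L, n_same_degree = 0L, n_diff_degree = 0L,
                pct_same_degree = 0, pct_diff_degree = 0))
  }
  same_deg <- net$degree[cls$from] == net$degree[cls$to]
  list(n_total = n,
       n_same_degree = sum(same_deg),
       n_diff_degree = sum(!same_deg),
       pct_same_degree = 100 * mean(same_deg),
       pct_diff_degree = 100 * mean(!same_deg))
}

#' Box-plot summary of coefficient-variation values
#'
#' First/second/third quartiles (linear-interpolation quantile rule) and the
#' arithmetic mean — the statistics drawn in a box-whisker comparison of
#' annotation groups.
#'
#' @param cv_values non-empty numeric vector of coefficient variations.
#' @return named list `q1`, `median`, `q3`, `mean`.
#' @export
cv_distribution_summary <- function(cv_values) {
  if (!length(cv_values)) stop("cv_values is empty")
  q <- stats::quantile(cv_values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(q1 = q[[1L]], median = q[[2L]], q3 = q[[3L]], mean = mean(cv_values))
}
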