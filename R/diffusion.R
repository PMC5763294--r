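#' Diffusion configuration
#'
#' @param convention exponent convention for the ideal semantic value.
#'   `"worked_example"` (default) scales a known term's semantic value by
#'   `(1 + CV)^(+O)`; `"equation4"` uses `(1 + CV)^(-O)`. The two are
#'   reciprocal images of each other (their product is the squared known
#'   value).
#' @param tie_policy `"all_ties"` keeps every relative at the minimal
#'   distance from the ideal value; `"lexicographic_first"` keeps only the
#'   smallest term id among them.
#' @param max_iterations safety cap on diffusion iterations; the algorithm
#'   provably halts within one iteration per protein, so the cap only
#'   triggers on a deliberately small value (with a warning).
#' @param namespace sub-ontology to diffuse; `NULL` means the ontology's
#'   single namespace (an error if it has several).
#' @return list of class `diffusion_config`.
#' @export
diffusion_config <- function(convention = c("worked_example", "equation4"),
                             tie_policy = c("all_ties", "lexicographic_first"),
                             max_iterations = 100000L,
                             namespace = NULL) {
  structure(list(
    convention = match.arg(convention),
    tie_policy = match.arg(tie_policy),
    max_iterations = as.integer(max_iterations),
    namespace = namespace
  ), class = "diffusion_config")
}

#' Ideal semantic value across an oriented interaction
#'
#' Given a known term of semantic value `s_known` on one endpoint of an
#' interaction, the ideal term for the other endpoint has semantic value
#' `(1 + cv)^(+o) * s_known` under the `worked_example` convention (the
#' default), or `(1 + cv)^(-o) * s_known` under `equation4`. With `o = 1`
#' (diffusing from the proactive, more specific protein toward the hub) the
#' default convention *raises* the target specificity scale by the
#' coefficient variation; with `o = -1` it lowers it; with `o = 0`
#' (equal-degree partners) the value passes through unchanged.
#'
#' @param s_known non-negative semantic value of the known term.
#' @param o descent direction in `{-1, 0, 1}` along the diffusion direction.
#' @param cv coefficient variation of the interaction (must be 0 when
#'   `o = 0`).
#' @param convention `"worked_example"` or `"equation4"`.
#' @return non-negative real.
#' @export
ideal_semantic_value <- function(s_known, o, cv,
                                 convention = c("worked_example", "equation4")) {
  convention <- match.arg(convention)
  stopifnot(length(o) == 1L, o %in% c(-1L, 0L, 1L), cv >= 0, s_known >= 0)
  if (o == 0L && cv != 0) {
    stop("contract violation: o = 0 requires cv = 0 (equal degrees)")
  }
  expo <- if (convention == "worked_example") o else -o
  (1 + cv)^expo * s_known
}

#' Select the relatives closest to an ideal semantic value
#'
#' Scans the relatives of a known term (parents, grandparents, siblings,
#' children, grandchildren) and returns the minimizer(s) of
#' `|S(relative) - ideal_value|`.
#'
#' @param dag a [go_dag()].
#' @param sem a [semantic_index()] for `dag`.
#' @param known_term the known term whose relatives are candidates.
#' @param ideal_value target semantic value.
#' @param tie_policy `"all_ties"` (every minimizer) or
#'   `"lexicographic_first"` (smallest term id among minimizers).
#' @param tol absolute tolerance under which two distances count as tied.
#' @return sorted character vector of selected term ids (empty if the term
#'   has no relatives).
#' @export
select_relatives <- function(dag, sem, known_term, ideal_value,
                             tie_policy = c("all_ties", "lexicographic_first"),
                             tol = 1e-9) {
  tie_policy <- match.arg(tie_policy)
  rel <- relatives(dag, known_term)
  if (!length(rel)) return(character(0))
  dist <- abs(sem$sem_value[rel] - ideal_value)
  winners <- sort(rel[dist <= min(dist) + tol])
  if (tie_policy == "lexicographic_first") winners[1L] else winners
}

# ---- diffusion state ----------------------------------------------------

empty_history <- function() {
  data.frame(iteration = integer(), protein = character(),
             term = character(), source_protein = character(),
             source_term = character(), ideal_value = numeric(),
             selected_value = numeric(), stringsAsFactors = FALSE)
}

new_diffusion_state <- function(net, oriented, annotations, sem, config) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(oriented))) {
    s <- oriented$source[[i]]; t <- oriented$target[[i]]
    adj[[s]] <- c(adj[[s]], i)
    adj[[t]] <- c(adj[[t]], i)
  }
  structure(list(
    annotations = annotations,
    retired_seeds = character(0),
    consumed_edges = integer(0),
    history = empty_history(),
    iteration = 0L,
    net = net,
    oriented = oriented,
    adj = adj,
    sem = sem,
    config = config
  ), class = "diffusion_state")
}

#' @export
print.diffusion_state <- function(x, ...) {
  ann <- x$annotations[vapply(x$annotations, length, 1L) > 0L]
  cat("diffusion_state:", x$iteration, "iteration(s),",
      length(ann), "annotated protein(s),",
      nrow(x$history), "prediction record(s),",
      length(x$consumed_edges), "/", nrow(x$oriented), "edges consumed\n")
  invisible(x)
}

usable_edges <- function(state, v) {
  setdiff(state$adj[[v]], state$consumed_edges)
}

protein_terms <- function(state, v) {
  t <- state$annotations[[v]]
  if (is.null(t)) character(0) else t
}

#' Select the seed proteins for one diffusion iteration
#'
#' Candidates are the annotated, not-yet-retired proteins that still have at
#' least one non-consumed incident edge. They are scanned greedily in
#' descending order of annotation specificity (the maximum semantic value
#' among a protein's current terms; ties broken by protein id), and a
#' candidate adjacent through a usable edge to a seed already chosen in this
#' iteration is deferred to a later iteration — the chosen seed's own
#' processing covers that edge. This reproduces the intended behaviour that
#' a protein whose annotated partner is diffusing this round waits its turn.
#'
#' @param state a `diffusion_state`.
#' @param oriented the oriented edge table (defaults to the one inside
#'   `state`).
#' @return character vector of seed protein ids, sorted.
#' @export
select_seeds <- function(state, oriented = state$oriented) {
  ann <- state$annotations
  candidates <- names(ann)[vapply(ann, length, 1L) > 0L]
  candidates <- setdiff(candidates, state$retired_seeds)
  candidates <- candidates[vapply(candidates,
                                  function(v) length(usable_edges(state, v)) > 0L,
                                  TRUE)]
  if (!length(candidates)) return(character(0))
  spec <- vapply(candidates, function(v) max(state$sem$sem_value[ann[[v]]]), 0)
  candidates <- candidates[order(-spec, candidates)]
  seeds <- character(0)
  for (v in candidates) {
    e <- usable_edges(state, v)
    partners <- c(oriented$source[e], oriented$target[e])
    if (!any(partners %in% seeds)) seeds <- c(seeds, v)
  }
  sort(seeds)
}

#' Diffuse terms across the edges of one seed protein
#'
#' Implements one seed's share of an iteration, reading the annotation state
#' as of the start of the iteration (`state`) and returning the prediction
#' records to merge at iteration end:
#'
#' * forward (step 2): across every usable incident edge, each known term of
#'   the seed produces its ideal semantic value along the seed-to-partner
#'   direction and the closest relative(s) annotate the partner; on
#'   bidirectional (equal-degree) edges the terms are instead copied
#'   verbatim, and only onto partners not yet annotated.
#' * reverse (step 3): partners that were annotated before this iteration
#'   and are reactive (higher degree) or equal to the seed diffuse their
#'   terms back onto the seed the same way, along the partner-to-seed
#'   direction.
#' * True Path Rule guard: a candidate term that already annotates the
#'   target, or is an ancestor of one of the target's terms, is discarded
#'   (an ancestor adds no information under the True Path Rule).
#'
#' @param state a `diffusion_state` snapshot at iteration start.
#' @param seed a seed protein id (from [select_seeds()]).
#' @param dag a [go_dag()].
#' @param sem a [semantic_index()] (defaults to the one inside `state`).
#' @param oriented oriented edge table (defaults to the one inside `state`).
#' @param config a [diffusion_config()] (defaults to the one inside `state`).
#' @return data.frame of prediction records (columns as in the diffusion
#'   history).
#' @export
propagate_from_seed <- function(state, seed, dag, sem = state$sem,
                                oriented = state$oriented,
                                config = state$config) {
  seed_terms <- protein_terms(state, seed)
  if (!length(seed_terms)) stop("contract violation: seed ", seed, " has no known terms")
  anc <- ancestor_sets(dag)
  recs <- list()
  add <- function(protein, term, source_protein, source_term, ideal, selected) {
    recs[[length(recs) + 1L]] <<- data.frame(
      iteration = state$iteration, protein = protein, term = term,
      source_protein = source_protein, source_term = source_term,
      ideal_value = ideal, selected_value = selected, stringsAsFactors = FALSE)
  }
  # TPR guard relative to the target's snapshot terms
  guard <- function(candidate, target_terms) {
    if (candidate %in% target_terms) return(FALSE)          # no-op duplicate
    !any(vapply(target_terms, function(t) candidate %in% anc[[t]], TRUE))
  }
  diffuse_terms <- function(from, to, terms, o, cv) {
    to_terms <- protein_terms(state, to)
    for (g in terms) {
      s_g <- sem$sem_value[[g]]
      if (o == 0L) {
        if (guard(g, to_terms)) add(to, g, from, g, s_g, s_g)
      } else {
        ideal <- ideal_semantic_value(s_g, o, cv, config$convention)
        for (cand in select_relatives(dag, sem, g, ideal, config$tie_policy)) {
          if (guard(cand, to_terms)) {
            add(to, cand, from, g, ideal, sem$sem_value[[cand]])
          }
        }
      }
    }
  }

  d <- state$net$degree
  for (e in usable_edges(state, seed)) {
    v <- if (oriented$source[[e]] == seed) oriented$target[[e]] else oriented$source[[e]]
    o_sv <- if (d[[seed]] < d[[v]]) 1L else if (d[[seed]] > d[[v]]) -1L else 0L
    cv <- oriented$cv[[e]]
    v_annotated <- length(protein_terms(state, v)) > 0L
    # step 2: push seed terms to the partner (equal-degree copies only onto
    # unannotated partners; directed pushes regardless)
    if (o_sv != 0L || !v_annotated) {
      diffuse_terms(seed, v, seed_terms, o_sv, cv)
    }
    # step 3: pull from partners annotated before this iteration that are
    # reactive (higher degree) or equal to the seed
    if (v_annotated && d[[v]] >= d[[seed]]) {
      diffuse_terms(v, seed, protein_terms(state, v), -o_sv, cv)
    }
  }
  if (!length(recs)) empty_history() else do.call(rbind, recs)
}

#' Diffuse GO terms through a degree-oriented PPI network
#'
#' Runs the iterative four-step algorithm: (1) select seed proteins; (2)
#' diffuse each seed's known terms to its partners through ideal semantic
#' values and nearest relatives; (3) update each seed from its previously
#' annotated reactive partners; (4) retire the seeds and consume every edge
#' incident to them, then repeat until no seed remains. All propagation in
#' one iteration reads the annotation state as of the iteration's start;
#' writes are merged at iteration end. Degrees are frozen at load time:
#' descent directions and coefficient variations always refer to the
#' original network.
#'
#' @param net a [ppi_network()].
#' @param dag a [go_dag()].
#' @param initial an [annotation_set()] or a named list mapping protein id to
#'   a character vector of term ids.
#' @param config a [diffusion_config()].
#' @param sem optional [semantic_index()] (computed from `dag` if omitted);
#'   pass an overridden index to posit semantic values.
#' @return a `diffusion_state` with final `annotations`, `retired_seeds`,
#'   `consumed_edges`, `history` (one row per prediction, with provenance),
#'   `seed_log` (the seed set of each iteration) and the iteration count.
#' @export
diffuse <- function(net, dag, initial, config = diffusion_config(), sem = NULL) {
  ns <- config$namespace
  if (is.null(ns)) {
    if (length(dag$roots) != 1L) {
      stop("ontology has several namespaces; set diffusion_config(namespace = ...)")
    }
    ns <- names(dag$roots)
  }
  if (is.null(sem)) sem <- semantic_index(dag)
  ann <- if (inherits(initial, "annotation_set")) {
    annotation_index(initial, namespace = ns)
  } else {
    lapply(initial, function(x) sort(unique(as.character(x))))
  }
  ann <- ann[names(ann) %in% net$nodes]
  ann <- ann[vapply(ann, length, 1L) > 0L]
  if (!length(ann)) stop("no initially annotated proteins in the network")
  bad <- setdiff(unlist(ann, use.names = FALSE), dag$id)
  if (length(bad)) stop("initial annotations reference unknown term(s): ",
                        paste(utils::head(bad, 3L), collapse = ", "))

  oriented <- orient_network(net)
  state <- new_diffusion_state(net, oriented, ann, sem, config)
  history <- list()
  state$seed_log <- list()

  repeat {
    state$iteration <- state$iteration + 1L
    seeds <- select_seeds(state)
    if (!length(seeds)) {
      state$iteration <- state$iteration - 1L
      break
    }
    state$seed_log[[state$iteration]] <- seeds
    # snapshot semantics: every seed reads iteration-start annotations
    recs <- lapply(seeds, function(s) propagate_from_seed(state, s, dag))
    recs <- do.call(rbind, recs)
    if (nrow(recs)) {
      history[[length(history) + 1L]] <- recs
      for (i in seq_len(nrow(recs))) {
        p <- recs$protein[[i]]
        state$annotations[[p]] <- sort(unique(c(state$annotations[[p]], recs$term[[i]])))
      }
    }
    state$retired_seeds <- sort(unique(c(state$retired_seeds, seeds)))
    seed_edges <- unique(unlist(state$adj[seeds], use.names = FALSE))
    state$consumed_edges <- sort(unique(c(state$consumed_edges, seed_edges)))
    if (state$iteration >= state$config$max_iterations) {
      if (length(select_seeds(state))) {
        warning("max_iterations reached before diffusion exhausted its seeds; state truncated")
      }
      break
    }
  }
  state$history <- if (length(history)) do.call(rbind, history) else empty_history()
  rownames(state$history) <- NULL
  state
}
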