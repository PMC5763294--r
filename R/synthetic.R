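# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  force(code)
}

#' Generate a toy GO-like DAG
#'
#' Builds a random rooted DAG of `n_terms` terms in one namespace: a backbone
#' chain guarantees `dag_depth` levels, remaining terms attach to random
#' parents (bounded by `max_children` where possible), and a quarter of them
#' gain a second parent, giving diamonds. Pure function of its arguments and
#' seed.
#'
#' @param n_terms number of terms (>= 3).
#' @param dag_depth target number of depth levels (backbone length).
#' @param max_children soft cap on the children of one term.
#' @param namespace namespace label for all terms.
#' @param rng_seed integer seed.
#' @return a [go_dag()].
#' @export
make_toy_dag <- function(n_terms, dag_depth = 4L, max_children = 4L,
                         namespace = "biological_process", rng_seed = 1L) {
  if (n_terms < 3L) stop("n_terms must be >= 3")
  if (dag_depth > n_terms) stop("dag_depth cannot exceed n_terms")
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  with_seed(rng_seed, {
    parents <- stats::setNames(vector("list", n_terms), ids)
    depth <- stats::setNames(integer(n_terms), ids)
    depth[[ids[[1L]]]] <- 1L
    for (i in seq_len(dag_depth)[-1L]) {          # backbone chain
      parents[[ids[[i]]]] <- ids[[i - 1L]]
      depth[[ids[[i]]]] <- i
    }
    n_children <- stats::setNames(integer(n_terms), ids)
    if (dag_depth > 1L) n_children[ids[seq_len(dag_depth - 1L)]] <- 1L
    if (n_terms > dag_depth) {
      for (i in (dag_depth + 1L):n_terms) {
        prior <- ids[seq_len(i - 1L)]
        eligible <- prior[depth[prior] < dag_depth & n_children[prior] < max_children]
        if (!length(eligible)) eligible <- prior[depth[prior] < dag_depth]
        if (!length(eligible)) eligible <- prior
        p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        ps <- p
        if (i > 3L && stats::runif(1) < 0.25) {   # occasional second parent
          extra <- setdiff(prior, ps)
          if (length(extra)) ps <- c(ps, if (length(extra) == 1L) extra else sample(extra, 1L))
        }
        parents[[ids[[i]]]] <- ps
        n_children[ps] <- n_children[ps] + 1L
        depth[[ids[[i]]]] <- 1L + max(depth[ps])
      }
    }
    go_dag(ids, parents = parents, namespace = namespace)
  })
}

#' Generate a synthetic PPI network
#'
#' `barabasi_albert_like` grows a preferential-attachment graph (each new
#' protein attaches to `attachment_param` existing ones), yielding the
#' heavy-tailed, hub-rich degree distribution typical of curated PPI
#' networks. `erdos_renyi_like` draws a density-matched uniform random graph
#' for contrast. In both cases the largest connected component is kept and
#' the graph is simplified.
#'
#' @param n_proteins number of proteins (>= 3) before component extraction.
#' @param model `"barabasi_albert_like"` or `"erdos_renyi_like"`.
#' @param attachment_param edges added per protein (BA), also sets the
#'   matched ER density.
#' @param rng_seed integer seed.
#' @return a [ppi_network()] with protein ids `P0001`, `P0002`, ...
#' @export
make_network <- function(n_proteins,
                         model = c("barabasi_albert_like", "erdos_renyi_like"),
                         attachment_param = 2, rng_seed = 1L) {
  model <- match.arg(model)
  if (n_proteins < 3L) stop("n_proteins must be >= 3")
  if (attachment_param < 1 || attachment_param >= n_proteins) {
    stop("attachment_param must be in [1, n_proteins)")
  }
  with_seed(rng_seed, {
    g <- if (model == "barabasi_albert_like") {
      igraph::sample_pa(n_proteins, m = attachment_param, directed = FALSE)
    } else {
      igraph::sample_gnp(n_proteins, p = min(1, 2 * attachment_param / (n_proteins - 1)))
    }
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el) == 0L) stop("generated network has no edges; raise attachment_param")
    ids <- sprintf("P%04d", seq_len(igraph::vcount(g)))
    ppi_network(ids[el[, 1L]], ids[el[, 2L]])
  })
}

#' Plant annotations under the diffusion model itself
#'
#' Seeds a fraction of the network's locally minimal-degree proteins (those
#' with no lower-degree neighbour — the most proactive proteins) with random
#' deep terms, then generates every other protein's annotations by running
#' the diffusion itself. The returned annotation set is therefore exactly
#' recoverable: hiding all non-source proteins and re-diffusing under the
#' same configuration replays the identical trajectory.
#'
#' @param net a [ppi_network()].
#' @param dag a [go_dag()] with at least 3 depth levels.
#' @param density fraction in (0, 1] of the minimum-degree proteins used as
#'   sources.
#' @param config a [diffusion_config()]; its tie policy and convention are
#'   the generative ones.
#' @param rng_seed integer seed for source and term sampling.
#' @param sem optional [semantic_index()].
#' @param min_depth minimum depth of the terms planted on sources.
#' @return list with `annotations` (named list protein -> terms, the full
#'   planted truth), `sources` (character), `source_annotations` (named
#'   list), and `log` (the diffusion history augmented with a
#'   `tie_partners` column listing, per prediction, every relative tied at
#'   the minimal distance from the ideal value).
#' @export
plant_annotations <- function(net, dag, density = 0.4,
                              config = diffusion_config(tie_policy = "lexicographic_first"),
                              rng_seed = 1L, sem = NULL, min_depth = 3L) {
  if (is.null(sem)) sem <- semantic_index(dag)
  depth <- depth_map(dag)
  if (max(depth) < 3L) stop("dag too shallow for relative steps (need >= 3 depth levels)")
  deep_terms <- dag$id[depth >= min(min_depth, max(depth))]
  nbrs <- neighbour_list(net)
  is_local_min <- vapply(net$nodes, function(v) {
    all(net$degree[[v]] <= net$degree[nbrs[[v]]])
  }, TRUE)
  pool <- net$nodes[is_local_min]
  n_src <- max(1L, ceiling(density * length(pool)))
  with_seed(rng_seed, {
    sources <- sort(sample(pool, n_src))
    src_ann <- stats::setNames(lapply(sources, function(v) {
      k <- sample(1:2, 1L)
      sort(sample(deep_terms, min(k, length(deep_terms))))
    }), sources)
    state <- diffuse(net, dag, src_ann, config = config, sem = sem)
    log <- state$history
    log$tie_partners <- vapply(seq_len(nrow(log)), function(i) {
      if (log$source_term[[i]] == log$term[[i]]) return(log$term[[i]])  # o = 0 copy
      paste(select_relatives(dag, sem, log$source_term[[i]], log$ideal_value[[i]],
                             tie_policy = "all_ties"), collapse = ",")
    }, "")
    list(annotations = state$annotations, sources = sources,
         source_annotations = src_ann, log = log)
  })
}

neighbour_list <- function(net) {
  nb <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[[i]]; b <- net$edges$to[[i]]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

#' The narrated worked-example fixture
#'
#' A hand-built reconstruction of the paper-of-record style walk-through:
#' six named proteins (M, E, L, J, A and a satellite of L) embedded in a
#' larger network of padding proteins that realise the stated degrees
#' (d(M) = d(L) = 3, d(E) = 6, d(J) = d(A) = 4), a nine-term single-namespace
#' DAG in which g4 is an ancestor of g7 and g7, g8 are siblings, and posited
#' semantic values (S(g7) = 0.35, S(g8) = 0.4) supplied as a semantic-index
#' override. Initially M carries g7 and L carries g4. Under the default
#' configuration, iteration 1 selects exactly M as seed (E gains g8 via ideal
#' value 0.408; the pull of L's g4 into M is blocked by the True Path Rule),
#' and iteration 2 selects E and J (L gains g7 via ideal value 0.343; A gains
#' g8 by equal-degree sharing).
#'
#' @return list with `dag`, `sem` (overridden [semantic_index()]), `net`,
#'   `initial` (named list), and `expected` (data.frame of the narrated
#'   prediction records of iterations 1-2).
#' @export
fig3_fixture <- function() {
  dag <- go_dag(
    ids = paste0("g", 1:8),
    parents = list(g2 = "g1", g3 = "g2", g4 = "g1",
                   g5 = "g4", g6 = "g4", g7 = "g6", g8 = "g6"),
    namespace = "biological_process"
  )
  sem <- semantic_index(dag, override = c(
    g1 = 0, g2 = 0.25, g3 = 0.45, g4 = 0.2,
    g5 = 0.33, g6 = 0.3, g7 = 0.35, g8 = 0.4
  ))
  pad <- sprintf("X%02d", 1:10)
  net <- ppi_network(
    from = c("M", "M", "M", "L", "L", "J", "E", "E", "E", "E", "J", "J", "A", "A", "A"),
    to   = c("E", "L", "J", "E", pad[[5L]], "A",
             pad[[1L]], pad[[2L]], pad[[3L]], pad[[4L]],
             pad[[6L]], pad[[7L]], pad[[8L]], pad[[9L]], pad[[10L]])
  )
  stopifnot(net$degree[["M"]] == 3L, net$degree[["E"]] == 6L,
            net$degree[["L"]] == 3L, net$degree[["J"]] == 4L,
            net$degree[["A"]] == 4L)
  expected <- data.frame(
    iteration = c(1L, 1L, 2L, 2L),
    protein = c("E", "J", "L", "A"),
    term = c("g8", "g8", "g7", "g8"),
    source_protein = c("M", "M", "E", "J"),
    source_term = c("g7", "g7", "g8", "g8"),
    ideal_value = c(0.35 * 7 / 6, 0.35 * 13 / 12, 0.4 * 6 / 7, 0.4),
    selected_value = c(0.4, 0.4, 0.35, 0.4),
    stringsAsFactors = FALSE
  )
  list(dag = dag, sem = sem, net = net,
       initial = list(M = "g7", L = "g4"),
       expected = expected)
}
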