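# In-code fixtures shared across the suite.

chain_dag <- function() {
  go_dag(c("r", "a", "b"), parents = list(a = "r", b = "a"))
}

# r <- a <- c and r <- c: c has parents {a, r}
diamond_dag <- function() {
  go_dag(c("r", "a", "c"), parents = list(a = "r", c = c("a", "r")))
}

# t with parent p, grandparent gp (root), child c, grandchild gc, sibling s
family_dag <- function() {
  go_dag(c("gp", "p", "t", "s", "c", "gc"),
         parents = list(p = "gp", t = "p", s = "p", c = "t", gc = "c"))
}

path3_net <- function() ppi_network(c("a", "b"), c("b", "c"))

star_net <- function() ppi_network(rep("a", 3), c("b", "c", "d"))

obo_lines <- function(...) paste(c(...), collapse = "\n")

tiny_obo <- function() obo_lines(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: mid", "namespace: biological_process",
  "is_a: GO:0000001 ! root", "alt_id: GO:0000099", "",
  "[Term]", "id: GO:0000003", "name: leaf", "namespace: biological_process",
  "is_a: GO:0000002", ""
)

# independent brute-force minimizer used as the oracle for select_relatives
brute_force_nearest <- function(dag, sem, term, ideal) {
  rel <- relatives(dag, term)
  if (!length(rel)) return(character(0))
  best <- Inf
  winners <- character(0)
  for (r in rel) {
    d <- abs(sem$sem_value[[r]] - ideal)
    if (d < best - 1e-9) {
      best <- d
      winners <- r
    } else if (d <= best + 1e-9) {
      winners <- c(winners, r)
      best <- min(best, d)
    }
  }
  sort(unique(winners))
}

random_case <- function(seed, n_proteins = 60, n_terms = 20, density = 0.5) {
  dag <- make_toy_dag(n_terms, dag_depth = 4L, rng_seed = seed)
  net <- make_network(n_proteins, attachment_param = 2, rng_seed = seed + 1000L)
  planted <- plant_annotations(net, dag, density = density, rng_seed = seed + 2000L)
  list(dag = dag, net = net, planted = planted)
}

# replay a diffusion history iteration by iteration, asserting that no record
# adds a term that was an ancestor of one of the target's terms at the start
# of that record's iteration; returns the number of violations
count_tpr_violations <- function(dag, initial, history) {
  anc <- lapply(stats::setNames(dag$id, dag$id), function(t) ancestors(dag, t))
  ann <- lapply(initial, identity)
  violations <- 0L
  for (it in sort(unique(history$iteration))) {
    rows <- history[history$iteration == it, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      existing <- ann[[rows$protein[[i]]]]
      blocked <- any(vapply(existing, function(t) rows$term[[i]] %in% anc[[t]], TRUE))
      if (isTRUE(blocked)) violations <- violations + 1L
    }
    for (i in seq_len(nrow(rows))) {
      p <- rows$protein[[i]]
      ann[[p]] <- unique(c(ann[[p]], rows$term[[i]]))
    }
  }
  violations
}
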