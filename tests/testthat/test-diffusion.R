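test_that("ideal semantic value reproduces the worked-example numbers", {
  expect_equal(round(ideal_semantic_value(0.35, 1L, 1 / 6, "worked_example"), 3), 0.408)
  expect_equal(round(ideal_semantic_value(0.4, -1L, 1 / 6, "worked_example"), 3), 0.343)
  expect_equal(ideal_semantic_value(0.7, 0L, 0, "worked_example"), 0.7)
  expect_equal(ideal_semantic_value(0.7, 0L, 0, "equation4"), 0.7)
  expect_error(ideal_semantic_value(0.5, 0L, 0.2), "contract violation")
})

test_that("the two exponent conventions are reciprocal images", {
  for (i in 1:20) {
    s <- runif(1, 0.1, 3); cv <- runif(1, 0, 0.9); o <- sample(c(-1L, 1L), 1)
    we <- ideal_semantic_value(s, o, cv, "worked_example")
    e4 <- ideal_semantic_value(s, o, cv, "equation4")
    expect_equal(we * e4, s^2)
  }
})

test_that("select_relatives agrees with the brute-force minimizer", {
  fam <- family_dag()
  sem <- semantic_index(fam, override = c(gp = 0.30, p = 0.41, s = 0.50,
                                          t = 0.35, c = 0.6, gc = 0.9))
  # nearest to 0.408 among relatives of t is the 0.41 term
  expect_equal(select_relatives(fam, sem, "t", 0.408), "p")
  # symmetric tie at 0.355: 0.30 and 0.41 both at distance 0.055
  sem2 <- semantic_index(fam, override = c(gp = 0.30, p = 0.41, s = 0.30,
                                           t = 0.35, c = 0.6, gc = 0.9))
  expect_setequal(select_relatives(fam, sem2, "t", 0.355, tie_policy = "all_ties"),
                  c("gp", "p", "s"))
  expect_equal(select_relatives(fam, sem2, "t", 0.355, tie_policy = "lexicographic_first"),
               "gp")
  # a two-term namespace's leaf has only the root as relative
  lone <- go_dag(c("r", "x"), parents = list(x = "r"))
  expect_equal(select_relatives(lone, semantic_index(lone), "r", 0.5), "x")

  for (seed in 1:10) {
    dag <- make_toy_dag(30, dag_depth = 5, rng_seed = seed)
    sem <- semantic_index(dag)
    for (k in 1:10) {
      term <- sample(dag$id, 1)
      ideal <- runif(1, 0, max(sem$sem_value))
      expect_equal(select_relatives(dag, sem, term, ideal, "all_ties"),
                   brute_force_nearest(dag, sem, term, ideal))
    }
  }
})

test_that("seed selection retires, defers adjacent candidates, and empties", {
  fx <- fig3_fixture()
  st <- godin:::new_diffusion_state(fx$net, orient_network(fx$net),
                                    fx$initial, fx$sem, diffusion_config())
  # M (g7, S 0.35) outranks L (g4, S 0.2); L is adjacent to M, so defers
  expect_equal(select_seeds(st), "M")
  # no annotated proteins -> no seeds
  st$annotations <- list()
  expect_equal(select_seeds(st), character(0))
})

test_that("propagation composes ideal values, nearest relatives and the TPR guard", {
  fx <- fig3_fixture()
  st <- godin:::new_diffusion_state(fx$net, orient_network(fx$net),
                                    fx$initial, fx$sem, diffusion_config())
  st$iteration <- 1L
  recs <- propagate_from_seed(st, "M", fx$dag)
  # across o = 1, cv = 1/6 the ideal from S = 0.35 is 0.408 -> the S = 0.4 relative
  e_row <- recs[recs$protein == "E", ]
  expect_equal(e_row$term, "g8")
  expect_equal(e_row$ideal_value, 0.35 * 7 / 6)
  # the g4 pulled back from L is an ancestor of M's g7: discarded
  expect_false(any(recs$protein == "M"))
  # equal-degree copy onto an unannotated partner transfers the term verbatim
  eq_net <- ppi_network("a", "b")
  st2 <- godin:::new_diffusion_state(eq_net, orient_network(eq_net),
                                     list(a = "g8"), fx$sem,
                                     diffusion_config())
  st2$iteration <- 1L
  recs2 <- propagate_from_seed(st2, "a", fx$dag)
  expect_equal(recs2$protein, "b")
  expect_equal(recs2$term, "g8")
  expect_error(propagate_from_seed(st2, "b", fx$dag), "contract violation")
})

test_that("diffusion on the worked-example fixture matches the narrated outcome", {
  fx <- fig3_fixture()
  st <- diffuse(fx$net, fx$dag, fx$initial, sem = fx$sem)
  hist <- st$history
  # iteration 1: E and J annotated with g8 from M's g7; nothing else
  it1 <- hist[hist$iteration == 1L, ]
  expect_setequal(it1$protein, c("E", "J"))
  expect_equal(unique(it1$term), "g8")
  # iteration 2: L gains g7 through ideal 0.343, A gains g8 by sharing
  it2 <- hist[hist$iteration == 2L, ]
  expect_equal(it2$term[it2$protein == "L"], "g7")
  expect_equal(it2$ideal_value[it2$protein == "L"], 0.4 * 6 / 7)
  expect_equal(it2$term[it2$protein == "A"], "g8")
  # every narrated record appears verbatim in the history
  merged <- merge(fx$expected, hist,
                  by = c("iteration", "protein", "term", "source_protein", "source_term"))
  expect_equal(nrow(merged), nrow(fx$expected))
  expect_equal(merged$ideal_value.x, merged$ideal_value.y)
  # M retains exactly its initial term; no annotation was ever removed
  expect_equal(st$annotations[["M"]], "g7")
})

test_that("an unannotated component stays unannotated and diffusion still halts", {
  net <- ppi_network(c("a", "b", "x"), c("b", "c", "y"))
  dag <- chain_dag()
  st <- diffuse(net, dag, list(a = "b"))
  expect_true(all(lengths(st$annotations[c("x", "y")]) == 0) ||
                !any(c("x", "y") %in% names(st$annotations)))
  expect_lte(st$iteration, length(net$nodes))
})

test_that("diffusion is deterministic and its state grows monotonically", {
  case <- random_case(7)
  init <- case$planted$source_annotations
  s1 <- diffuse(case$net, case$dag, init)
  s2 <- diffuse(case$net, case$dag, init)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$annotations, s2$annotations)
  # per-iteration monotonic growth of every protein's term set
  hist <- s1$history
  for (p in names(init)) {
    expect_true(all(init[[p]] %in% s1$annotations[[p]]))
  }
  expect_true(all(table(hist$iteration) > 0))
})

test_that("max_iterations truncates with a warning", {
  case <- random_case(8)
  cfg <- diffusion_config(max_iterations = 1L)
  expect_warning(st <- diffuse(case$net, case$dag,
                               case$planted$source_annotations, cfg),
                 "max_iterations")
  expect_equal(st$iteration, 1L)
})

test_that("degrees never change while edges are consumed", {
  case <- random_case(9)
  before <- case$net$degree
  st <- diffuse(case$net, case$dag, case$planted$source_annotations)
  expect_identical(st$net$degree, before)
  expect_gt(length(st$consumed_edges), 0L)
})
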