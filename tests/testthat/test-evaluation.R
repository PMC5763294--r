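test_that("precision, recall and F match their definitions on small cases", {
  known <- list(x = c("a", "b"))
  pred <- list(x = c("a", "c"))
  expect_equal(precision(known, pred), 0.5)
  expect_equal(recall(known, pred, "x"), 0.5)
  expect_equal(f_measure(0.5, 0.5), 0.5)

  # a protein with no predictions is excluded from m but counts in |S|
  known2 <- list(x = c("a", "b"), y = "a")
  pred2 <- list(x = c("a", "c"))
  expect_equal(precision(known2, pred2), 0.5)
  expect_equal(recall(known2, pred2, c("x", "y")), 0.25)

  expect_equal(precision(known2, known2), 1)
  expect_equal(recall(known2, known2, c("x", "y")), 1)
  expect_equal(f_measure(0.7, 0.7), 0.7)
  expect_equal(f_measure(0.6, 0.4), 0.48)
  expect_equal(f_measure(0, 1), 0)
  expect_warning(p0 <- precision(known, list()), "no protein has predictions")
  expect_equal(p0, 0)
  expect_warning(recall(list(x = character()), pred, "x"), "no known terms")
})

test_that("P, R, F stay in [0, 1] on random prediction maps", {
  set.seed(42)
  terms <- paste0("t", 1:12)
  for (i in 1:30) {
    prots <- paste0("p", 1:6)
    known <- setNames(lapply(prots, function(p) sample(terms, sample(1:4, 1))), prots)
    pred <- setNames(lapply(prots, function(p) {
      if (runif(1) < 0.3) character(0) else sample(terms, sample(1:4, 1))
    }), prots)
    p <- precision(known, pred)
    r <- recall(known, pred, prots)
    f <- f_measure(p, r)
    expect_true(p >= 0 && p <= 1)
    expect_true(r >= 0 && r <= 1)
    expect_true(f >= 0 && f <= 1)
    if (isTRUE(all.equal(p, r))) expect_equal(f, p)
  }
})

test_that("interaction classification distinguishes same, similar, related", {
  ns <- c(g1 = "biological_process", g2 = "biological_process",
          g3 = "molecular_function")
  expect_equal(classify_interaction("g1", c("g1", "g2"), ns), "same")
  expect_equal(classify_interaction("g1", "g2", ns), "similar")
  expect_equal(classify_interaction("g1", "g3", ns), "related")
  expect_equal(classify_interaction("g1", character(0), ns), "unanalyzable")
})

test_that("annotation groups partition analyzable edges and percentages sum to 100", {
  dag <- go_dag(c("r1", "x", "z", "r2", "y"),
                parents = list(x = "r1", z = "r1", y = "r2"),
                namespace = c(r1 = "molecular_function", x = "molecular_function",
                              z = "molecular_function",
                              r2 = "biological_process", y = "biological_process"))
  net <- ppi_network(c("p1", "p2", "p3", "p4"), c("p2", "p3", "p4", "p5"))
  ann <- list(p1 = "x", p2 = "x", p3 = "z", p4 = "y")
  rep <- interaction_group_report(net, ann, dag)
  expect_equal(rep$n_same + rep$n_similar + rep$n_related, rep$n_total)
  expect_equal(rep$n_same, 1L)       # p1-p2 share x
  expect_equal(rep$n_similar, 1L)    # p2-p3: x vs z, same namespace
  expect_equal(rep$n_related, 1L)    # p3-p4: MF vs BP
  expect_equal(rep$n_unanalyzable, 1L)  # p4-p5: p5 unannotated
  expect_equal(rep$pct_same + rep$pct_similar + rep$pct_related, 100)
})

test_that("degree concordance splits a group by endpoint degree equality", {
  dag <- go_dag(c("r", "x"), parents = list(x = "r"))
  # triangle a-b-c plus pendant d: degrees a=3,b=2,c=2,d=1
  net <- ppi_network(c("a", "a", "b", "a"), c("b", "c", "c", "d"))
  ann <- list(a = "x", b = "x", c = "x", d = "x")
  dc <- degree_concordance(net, ann, dag, "same")
  expect_equal(dc$n_total, 4L)
  expect_equal(dc$n_same_degree, 1L)  # only b-c
  expect_equal(dc$pct_same_degree + dc$pct_diff_degree, 100)
  star <- star_net()
  dc_star <- degree_concordance(star, list(a = "x", b = "x", c = "x", d = "x"),
                                dag, "same")
  expect_equal(dc_star$pct_same_degree, 0)
  expect_warning(degree_concordance(star, list(a = "x"), dag, "similar"), "empty")
})

test_that("cv distribution summaries use interpolated quartiles and the mean", {
  s <- cv_distribution_summary(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(s$median, 0.25)
  expect_equal(s$mean, 0.25)
  s2 <- cv_distribution_summary(rep(0.3, 5))
  expect_equal(unlist(s2), c(q1 = 0.3, median = 0.3, q3 = 0.3, mean = 0.3))
  expect_equal(cv_distribution_summary(c(0, 1))$median, 0.5)
  expect_error(cv_distribution_summary(numeric(0)), "empty")
})

test_that("holdout evaluation is reproducible and scores hidden proteins", {
  case <- random_case(21)
  ann <- case$planted$annotations
  r1 <- holdout_evaluate(case$net, case$dag, ann, fraction_hidden = 0.3, rng_seed = 5)
  r2 <- holdout_evaluate(case$net, case$dag, ann, fraction_hidden = 0.3, rng_seed = 5)
  expect_identical(r1, r2)
  expect_true(r1$precision >= 0 && r1$precision <= 1)
  expect_lte(r1$n_predicted, r1$n_targets)
  expect_error(holdout_evaluate(case$net, case$dag, ann, fraction_hidden = 1e-6),
               "no targets or no seeds")
})

test_that("diffusion beats verbatim copying on a model-planted benchmark", {
  # under the generative model, partners hold *relatives* of their sources'
  # terms, so copying terms verbatim across edges must score worse
  case <- random_case(31, n_proteins = 80, n_terms = 25)
  truth <- case$planted$annotations
  sources <- case$planted$sources
  hidden <- setdiff(names(truth)[lengths(truth) > 0], sources)
  cfg <- diffusion_config(tie_policy = "lexicographic_first")
  st <- diffuse(case$net, case$dag, case$planted$source_annotations, cfg)
  f_diff <- f_measure(precision(truth[hidden], st$annotations[hidden]),
                      recall(truth[hidden], st$annotations[hidden], hidden))
  # direct-copy baseline: breadth-first inheritance of source terms
  copy_ann <- case$planted$source_annotations
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(case$net$edges))) {
      a <- case$net$edges$from[[i]]; b <- case$net$edges$to[[i]]
      for (pair in list(c(a, b), c(b, a))) {
        have <- copy_ann[[pair[1]]]
        if (length(have) && !length(copy_ann[[pair[2]]])) {
          copy_ann[[pair[2]]] <- have
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  f_copy <- f_measure(precision(truth[hidden], copy_ann[hidden]),
                      recall(truth[hidden], copy_ann[hidden], hidden))
  expect_equal(f_diff, 1)
  expect_gt(f_diff, f_copy)
})
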