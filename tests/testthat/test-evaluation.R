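# Small fixed graph used across the evaluation tests:
# pathway A -> B inside a chain A->B->C->D->E plus a detached edge F->G.
eval_fixture <- function() {
  g <- interactome(data.frame(
    tail = c("A", "B", "C", "D", "F"),
    head = c("B", "C", "D", "E", "G"),
    weight = rep(0.5, 5)), quiet = TRUE)
  truth <- pathway_truth(data.frame(tail = "A", head = "B"), g = g)
  list(g = g, truth = truth)
}

test_that("subsample_negatives honors size, determinism and the clamp rule", {
  fx <- random_graph_fixture(40, 0.2, 1)
  universe <- fx$g$edges
  positives <- universe[1:10, c("tail", "head")]
  neg <- subsample_negatives(universe, positives, neg_ratio = 5, seed = 9)
  expect_equal(nrow(neg), 50)
  expect_length(intersect(edge_key(neg$tail, neg$head),
                          edge_key(positives$tail, positives$head)), 0)
  neg2 <- subsample_negatives(universe, positives, neg_ratio = 5, seed = 9)
  expect_identical(neg, neg2)
  expect_false(identical(
    neg, subsample_negatives(universe, positives, neg_ratio = 5, seed = 10)))

  # ratio exhausting the pool returns all non-positives
  all_neg <- subsample_negatives(universe, positives, neg_ratio = 1e6, seed = 1)
  expect_equal(nrow(all_neg), nrow(universe) - 10)

  expect_error(subsample_negatives(positives, positives, seed = 1), "empty")
  expect_error(subsample_negatives(universe[1:5, ], positives, seed = 1),
               "subset")
})

test_that("precision_recall reproduces hand-computed values", {
  # ranked [P, N, P] at distinct indices, |positives| = 2
  pr <- precision_recall(data.frame(item = c("p1", "n1", "p2"), index = 1:3),
                         positives = c("p1", "p2"), negatives = "n1")
  expect_equal(pr$points$precision, c(1, 0.5, 2 / 3))
  expect_equal(pr$points$recall, c(0.5, 0.5, 1))
  expect_equal(pr$positives_total, 2)

  # all ranked items positive: precision constant 1
  pr <- precision_recall(data.frame(item = c("p1", "p2"), index = 1:2),
                         positives = c("p1", "p2"),
                         negatives = "n1")
  expect_true(all(pr$points$precision == 1))

  # two items tied at index 1, one P one N: a single block point
  pr <- precision_recall(data.frame(item = c("p1", "n1"), index = c(1L, 1L)),
                         positives = c("p1", "p2"), negatives = "n1")
  expect_equal(nrow(pr$points), 1)
  expect_equal(pr$points$recall, 0.5)
  expect_equal(pr$points$precision, 0.5)

  # items in neither set are ignored; recall is nondecreasing
  pr <- precision_recall(data.frame(item = c("p1", "zz", "n1"), index = 1:3),
                         positives = c("p1", "p2"), negatives = "n1")
  expect_equal(nrow(pr$points), 2)
  expect_true(all(diff(pr$points$recall) >= 0))

  expect_error(precision_recall(data.frame(item = "x", index = 1),
                                positives = character(), negatives = "x"),
               "no positives")
  expect_error(precision_recall(data.frame(item = "x", index = 1),
                                positives = "x", negatives = "x"),
               "overlap")
})

test_that("edge distance from the pathway counts undirected hops", {
  fx <- eval_fixture()
  d <- edge_distance_from_pathway(
    data.frame(tail = c("A", "B", "C", "D", "F"),
               head = c("B", "C", "D", "E", "G")),
    fx$truth, fx$g)
  # A->B is the positive; B->C touches pathway node B; C->D is 1 + d(C) = 2;
  # D->E is 1 + d(D) = 3; F->G is disconnected from the pathway
  expect_equal(d, c(0, 1, 2, 3, Inf))
})

test_that("exclude_adjacent_negatives removes exactly the distance-1 edges", {
  fx <- eval_fixture()
  negs <- data.frame(tail = c("B", "C", "D", "F"),
                     head = c("C", "D", "E", "G"))
  kept <- exclude_adjacent_negatives(negs, fx$truth, fx$g)
  expect_equal(edge_key(kept$tail, kept$head),
               c("C -> D", "D -> E", "F -> G"))
})

test_that("recovery_ranks finds the first incident interaction", {
  ranked <- data.frame(tail = c("A", "B", "C"), head = c("B", "C", "R1"),
                       index = c(2L, 3L, 4L))
  rk <- recovery_ranks(ranked, c("R1", "B", "Q"))
  expect_equal(rk$rank, c(4L, 2L, NA_integer_))
})

test_that("perturb_roles removes/adds round(fraction * size) members, seeded", {
  roles <- role_set(sprintf("r%02d", 1:10), sprintf("t%02d", 1:10))
  out <- perturb_roles(roles, 0.3, "remove", seed = 4)
  expect_length(out$receptors, 7)
  expect_length(out$trs, 7)
  expect_true(all(out$receptors %in% roles$receptors))
  expect_identical(perturb_roles(roles, 0.3, "remove", seed = 4), out)

  expect_identical(perturb_roles(roles, 0, "remove", seed = 1)$receptors,
                   roles$receptors)

  pool <- sprintf("x%02d", 1:20)
  out <- perturb_roles(roles, 0.3, "add", candidate_pool = pool, seed = 4)
  expect_length(out$receptors, 13)
  expect_length(out$trs, 13)
  expect_length(intersect(out$receptors, out$trs), 0)

  small <- role_set("r1", "t1")
  expect_error(perturb_roles(small, 0.9, "remove", seed = 1), "empty")
})

test_that("rwr_baseline matches closed forms and the linear-system oracle", {
  fx <- worked_example()
  roles <- fx$roles

  # teleport = 1: stationary mass sits uniformly on the receptors
  rw <- rwr_baseline(fx$interactome, roles, teleport = 1)
  p <- attr(rw, "p")
  expect_equal(unname(p["R"]), 1)
  expect_equal(sum(p), 1)

  # 6-node fixture vs direct dense solve
  g6 <- interactome(data.frame(
    tail = c("a", "a", "b", "c", "d", "e", "b"),
    head = c("b", "c", "d", "d", "e", "a", "f"),
    weight = c(0.9, 0.3, 0.6, 0.4, 0.8, 0.5, 0.7)), quiet = TRUE)
  roles6 <- role_set(c("a", "b"), "e")
  rw <- rwr_baseline(g6, roles6, teleport = 0.4)
  expect_equal(sum(attr(rw, "p")), 1, tolerance = 1e-9)
  expect_equal(attr(rw, "p"), oracle_rwr_solve(g6, roles6, 0.4),
               tolerance = 1e-8)

  # ranked edges: flux nonincreasing, every edge ranked exactly once
  expect_true(all(diff(rw$flux) <= 1e-15))
  expect_equal(rw$index, seq_len(nrow(g6$edges)))

  # iteration cap produces an error that reports the residual
  expect_error(rwr_baseline(g6, roles6, teleport = 0.05, tol = 1e-14,
                            max_iter = 2),
               "residual|converge")
})

test_that("aggregate_pr pools pathways as distinct tagged items", {
  one <- list(ranked = data.frame(item = c("p1", "n1", "p2"), index = 1:3),
              positives = c("p1", "p2"), negatives = "n1")
  # single pathway: identical to its own curve
  solo <- precision_recall(one$ranked, one$positives, one$negatives)
  agg <- aggregate_pr(list(one))
  expect_equal(agg$points[c("precision", "recall")],
               solo$points[c("precision", "recall")])

  # two pathways with identical item names stay distinct; totals add
  agg2 <- aggregate_pr(list(a = one, b = one))
  expect_equal(agg2$positives_total, 4)
  expect_equal(agg2$points$recall[nrow(agg2$points)], 1)
  # identical copies of one pathway reproduce that pathway's curve shape
  expect_equal(unique(agg2$points$precision), solo$points$precision)
})
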