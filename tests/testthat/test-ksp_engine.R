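# cost_graph helper over explicit edges, augmented with s/t around given
# roles; weight chosen so that cost = -log(w) reproduces the requested cost.
cg_from_costs <- function(tail, head, cost, source_to, sink_from) {
  g <- interactome(data.frame(tail = tail, head = head, weight = exp(-cost)),
                   quiet = TRUE)
  augment(g, role_set(source_to, sink_from))
}

test_that("dijkstra is exact, flags unreachable nodes, and tie-breaks", {
  # line graph s -> a -(1.0)-> b -> t with zero-cost artificial edges
  cg <- cg_from_costs("a", "b", 1.0, source_to = "a", sink_from = "b")
  d <- dijkstra(cg, "__source__")
  expect_equal(unname(d$dist["__sink__"]), 1.0)
  expect_equal(unname(d$dist["a"]), 0)

  g <- interactome(data.frame(tail = c("a", "z"), head = c("b", "q"),
                              weight = c(0.5, 0.5)), quiet = TRUE)
  cg <- augment(g, role_set("a", "b"))
  d <- dijkstra(cg, "__source__")
  expect_identical(unname(d$dist["z"]), Inf)

  # diamond with equal-cost branches: predecessor of the join is the
  # lexicographically smaller upstream node
  cg <- cg_from_costs(c("s0", "s0", "a", "b"), c("a", "b", "x", "x"),
                      c(0.5, 0.5, 0.5, 0.5), "s0", "x")
  d <- dijkstra(cg, "s0")
  expect_equal(unname(d$prev["x"]), "a")

  expect_error(dijkstra(cg, "nope"), "not in graph")
})

test_that("reverse_distances gives exact costs-to-sink and a consistent heuristic", {
  cg <- cg_from_costs(c("a", "b"), c("b", "t0"), c(1, 1), "a", "t0")
  h <- reverse_distances(cg)
  expect_equal(unname(h[c("a", "b", "t0")]), c(2, 1, 0))
  expect_equal(unname(h["__sink__"]), 0)

  g <- interactome(data.frame(tail = c("a", "z"), head = c("b", "q"),
                              weight = c(0.5, 0.5)), quiet = TRUE)
  h <- reverse_distances(augment(g, role_set("a", "b")))
  expect_identical(unname(h["z"]), Inf)

  # consistency h(u) <= c(u,v) + h(v) on every edge, and agreement with a
  # Dijkstra run on an explicitly reversed copy of the graph
  for (seed in 1:10) {
    fx <- random_graph_fixture(12, 0.3, seed, n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    h <- reverse_distances(cg)
    slack <- h[cg$nodes[cg$tail]] - (cg$cost + h[cg$nodes[cg$head]])
    expect_true(all(slack <= 1e-12 | is.nan(slack)))

    rev_g <- interactome(data.frame(tail = fx$g$edges$head,
                                    head = fx$g$edges$tail,
                                    weight = fx$g$edges$weight),
                         nodes = fx$g$nodes, quiet = TRUE)
    rev_cg <- augment(rev_g, role_set(fx$roles$trs, fx$roles$receptors))
    d_rev <- dijkstra(rev_cg, "__source__")
    real <- fx$g$nodes
    expect_equal(unname(h[real]), unname(d_rev$dist[real] ))
  }
})

test_that("A* matches a Dijkstra oracle on banned subgraphs", {
  # no bans: equal to the plain shortest path
  fx <- worked_example()
  cg <- augment(fx$interactome, fx$roles)
  h <- reverse_distances(cg)
  p <- astar_shortest_path(cg, "__source__", "__sink__", h)
  expect_equal(p$cost, unname(dijkstra(cg, "__source__")$dist["__sink__"]))
  expect_identical(p$nodes, c("__source__", "R", "A", "X", "__sink__"))

  # banning the only bridge disconnects
  cg1 <- cg_from_costs("a", "b", 1, "a", "b")
  h1 <- reverse_distances(cg1)
  expect_null(astar_shortest_path(cg1, "__source__", "__sink__", h1,
                                  banned_edges = data.frame(tail = "a",
                                                            head = "b")))

  # 100 seeded random graphs with random bans: cost always equals Dijkstra
  # run on the explicitly banned subgraph
  for (seed in 1:100) {
    fx <- random_graph_fixture(12, 0.3, seed, n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    h <- reverse_distances(cg)
    set.seed(seed + 5000)
    ne <- nrow(fx$g$edges)
    ban_e <- fx$g$edges[sample(ne, min(3, ne)), c("tail", "head")]
    ban_n <- sample(setdiff(fx$g$nodes,
                            c(fx$roles$receptors, fx$roles$trs)), 2)
    p <- astar_shortest_path(cg, "__source__", "__sink__", h,
                             banned_edges = ban_e, banned_nodes = ban_n)
    # oracle: rebuild the subgraph without the banned parts, run dijkstra
    keep <- !(edge_key(fx$g$edges$tail, fx$g$edges$head) %in%
                edge_key(ban_e$tail, ban_e$head)) &
      !(fx$g$edges$tail %in% ban_n) & !(fx$g$edges$head %in% ban_n)
    sub_edges <- fx$g$edges[keep, ]
    sub <- interactome(sub_edges, nodes = setdiff(fx$g$nodes, ban_n),
                       quiet = TRUE)
    sub_cg <- augment(sub, role_set(setdiff(fx$roles$receptors, ban_n),
                                    setdiff(fx$roles$trs, ban_n)))
    oracle <- dijkstra(sub_cg, "__source__")$dist[["__sink__"]]
    if (is.null(p)) {
      expect_identical(oracle, Inf)
    } else {
      expect_equal(p$cost, oracle, tolerance = 1e-12)
    }
  }
})

test_that("yen_ksp reproduces the worked two-branch ranking", {
  fx <- worked_example()
  cg <- augment(fx$interactome, fx$roles)
  out <- yen_ksp(cg, k = 2)
  expect_length(out, 2)
  expect_identical(out[[1]]$nodes, c("__source__", "R", "A", "X", "__sink__"))
  expect_identical(out[[2]]$nodes, c("__source__", "R", "B", "X", "__sink__"))
  expect_equal(out[[1]]$score, 0.81)
  expect_equal(out[[2]]$score, 0.25)
  expect_equal(vapply(out, `[[`, 0L, "index"), 1:2)

  # k exceeding the number of simple paths returns them all
  out <- yen_ksp(cg, k = 50)
  expect_length(out, 2)

  # single chain: one path regardless of k
  cg1 <- cg_from_costs("x", "y", 0.3, "x", "y")
  expect_length(yen_ksp(cg1, k = 10), 1)
})

test_that("yen_ksp matches brute-force enumeration on small random graphs", {
  n_checked <- 0
  for (seed in 1:60) {
    fx <- random_graph_fixture(sample(4:9, 1), 0.35, seed,
                               n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    oracle <- brute_force_paths(cg)
    if (!length(oracle)) {
      expect_error(yen_ksp(cg, 5), "no path")
      next
    }
    out <- yen_ksp(cg, k = 8)
    cm <- oracle_cost_map(cg)
    expect_length(out, min(8, length(oracle)))
    for (i in seq_along(out)) {
      expect_equal(out[[i]]$cost, oracle_path_cost(cm, oracle[[i]]),
                   tolerance = 1e-12)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("the A* heuristic is a pure acceleration (identical output)", {
  for (seed in 1:10) {
    fx <- random_graph_fixture(20, 0.2, seed, n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    if (!oracle_has_st_path(cg)) next
    with_a <- yen_ksp(cg, k = 10, use_astar = TRUE)
    without <- yen_ksp(cg, k = 10, use_astar = FALSE)
    expect_identical(lapply(with_a, `[[`, "nodes"),
                     lapply(without, `[[`, "nodes"))
  }
})

test_that("returned paths are cost-sorted with score = exp(-cost)", {
  for (seed in 1:5) {
    fx <- random_graph_fixture(15, 0.25, seed, n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    if (!oracle_has_st_path(cg)) next
    out <- yen_ksp(cg, k = 12)
    costs <- vapply(out, `[[`, 0, "cost")
    scores <- vapply(out, `[[`, 0, "score")
    expect_true(all(diff(costs) >= -1e-12))
    expect_true(all(diff(scores) <= 1e-12))
    expect_equal(scores, exp(-costs), tolerance = 1e-9)
  }
})

test_that("path costs agree with an independent igraph implementation", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 11, 23)) {
    fx <- random_graph_fixture(15, 0.25, seed, n_receptors = 2, n_trs = 2)
    cg <- augment(fx$g, fx$roles)
    if (!oracle_has_st_path(cg)) next
    out <- yen_ksp(cg, k = 6)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = cg$nodes[cg$tail], to = cg$nodes[cg$head],
                 weight = cg$cost))
    ref <- igraph::k_shortest_paths(ig, from = "__source__",
                                    to = "__sink__", k = 6,
                                    weights = igraph::E(ig)$weight)
    cm <- oracle_cost_map(cg)
    ref_costs <- vapply(ref$vpaths, function(vp) {
      oracle_path_cost(cm, match(names(vp), cg$nodes))
    }, 0)
    expect_equal(vapply(out, `[[`, 0, "cost"),
                 ref_costs[seq_along(out)], tolerance = 1e-9)
  }
})
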