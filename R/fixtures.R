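# Synthetic fixtures: seeded random background interactomes with planted
# receptor-to-TR pathways of elevated edge weights. Stands in for curated
# pathway databases so every module is testable end-to-end offline.

#' Specification for a synthetic planted-pathway fixture
#'
#' Defaults describe the reference recovery setting: a 200-node directed
#' Erdos-Renyi background at density 0.05 with probability-like weights from
#' U(0.05, 0.4), and 5 planted receptor-to-intermediate-to-TR chains (one
#' intermediate each, distinct across chains) with weights from U(0.7, 0.95).
#' With these bounds the lowest planted-path score (0.7^2 = 0.49) exceeds the
#' highest score of any path using a background edge (max(0.4, 0.95 * 0.4) =
#' 0.4), so the planted paths are provably the top-scoring receptor-to-TR
#' paths and recovery is guaranteed, not merely likely. Longer chains
#' (`length_range`) are supported but lose that guarantee: a single direct
#' background receptor-to-TR edge of weight 0.4 can outrank a three-edge
#' planted chain (0.7^3 = 0.343).
#'
#' Generation is a pure function of the spec; the PRNG is R's Mersenne
#' -Twister seeded from `seed` (recorded in the metadata the CLI writes).
#'
#' @param n_nodes Number of nodes (default 200).
#' @param edge_prob Background edge probability in \[0, 1\] (default 0.05).
#' @param n_receptors,n_trs Role set sizes (default 5 each).
#' @param n_planted Number of planted paths (default 5); must be >=
#'   max(n_receptors, n_trs) so every receptor and TR lies on a planted path
#'   (roles are assigned round-robin).
#' @param length_range Planted path length in edges, `c(lo, hi)` (default
#'   `c(2, 2)`).
#' @param w_background,w_planted Uniform weight bounds `c(low, high)` within
#'   (0, 1].
#' @param seed Integer seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 200, edge_prob = 0.05, n_receptors = 5,
                         n_trs = 5, n_planted = 5, length_range = c(2, 2),
                         w_background = c(0.05, 0.4),
                         w_planted = c(0.7, 0.95), seed = 1) {
  stopifnot(n_nodes >= 3, edge_prob >= 0, edge_prob <= 1,
            n_receptors >= 1, n_trs >= 1,
            n_receptors + n_trs <= n_nodes,
            n_planted >= max(n_receptors, n_trs),
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            length(w_background) == 2, length(w_planted) == 2,
            w_background[1] > 0, w_background[2] <= 1,
            w_background[1] <= w_background[2],
            w_planted[1] > 0, w_planted[2] <= 1,
            w_planted[1] <= w_planted[2])
  structure(list(n_nodes = as.integer(n_nodes), edge_prob = edge_prob,
                 n_receptors = as.integer(n_receptors),
                 n_trs = as.integer(n_trs),
                 n_planted = as.integer(n_planted),
                 length_range = as.integer(length_range),
                 w_background = w_background, w_planted = w_planted,
                 seed = as.integer(seed), rng = "Mersenne-Twister"),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> n=", x$n_nodes, " p=", x$edge_prob, " |S|=",
      x$n_receptors, " |T|=", x$n_trs, " planted=", x$n_planted,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a random background interactome
#'
#' Directed Erdos-Renyi graph G(n, p) without self-loops; weights i.i.d.
#' uniform on `w_background`. Deterministic given the spec.
#'
#' @param spec A [fixture_spec()].
#' @return An [interactome()] (isolated nodes retained in the node set).
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_nodes
  nodes <- sprintf("P%04d", seq_len(n))
  ti <- rep(seq_len(n), each = n)
  hi <- rep(seq_len(n), times = n)
  keep <- ti != hi
  ti <- ti[keep]; hi <- hi[keep]
  with_seed(spec$seed, {
    pick <- stats::runif(length(ti)) < spec$edge_prob
    ti <- ti[pick]; hi <- hi[pick]
    w <- stats::runif(sum(pick), spec$w_background[1], spec$w_background[2])
  })
  interactome(data.frame(tail = nodes[ti], head = nodes[hi], weight = w,
                         stringsAsFactors = FALSE),
              nodes = nodes, quiet = TRUE)
}

#' Plant a high-weight receptor-to-TR pathway into an interactome
#'
#' Designates disjoint receptor and TR sets, then adds `n_planted` simple
#' paths from receptors to TRs (round-robin over both role sets, so each
#' receptor and each TR lies on at least one planted path) with weights
#' drawn from `w_planted`, overwriting any colliding background edge.
#' Intermediate nodes are drawn from the non-role nodes without replacement
#' across paths, so planted chains never share intermediates (see
#' [fixture_spec()] for why that makes recovery provable). The returned
#' truth records exactly the planted edges and their endpoint nodes.
#'
#' @param g A background [interactome()] (e.g. from
#'   [generate_interactome()]).
#' @param spec The [fixture_spec()].
#' @return List with `interactome` (planted graph), `roles` ([role_set()])
#'   and `truth` ([pathway_truth()]).
#' @export
plant_pathway <- function(g, spec) {
  stopifnot(inherits(g, "interactome"), inherits(spec, "fixture_spec"))
  if (spec$n_receptors + spec$n_trs > length(g$nodes)) {
    stop("not enough nodes for the requested role sets", call. = FALSE)
  }
  lo <- spec$length_range[1]; hi <- spec$length_range[2]
  res <- with_seed(spec$seed + 1L, {
    role_nodes <- sample(g$nodes, spec$n_receptors + spec$n_trs)
    receptors <- sort_c(role_nodes[seq_len(spec$n_receptors)])
    trs <- sort_c(role_nodes[spec$n_receptors + seq_len(spec$n_trs)])
    pool <- sort_c(setdiff(g$nodes, role_nodes))
    p_tail <- character(); p_head <- character(); p_w <- numeric()
    for (i in seq_len(spec$n_planted)) {
      r <- receptors[((i - 1L) %% spec$n_receptors) + 1L]
      tt <- trs[((i - 1L) %% spec$n_trs) + 1L]
      L <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
      n_int <- L - 1L
      if (n_int > length(pool)) {
        stop("requested planted path length infeasible: intermediate pool ",
             "exhausted", call. = FALSE)
      }
      ints <- if (n_int > 0) sample(pool, n_int) else character()
      pool <- setdiff(pool, ints)
      pn <- c(r, ints, tt)
      if (anyDuplicated(pn)) {
        stop("requested planted path length infeasible for these roles",
             call. = FALSE)
      }
      p_tail <- c(p_tail, pn[-length(pn)])
      p_head <- c(p_head, pn[-1L])
      p_w <- c(p_w, stats::runif(L, spec$w_planted[1], spec$w_planted[2]))
    }
    list(receptors = receptors, trs = trs,
         planted = data.frame(tail = p_tail, head = p_head, weight = p_w,
                              stringsAsFactors = FALSE))
  })
  planted <- res$planted
  # overwrite colliding background edges, append the rest
  ed <- g$edges
  ov <- match(edge_key(planted$tail, planted$head),
              edge_key(ed$tail, ed$head))
  hitp <- !is.na(ov)
  ed$weight[ov[hitp]] <- planted$weight[hitp]
  ed <- rbind(ed, planted[!hitp, , drop = FALSE])
  gg <- interactome(ed, nodes = g$nodes, quiet = TRUE)
  list(interactome = gg,
       roles = role_set(res$receptors, res$trs, g = gg),
       truth = pathway_truth(planted[, c("tail", "head")], g = gg))
}

#' Fixed hand-checkable two-branch worked example
#'
#' A four-node interactome with one receptor R and one TR X joined by two
#' branches: a strong one R -> A -> X (weights 0.9, 0.9; score 0.81) and a
#' weak one R -> B -> X (weights 0.5, 0.5; score 0.25). The truth is the
#' strong branch. Built in code, stable across calls; used throughout the
#' documentation and tests.
#'
#' @return List with `interactome`, `roles` and `truth`.
#' @examples
#' fx <- worked_example()
#' reconstruct(fx$interactome, fx$roles, k = 2)
#' @export
worked_example <- function() {
  g <- interactome(data.frame(
    tail = c("R", "A", "R", "B"),
    head = c("A", "X", "B", "X"),
    weight = c(0.9, 0.9, 0.5, 0.5),
    stringsAsFactors = FALSE
  ), quiet = TRUE)
  list(interactome = g,
       roles = role_set("R", "X", g = g),
       truth = pathway_truth(data.frame(tail = c("R", "A"),
                                        head = c("A", "X"),
                                        stringsAsFactors = FALSE), g = g))
}
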