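# End-to-end pathway reconstruction and first-path-index ranking.

# Assemble a reconstruction object from stripped paths (list of
# list(nodes, cost, score, index)); recomputes the first-path-index maps.
build_reconstruction <- function(paths, k_requested) {
  e_tail <- character(); e_head <- character(); e_idx <- integer()
  n_node <- character(); n_idx <- integer()
  seen_e <- new.env(hash = TRUE, parent = emptyenv())
  seen_n <- new.env(hash = TRUE, parent = emptyenv())
  for (p in paths) {
    nn <- p$nodes
    for (v in nn) {
      if (is.null(get0(v, envir = seen_n, inherits = FALSE))) {
        assign(v, TRUE, envir = seen_n)
        n_node <- c(n_node, v); n_idx <- c(n_idx, p$index)
      }
    }
    for (i in seq_len(length(nn) - 1L)) {
      ky <- edge_key(nn[i], nn[i + 1L])
      if (is.null(get0(ky, envir = seen_e, inherits = FALSE))) {
        assign(ky, TRUE, envir = seen_e)
        e_tail <- c(e_tail, nn[i]); e_head <- c(e_head, nn[i + 1L])
        e_idx <- c(e_idx, p$index)
      }
    }
  }
  structure(list(
    paths = paths,
    edge_first_index = data.frame(tail = e_tail, head = e_head,
                                  index = e_idx, stringsAsFactors = FALSE),
    node_first_index = stats::setNames(n_idx, n_node),
    k_used = length(paths),
    k_requested = k_requested
  ), class = "reconstruction")
}

#' Reconstruct a signaling pathway by k highest-scoring paths
#'
#' The full pipeline: augment the interactome with the artificial source and
#' sink ([augment()]), run Yen's k-shortest loopless paths with the A*
#' heuristic ([yen_ksp()]), strip the artificial endpoints, and rank every
#' node and edge by the index of the first path in which it appears. The
#' reconstruction G_k is the union of the first k paths; by construction its
#' edge sets are nested in k and every reconstruction edge lies on a stored
#' path that starts at a receptor and ends at a TR.
#'
#' Degenerate paths with no real interaction (a node that is both receptor
#' and TR yields an s-node-t path of zero real edges) are filtered out and
#' the remaining paths re-indexed contiguously.
#'
#' @param g An [interactome()].
#' @param roles A [role_set()].
#' @param k Number of paths to compute (default 20000, suited to the high
#'   edge reuse among paths in real signaling networks; use small k for small
#'   graphs).
#' @param use_astar Use the A* acceleration (identical results either way).
#' @return Object of class `reconstruction`: `paths` (each with `nodes`,
#'   `score`, `cost`, `index`), `edge_first_index` (data frame `tail`,
#'   `head`, `index` in rank order), `node_first_index` (named integer
#'   vector), `k_used` and `k_requested`.
#' @examples
#' fx <- worked_example()
#' rec <- reconstruct(fx$interactome, fx$roles, k = 2)
#' vapply(rec$paths, `[[`, 0, "score")   # 0.81, 0.25
#' @export
reconstruct <- function(g, roles, k = 20000, use_astar = TRUE) {
  stopifnot(inherits(g, "interactome"), inherits(roles, "role_set"), k >= 1)
  cg <- augment(g, roles)
  raw <- yen_ksp(cg, k, use_astar = use_astar)
  paths <- list()
  for (p in raw) {
    nodes <- p$nodes[-c(1L, length(p$nodes))]   # strip artificial s/t
    if (length(nodes) < 2L) next                # zero real edges: degenerate
    paths[[length(paths) + 1L]] <- list(nodes = nodes, cost = p$cost,
                                        score = p$score,
                                        index = length(paths) + 1L)
  }
  if (!length(paths)) {
    stop("no receptor-to-TR path containing a real interaction exists",
         call. = FALSE)
  }
  build_reconstruction(paths, k_requested = as.integer(k))
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> ", x$k_used, " path(s) (k requested: ",
      x$k_requested, "), ", nrow(x$edge_first_index), " edge(s), ",
      length(x$node_first_index), " node(s)\n", sep = "")
  invisible(x)
}

#' Edges ranked by first path index
#'
#' Each edge of the reconstruction is ranked by the index of the first path
#' containing it; within one path index, edges are ordered by their position
#' along that path. Edges sharing an index are tied for evaluation purposes
#' (see [precision_recall()]).
#'
#' @param rec A [reconstruct()] result.
#' @return Data frame `tail`, `head`, `index`, ascending by index.
#' @export
ranked_edges <- function(rec) {
  stopifnot(inherits(rec, "reconstruction"))
  rec$edge_first_index
}

#' Nodes ranked by first path index
#'
#' @param rec A [reconstruct()] result.
#' @return Data frame `node`, `index`, ascending by index (within a path, in
#'   path order).
#' @export
ranked_nodes <- function(rec) {
  stopifnot(inherits(rec, "reconstruction"))
  data.frame(node = names(rec$node_first_index),
             index = unname(rec$node_first_index),
             stringsAsFactors = FALSE)
}

#' Shortest-paths baseline
#'
#' The classical baseline: one least-cost path (product-of-weights scoring,
#' same -log cost transform) for every (receptor, TR) pair, returned as the
#' union of their edges. Pairs with no connecting path are skipped with a
#' warning. Ties resolve by the deterministic Dijkstra rule (lexicographically
#' smaller predecessor).
#'
#' @param g An [interactome()].
#' @param roles A [role_set()].
#' @return Data frame `tail`, `head` of the edge union, sorted
#'   lexicographically.
#' @export
shortest_paths_baseline <- function(g, roles) {
  stopifnot(inherits(g, "interactome"), inherits(roles, "role_set"))
  cg <- real_cost_graph(g)
  e_tail <- character(); e_head <- character()
  for (r in roles$receptors) {
    ri <- match(r, cg$nodes)
    res <- sp_search(cg, ri)
    for (tt in roles$trs) {
      if (tt == r) next
      ti <- match(tt, cg$nodes)
      if (!is.finite(res$dist[ti])) {
        warning("no path from receptor '", r, "' to TR '", tt,
                "'; pair skipped", call. = FALSE)
        next
      }
      p <- backtrack(res$prev, ri, ti)
      e_tail <- c(e_tail, cg$nodes[p[-length(p)]])
      e_head <- c(e_head, cg$nodes[p[-1L]])
    }
  }
  keep <- !duplicated(edge_key(e_tail, e_head))
  out <- data.frame(tail = e_tail[keep], head = e_head[keep],
                    stringsAsFactors = FALSE)
  out <- out[order_c(out$tail, out$head), , drop = FALSE]
  rownames(out) <- NULL
  out
}
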