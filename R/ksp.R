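# Core algorithmics: cost graph, Dijkstra / A* single-source search, exact
# distance-to-sink heuristic, and Yen's k-shortest loopless paths.
#
# Node names are mapped to integer indices into the C-locale-sorted node
# vector, so index comparisons double as lexicographic tie-breaks. Edges are
# held as forward and reverse adjacency lists; a directed edge (u, v) is
# identified by the scalar code (u - 1) * n + v for ban sets.

ARTIFICIAL_SOURCE <- "__source__"
ARTIFICIAL_SINK <- "__sink__"

new_cost_graph <- function(nodes, tail, head, cost, weight,
                           source = NA_character_, sink = NA_character_) {
  nodes <- sort_c(nodes)
  n <- length(nodes)
  ti <- match(tail, nodes)
  hi <- match(head, nodes)
  stopifnot(!anyNA(ti), !anyNA(hi), all(cost >= 0))
  o <- order(ti, hi)
  ti <- ti[o]; hi <- hi[o]; cost <- cost[o]; weight <- weight[o]
  f <- factor(ti, levels = seq_len(n))
  fr <- factor(hi, levels = seq_len(n))
  structure(list(
    nodes = nodes, n = n,
    tail = ti, head = hi, cost = cost, weight = weight,
    adj_to = split(hi, f), adj_cost = split(cost, f),
    adj_w = split(weight, f),
    radj_from = split(ti, fr), radj_cost = split(cost, fr),
    source = if (is.na(source)) NA_integer_ else match(source, nodes),
    sink = if (is.na(sink)) NA_integer_ else match(sink, nodes)
  ), class = "cost_graph")
}

#' @export
print.cost_graph <- function(x, ...) {
  cat("<cost_graph> ", x$n, " nodes, ", length(x$tail), " edges",
      if (!is.na(x$source)) " (augmented with artificial source/sink)", "\n",
      sep = "")
  invisible(x)
}

# Build a cost graph over the real interactome only (no s/t); used by the
# shortest-paths baseline.
real_cost_graph <- function(g) {
  new_cost_graph(g$nodes, g$edges$tail, g$edges$head, -log(g$edges$weight),
                 g$edges$weight)
}

#' Augment an interactome with an artificial source and sink
#'
#' Adds an artificial source `s` with a zero-cost directed edge to every
#' receptor and an artificial sink `t` with a zero-cost directed edge from
#' every TR, and assigns every real edge the additive cost `-log(w)` (natural
#' log; any base preserves the path ordering, and e keeps
#' `score = exp(-cost)` exact). Minimizing summed cost over s-t paths is then
#' equivalent to maximizing the product-of-weights path score over
#' receptor-to-TR paths. Real edges into receptors and out of TRs are kept:
#' paths may traverse receptors/TRs as intermediates; only the endpoints are
#' constrained.
#'
#' @param g An [interactome()].
#' @param roles A [role_set()] validated against `g`.
#' @return A `cost_graph` with `source`/`sink` set.
#' @export
augment <- function(g, roles) {
  stopifnot(inherits(g, "interactome"), inherits(roles, "role_set"))
  if (any(c(ARTIFICIAL_SOURCE, ARTIFICIAL_SINK) %in% g$nodes)) {
    stop("interactome uses the reserved artificial node names", call. = FALSE)
  }
  S <- intersect(roles$receptors, g$nodes)
  T_ <- intersect(roles$trs, g$nodes)
  if (!length(S)) stop("no receptor is present in the interactome", call. = FALSE)
  if (!length(T_)) stop("no TR is present in the interactome", call. = FALSE)
  tl <- c(g$edges$tail, rep(ARTIFICIAL_SOURCE, length(S)), T_)
  hd <- c(g$edges$head, S, rep(ARTIFICIAL_SINK, length(T_)))
  cost <- c(-log(g$edges$weight), rep(0, length(S) + length(T_)))
  # artificial edges carry weight 1 so the product over all edges equals the
  # product over real edges
  w <- c(g$edges$weight, rep(1, length(S) + length(T_)))
  new_cost_graph(c(g$nodes, ARTIFICIAL_SOURCE, ARTIFICIAL_SINK),
                 tl, hd, cost, w,
                 source = ARTIFICIAL_SOURCE, sink = ARTIFICIAL_SINK)
}

# Single-source least-cost search with non-negative costs.
#   - h = NULL: plain Dijkstra; h = numeric vector: A* with priority dist + h
#     (h must be consistent; nodes with h = Inf are never enqueued).
#   - target given: stops when the target is popped (exact for both modes).
#   - banned_nodes (int vector) and banned_edges (numeric codes) restrict the
#     graph without copying it.
#   - Tie-breaks: pops take the lowest node index among equal priorities;
#     on equal tentative distance the lexicographically smaller predecessor
#     wins. Node indices follow C-locale name order.
sp_search <- function(cg, source, target = NA_integer_, h = NULL,
                      banned_nodes = integer(), banned_edges = numeric(),
                      reverse = FALSE) {
  n <- cg$n
  adj_to <- if (reverse) cg$radj_from else cg$adj_to
  adj_cost <- if (reverse) cg$radj_cost else cg$adj_cost
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  if (length(banned_nodes)) done[banned_nodes] <- TRUE
  blocked <- done
  if (blocked[source]) return(list(dist = dist, prev = prev))
  dist[source] <- 0
  use_h <- !is.null(h)
  use_ban <- length(banned_edges) > 0L
  repeat {
    key <- if (use_h) dist + h else dist
    key[done] <- Inf
    u <- which.min(key)
    if (!is.finite(key[u])) break
    done[u] <- TRUE
    if (!is.na(target) && u == target) break
    nb <- adj_to[[u]]
    nc <- adj_cost[[u]]
    if (!length(nb)) next
    if (use_ban) {
      keep <- !((u - 1) * n + nb) %in% banned_edges
      nb <- nb[keep]; nc <- nc[keep]
    }
    keep <- !done[nb] & !blocked[nb]
    nb <- nb[keep]; nc <- nc[keep]
    if (!length(nb)) next
    nd <- dist[u] + nc
    better <- nd < dist[nb]
    if (any(better)) {
      dist[nb[better]] <- nd[better]
      prev[nb[better]] <- u
    }
    tie <- !better & nd == dist[nb] & u < prev[nb]
    tie[is.na(tie)] <- FALSE
    if (any(tie)) prev[nb[tie]] <- u
  }
  list(dist = dist, prev = prev)
}

# Follow predecessor pointers from target back to source (integer indices).
backtrack <- function(prev, source, target) {
  path <- integer()
  u <- target
  repeat {
    path <- c(u, path)
    if (u == source) return(path)
    u <- prev[u]
    if (is.na(u)) return(NULL)
  }
}

# Path cost/score recomputed edge-by-edge along the node sequence, so the
# arithmetic (and hence ordering) is bit-identical to a brute-force oracle
# summing in the same order.
path_cost_idx <- function(cg, p) {
  tot <- 0
  for (i in seq_len(length(p) - 1L)) {
    pos <- match(p[i + 1L], cg$adj_to[[p[i]]])
    if (is.na(pos)) return(NA_real_)
    tot <- tot + cg$adj_cost[[p[i]]][pos]
  }
  tot
}

path_score_idx <- function(cg, p) {
  tot <- 1
  for (i in seq_len(length(p) - 1L)) {
    pos <- match(p[i + 1L], cg$adj_to[[p[i]]])
    if (is.na(pos)) return(NA_real_)
    tot <- tot * cg$adj_w[[p[i]]][pos]
  }
  tot
}

# TRUE if integer node sequence a precedes b lexicographically.
seq_less <- function(a, b) {
  L <- min(length(a), length(b))
  for (i in seq_len(L)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exact least-cost distances from a source node (Dijkstra)
#'
#' @param cg A `cost_graph` (see [augment()]).
#' @param source Node name.
#' @return List with `dist` (named numeric; `Inf` for unreachable nodes) and
#'   `prev` (named character predecessor map, `NA` where undefined). Equal
#'   -cost predecessors resolve to the lexicographically smaller upstream
#'   node.
#' @export
dijkstra <- function(cg, source) {
  stopifnot(inherits(cg, "cost_graph"))
  si <- match(source, cg$nodes)
  if (is.na(si)) stop("source node '", source, "' not in graph", call. = FALSE)
  res <- sp_search(cg, si)
  list(dist = stats::setNames(res$dist, cg$nodes),
       prev = stats::setNames(ifelse(is.na(res$prev), NA_character_,
                                     cg$nodes[res$prev]), cg$nodes))
}

#' Exact least cost from every node to the sink (A* heuristic table)
#'
#' One Dijkstra pass over the edge-reversed graph from the artificial sink
#' `t`. The result `h` is the exact remaining distance, hence a consistent
#' (and admissible) A* heuristic: `h(t) = 0` and
#' `h(u) <= c(u, v) + h(v)` for every edge. Removing edges or nodes (as Yen's
#' spur searches do) can only increase true distances, so `h` stays
#' admissible under bans.
#'
#' @param cg An augmented `cost_graph` (needs a sink; see [augment()]).
#' @return Named numeric vector node -> least cost to the sink (`Inf` if the
#'   sink is unreachable).
#' @export
reverse_distances <- function(cg) {
  stopifnot(inherits(cg, "cost_graph"))
  if (is.na(cg$sink)) stop("cost graph has no sink", call. = FALSE)
  stats::setNames(sp_search(cg, cg$sink, reverse = TRUE)$dist, cg$nodes)
}

#' A* least-cost path between two nodes under edge/node bans
#'
#' With the exact [reverse_distances()] heuristic, A* pops nodes in order of
#' `dist + h` and may stop as soon as the target is popped; nodes that cannot
#' reach the sink (`h = Inf`) are never enqueued. The returned path cost is
#' identical to Dijkstra on the banned subgraph.
#'
#' @param cg A `cost_graph`.
#' @param source,target Node names.
#' @param h Heuristic as from [reverse_distances()] (`NULL` for plain
#'   Dijkstra).
#' @param banned_edges Data frame with `tail`, `head` columns of edges to
#'   remove, or `NULL`.
#' @param banned_nodes Character vector of nodes to remove, or `NULL`.
#' @return List with `nodes` (character sequence), `cost` and `score`, or
#'   `NULL` if target is unreachable.
#' @export
astar_shortest_path <- function(cg, source, target, h = NULL,
                                banned_edges = NULL, banned_nodes = NULL) {
  stopifnot(inherits(cg, "cost_graph"))
  si <- match(source, cg$nodes)
  ti <- match(target, cg$nodes)
  if (is.na(si) || is.na(ti)) stop("source or target not in graph", call. = FALSE)
  hv <- NULL
  if (!is.null(h)) {
    hv <- if (!is.null(names(h))) unname(h[cg$nodes]) else h
    stopifnot(length(hv) == cg$n)
  }
  bn <- integer()
  if (!is.null(banned_nodes) && length(banned_nodes)) {
    bn <- match(banned_nodes, cg$nodes)
    bn <- bn[!is.na(bn)]
  }
  be <- numeric()
  if (!is.null(banned_edges) && nrow(banned_edges %||% data.frame())) {
    bt <- match(as.character(banned_edges$tail), cg$nodes)
    bh <- match(as.character(banned_edges$head), cg$nodes)
    ok <- !is.na(bt) & !is.na(bh)
    be <- (bt[ok] - 1) * cg$n + bh[ok]
  }
  res <- sp_search(cg, si, target = ti, h = hv,
                   banned_nodes = bn, banned_edges = be)
  if (!is.finite(res$dist[ti])) return(NULL)
  p <- backtrack(res$prev, si, ti)
  list(nodes = cg$nodes[p], cost = path_cost_idx(cg, p),
       score = path_score_idx(cg, p))
}

#' Yen's k-shortest loopless paths with A* acceleration
#'
#' Computes the k least-cost simple (loopless) paths from the artificial
#' source to the artificial sink, in nondecreasing cost order — equivalently
#' the k highest-scoring receptor-to-TR paths, since score = exp(-cost).
#' Standard Yen's: for each prefix (root) of the previously accepted path,
#' ban the next-edges of all accepted paths sharing that root plus all root
#' nodes except the spur node, then search spur-to-sink; candidates are kept
#' in a pool keyed by the full node sequence (so no path is emitted twice)
#' and the minimum by (cost, lexicographic node sequence) is accepted next.
#' The A* heuristic ([reverse_distances()], computed once) is a pure
#' acceleration: results are identical with `use_astar = FALSE`.
#'
#' @param cg An augmented `cost_graph` (see [augment()]).
#' @param k Maximum number of paths (>= 1); if fewer simple paths exist, all
#'   are returned.
#' @param use_astar Use the A* heuristic for spur searches.
#' @return List of paths, each a list with `nodes` (character sequence
#'   including the artificial endpoints), `cost`, `score` and `index`
#'   (1-based emission order).
#' @export
yen_ksp <- function(cg, k, use_astar = TRUE) {
  stopifnot(inherits(cg, "cost_graph"), k >= 1)
  if (is.na(cg$source) || is.na(cg$sink)) {
    stop("cost graph lacks an artificial source/sink; call augment() first",
         call. = FALSE)
  }
  k <- as.integer(k)
  s <- cg$source; t <- cg$sink
  h <- if (use_astar) sp_search(cg, t, reverse = TRUE)$dist else NULL

  res <- sp_search(cg, s, target = t, h = h)
  if (!is.finite(res$dist[t])) {
    stop("no path connects any receptor to any TR in the interactome",
         call. = FALSE)
  }
  A <- list(backtrack(res$prev, s, t))
  emitted <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(A[[1]], collapse = ","), TRUE, envir = emitted)
  cand <- list()        # candidate paths: list(nodes = int vector, cost)
  cand_keys <- character()

  while (length(A) < k) {
    prev_path <- A[[length(A)]]
    for (j in seq_len(length(prev_path) - 1L)) {
      spur <- prev_path[j]
      root <- prev_path[seq_len(j)]
      be <- numeric()
      for (p in A) {
        if (length(p) > j && identical(p[seq_len(j)], root)) {
          be <- c(be, (p[j] - 1) * cg$n + p[j + 1L])
        }
      }
      bn <- if (j > 1L) root[seq_len(j - 1L)] else integer()
      r2 <- sp_search(cg, spur, target = t, h = h,
                      banned_nodes = bn, banned_edges = unique(be))
      if (!is.finite(r2$dist[t])) next
      spur_path <- backtrack(r2$prev, spur, t)
      total <- c(root[seq_len(j - 1L)], spur_path)
      key <- paste(total, collapse = ",")
      if (key %in% cand_keys ||
          !is.null(get0(key, envir = emitted, inherits = FALSE))) next
      cand[[length(cand) + 1L]] <- list(nodes = total,
                                        cost = path_cost_idx(cg, total))
      cand_keys <- c(cand_keys, key)
    }
    if (!length(cand)) break
    costs <- vapply(cand, `[[`, 0, "cost")
    best <- which(costs == min(costs))
    bi <- best[1L]
    for (b in best[-1L]) {
      if (seq_less(cand[[b]]$nodes, cand[[bi]]$nodes)) bi <- b
    }
    A[[length(A) + 1L]] <- cand[[bi]]$nodes
    assign(cand_keys[bi], TRUE, envir = emitted)
    cand <- cand[-bi]
    cand_keys <- cand_keys[-bi]
  }

  lapply(seq_along(A), function(i) {
    p <- A[[i]]
    list(nodes = cg$nodes[p], cost = path_cost_idx(cg, p),
         score = path_score_idx(cg, p), index = i)
  })
}
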