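# Evaluation machinery: negative subsampling, ranked precision-recall with
# block ties, pathway-adjacent-negative exclusion, distance-from-pathway,
# receptor/TR recovery ranks, role perturbation, micro-aggregation.

#' Subsample negative edges for evaluation
#'
#' Negatives are interactome edges not in the curated pathway. A seeded
#' uniform sample without replacement of size
#' `min(round(neg_ratio * n_positives), pool size)` is drawn from the
#' candidate pool (sorted before sampling, so the draw depends only on the
#' seed and the sets, not on input order). With `exclude_adjacent = TRUE`,
#' pathway-adjacent candidates (distance 1 from the pathway, i.e., touching a
#' pathway protein) are removed *before* subsampling.
#'
#' @param universe Edge data frame (`tail`, `head`) or key vector: the
#'   eligible edges, typically the whole interactome.
#' @param positives Edge data frame or key vector; must be a subset of
#'   `universe`.
#' @param neg_ratio Negatives per positive (> 0); default 50.
#' @param seed Integer RNG seed.
#' @param exclude_adjacent Drop pathway-adjacent candidates first (requires
#'   `truth` and `g`).
#' @param truth,g [pathway_truth()] and [interactome()], needed only when
#'   `exclude_adjacent = TRUE`.
#' @return Data frame `tail`, `head` of sampled negatives, sorted.
#' @export
subsample_negatives <- function(universe, positives, neg_ratio = 50, seed = 1,
                                exclude_adjacent = FALSE, truth = NULL,
                                g = NULL) {
  stopifnot(neg_ratio > 0)
  ukeys <- unique(as_item_keys(universe))
  pkeys <- unique(as_item_keys(positives))
  if (!all(pkeys %in% ukeys)) {
    stop("positives must be a subset of the universe", call. = FALSE)
  }
  pool <- sort_c(setdiff(ukeys, pkeys))
  if (exclude_adjacent) {
    if (is.null(truth) || is.null(g)) {
      stop("exclude_adjacent = TRUE requires `truth` and `g`", call. = FALSE)
    }
    cand <- key_to_edges(pool)
    d <- edge_distance_from_pathway(cand, truth, g)
    pool <- pool[d != 1]
  }
  if (!length(pool)) stop("empty negative candidate pool", call. = FALSE)
  n_neg <- min(round(neg_ratio * length(pkeys)), length(pool))
  sampled <- with_seed(seed, sample(pool, n_neg))
  out <- key_to_edges(sort_c(sampled))
  rownames(out) <- NULL
  out
}

key_to_edges <- function(keys) {
  parts <- strsplit(keys, " -> ", fixed = TRUE)
  data.frame(tail = vapply(parts, `[[`, "", 1),
             head = vapply(parts, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Precision-recall curve over a ranked item list with block ties
#'
#' Items sharing a rank index enter the confusion counts together (block
#' evaluation): within-path edge order is an artifact of traversal, so all
#' edges of one path index are treated as tied. Ranked items that are neither
#' positives nor negatives are ignored. At each distinct index threshold,
#' `precision = TP/(TP+FP)` and `recall = TP/|positives|`.
#'
#' @param ranked Data frame with an `index` column plus item columns
#'   (`tail`/`head` for edges, `node` for proteins, or `item`).
#' @param positives,negatives Item sets (edge data frames, node/key character
#'   vectors); must be disjoint, positives non-empty.
#' @return Object of class `pr_curve`: `points` (data frame `threshold`,
#'   `tp`, `fp`, `precision`, `recall`) and `positives_total`.
#' @examples
#' r <- data.frame(item = c("a", "b", "c"), index = 1:3)
#' precision_recall(r, positives = c("a", "c"), negatives = "b")$points
#' @export
precision_recall <- function(ranked, positives, negatives) {
  stopifnot(is.data.frame(ranked), "index" %in% names(ranked))
  items <- as_item_keys(ranked)
  index <- as.integer(ranked$index)
  pkeys <- unique(as_item_keys(positives))
  nkeys <- unique(as_item_keys(negatives))
  if (!length(pkeys)) stop("no positives to evaluate against", call. = FALSE)
  if (length(intersect(pkeys, nkeys))) {
    stop("positives and negatives overlap", call. = FALSE)
  }
  keep <- items %in% c(pkeys, nkeys)
  items <- items[keep]
  index <- index[keep]
  if (!length(items)) {
    return(structure(list(points = data.frame(threshold = integer(),
                                              tp = integer(), fp = integer(),
                                              precision = numeric(),
                                              recall = numeric()),
                          positives_total = length(pkeys)),
                     class = "pr_curve"))
  }
  o <- order(index)
  items <- items[o]; index <- index[o]
  is_pos <- items %in% pkeys
  tp_cum <- cumsum(is_pos)
  fp_cum <- cumsum(!is_pos)
  last <- !duplicated(index, fromLast = TRUE)   # end of each tie block
  tp <- tp_cum[last]; fp <- fp_cum[last]
  structure(list(points = data.frame(threshold = index[last], tp = tp,
                                     fp = fp,
                                     precision = tp / (tp + fp),
                                     recall = tp / length(pkeys)),
                 positives_total = length(pkeys)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$points), " threshold(s), ", x$positives_total,
      " positive(s); final recall ",
      if (nrow(x$points)) round(x$points$recall[nrow(x$points)], 4) else NA,
      "\n", sep = "")
  invisible(x)
}

#' Precision of a PR curve at (or before) a rank threshold
#'
#' Convenience accessor: the precision of the last curve point whose
#' threshold is <= `threshold` (`NA` if the curve has no such point).
#'
#' @param curve A [precision_recall()] result.
#' @param threshold Rank index.
#' @return Numeric precision.
#' @export
precision_at <- function(curve, threshold) {
  stopifnot(inherits(curve, "pr_curve"))
  i <- which(curve$points$threshold <= threshold)
  if (!length(i)) return(NA_real_)
  curve$points$precision[max(i)]
}

# Multi-source BFS hop distances on the undirected skeleton of g from the
# given start nodes. Returns named vector over g$nodes (Inf if unreachable).
undirected_node_distances <- function(g, from) {
  nodes <- g$nodes
  n <- length(nodes)
  ti <- match(g$edges$tail, nodes)
  hi <- match(g$edges$head, nodes)
  f <- factor(c(ti, hi), levels = seq_len(n))
  adj <- split(c(hi, ti), f)
  d <- rep(Inf, n)
  frontier <- match(intersect(from, nodes), nodes)
  d[frontier] <- 0
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    if (!length(nxt)) break
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  stats::setNames(d, nodes)
}

#' Distance of interactome edges from a curated pathway
#'
#' A distance of 0 marks a true positive (the edge is in the pathway); a
#' distance of 1 marks a pathway-adjacent edge (at least one endpoint is a
#' pathway protein); larger values are 1 + the minimum undirected hop
#' distance from either endpoint to the nearest pathway protein. Adjacency is
#' about participation of pathway proteins, not signal direction, hence the
#' undirected skeleton. Unreachable edges get `Inf`.
#'
#' @param edges Edge data frame (`tail`, `head`).
#' @param truth A [pathway_truth()].
#' @param g The [interactome()].
#' @return Numeric vector of distances, one per row of `edges`.
#' @export
edge_distance_from_pathway <- function(edges, truth, g) {
  stopifnot(inherits(truth, "pathway_truth"), inherits(g, "interactome"))
  keys <- edge_key(as.character(edges$tail), as.character(edges$head))
  tkeys <- edge_key(truth$edges$tail, truth$edges$head)
  nd <- undirected_node_distances(g, truth$nodes)
  dt <- nd[as.character(edges$tail)]
  dh <- nd[as.character(edges$head)]
  dt[is.na(dt)] <- Inf
  dh[is.na(dh)] <- Inf
  out <- 1 + pmin(dt, dh)
  out[keys %in% tkeys] <- 0
  unname(out)
}

#' Remove pathway-adjacent negatives
#'
#' Drops every negative at distance exactly 1 from the pathway (touching a
#' pathway protein; see [edge_distance_from_pathway()]). Applied before
#' subsampling in [subsample_negatives()] when requested; removing these
#' likely-undercurated interactions from the negative pool can only remove
#' false positives from the precision denominator.
#'
#' @param negatives Edge data frame (`tail`, `head`).
#' @param truth A [pathway_truth()].
#' @param g The [interactome()].
#' @return The filtered edge data frame.
#' @export
exclude_adjacent_negatives <- function(negatives, truth, g) {
  d <- edge_distance_from_pathway(negatives, truth, g)
  out <- negatives[d != 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recovery rank of target nodes in a ranked edge list
#'
#' For each target node (typically the curated receptors or TRs), the index
#' of the first ranked interaction incident to it, as head or tail; `NA` if
#' no ranked edge ever touches it.
#'
#' @param ranked Data frame `tail`, `head`, `index` (e.g. [ranked_edges()]).
#' @param targets Character vector of node identifiers.
#' @return Data frame `node`, `rank` (integer, `NA` = unranked).
#' @export
recovery_ranks <- function(ranked, targets) {
  stopifnot(all(c("tail", "head", "index") %in% names(ranked)))
  rk <- vapply(as.character(targets), function(v) {
    hit <- ranked$index[ranked$tail == v | ranked$head == v]
    if (length(hit)) min(hit) else NA_integer_
  }, 0L)
  data.frame(node = as.character(targets), rank = as.integer(rk),
             stringsAsFactors = FALSE)
}

#' Randomly perturb a role set (robustness protocol)
#'
#' Emulates noisy input annotations: `mode = "remove"` deletes
#' `round(fraction * |set|)` members uniformly at random, independently for
#' the receptor and TR sets; `mode = "add"` inserts that many nodes sampled
#' from `candidate_pool` (which must be disjoint from the perturbed sets).
#' Seeded and reproducible.
#'
#' @param roles A [role_set()].
#' @param fraction Fraction in \[0, 1\] (e.g. 0.3 for the 30% protocol).
#' @param mode `"remove"` or `"add"`.
#' @param candidate_pool Character vector of candidate nodes (required for
#'   `"add"`).
#' @param seed Integer RNG seed.
#' @return A perturbed [role_set()].
#' @export
perturb_roles <- function(roles, fraction, mode = c("remove", "add"),
                          candidate_pool = NULL, seed = 1) {
  stopifnot(inherits(roles, "role_set"), fraction >= 0, fraction <= 1)
  mode <- match.arg(mode)
  S <- roles$receptors
  T_ <- roles$trs
  if (mode == "remove") {
    nS <- round(fraction * length(S))
    nT <- round(fraction * length(T_))
    if (nS >= length(S) || nT >= length(T_)) {
      stop("removal would empty the receptor or TR set", call. = FALSE)
    }
    with_seed(seed, {
      if (nS > 0) S <- setdiff(S, sample(S, nS))
      if (nT > 0) T_ <- setdiff(T_, sample(T_, nT))
    })
  } else {
    stopifnot(!is.null(candidate_pool))
    pool <- sort_c(setdiff(as.character(candidate_pool), c(S, T_)))
    nS <- round(fraction * length(S))
    nT <- round(fraction * length(T_))
    if (nS + nT > length(pool)) {
      stop("candidate pool too small for requested additions", call. = FALSE)
    }
    with_seed(seed, {
      addS <- if (nS > 0) sample(pool, nS) else character()
      pool2 <- setdiff(pool, addS)
      addT <- if (nT > 0) sample(pool2, nT) else character()
      S <- c(S, addS)
      T_ <- c(T_, addT)
    })
  }
  role_set(S, T_)
}

#' Micro-aggregated precision-recall over several pathways
#'
#' Pools the (item, index) pairs of all pathways' ranked lists — items are
#' tagged by pathway, so the same interactome edge in two pathways counts as
#' two distinct items — sorts by index (ties enter as blocks), and computes a
#' single curve over the pooled positives and negatives.
#'
#' @param per_pathway List; each element a list with `ranked` (data frame
#'   with `index`), `positives` and `negatives` (item sets). Optional element
#'   names tag the pathways.
#' @return A `pr_curve` over the pooled items.
#' @export
aggregate_pr <- function(per_pathway) {
  stopifnot(is.list(per_pathway), length(per_pathway) >= 1)
  tags <- names(per_pathway) %||% rep("", length(per_pathway))
  tags[!nzchar(tags)] <- paste0("pathway", which(!nzchar(tags)))
  items <- character(); index <- integer()
  pos <- character(); neg <- character()
  for (i in seq_along(per_pathway)) {
    pw <- per_pathway[[i]]
    tag <- function(x) paste0(tags[i], "::", x)
    items <- c(items, tag(as_item_keys(pw$ranked)))
    index <- c(index, as.integer(pw$ranked$index))
    pos <- c(pos, tag(as_item_keys(pw$positives)))
    neg <- c(neg, tag(as_item_keys(pw$negatives)))
  }
  precision_recall(data.frame(item = items, index = index,
                              stringsAsFactors = FALSE), pos, neg)
}

#' End-to-end evaluation of a reconstruction against a curated pathway
#'
#' Convenience wrapper tying the pieces together: subsample negatives
#' (optionally excluding pathway-adjacent candidates first), pick the edge-
#' or protein-level ranked list, and compute the precision-recall curve. At
#' the node level, positives are the pathway proteins and negatives are the
#' endpoint nodes of the sampled negative edges that are not pathway
#' proteins.
#'
#' @param rec A [reconstruct()] result.
#' @param truth A [pathway_truth()].
#' @param g The [interactome()].
#' @param neg_ratio,seed,exclude_adjacent Passed to [subsample_negatives()].
#' @param level `"edge"` or `"node"`.
#' @return A `pr_curve`.
#' @export
evaluate_reconstruction <- function(rec, truth, g, neg_ratio = 50, seed = 1,
                                    exclude_adjacent = FALSE,
                                    level = c("edge", "node")) {
  level <- match.arg(level)
  stopifnot(inherits(rec, "reconstruction"))
  negs <- subsample_negatives(g$edges, truth$edges, neg_ratio = neg_ratio,
                              seed = seed,
                              exclude_adjacent = exclude_adjacent,
                              truth = truth, g = g)
  if (level == "edge") {
    precision_recall(ranked_edges(rec), truth$edges, negs)
  } else {
    neg_nodes <- sort_c(setdiff(unique(c(negs$tail, negs$head)), truth$nodes))
    precision_recall(ranked_nodes(rec), truth$nodes, neg_nodes)
  }
}
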