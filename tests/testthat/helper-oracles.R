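# Independent oracles and small random fixtures used across tests.
# The oracles only read the cost_graph's raw edge table (tail/head/cost
# vectors); they never call the search code they are checking.

# Edge-cost lookup table from the raw edge vectors of a cost_graph.
oracle_cost_map <- function(cg) {
  stats::setNames(cg$cost, paste(cg$tail, cg$head))
}

oracle_path_cost <- function(cost_map, p) {
  sum(cost_map[paste(p[-length(p)], p[-1])])
}

# All simple source->sink paths (integer index sequences) by DFS, sorted by
# (cost, lexicographic node sequence). Exponential; only for tiny graphs.
brute_force_paths <- function(cg) {
  s <- cg$source
  t <- cg$sink
  cost_map <- oracle_cost_map(cg)
  out <- list()
  dfs <- function(path, u) {
    if (u == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (v in cg$adj_to[[u]]) {
      if (!(v %in% path)) dfs(c(path, v), v)
    }
  }
  dfs(s, s)
  if (!length(out)) return(out)
  costs <- vapply(out, function(p) oracle_path_cost(cost_map, p), 0)
  # pad indices so string order == elementwise numeric order; "," < "0"
  seqs <- vapply(out, function(p) paste(sprintf("%06d", p), collapse = ","), "")
  out[order(costs, seqs)]
}

# Random directed weighted interactome plus random role sets (no planting).
# Roles are disjoint; the graph may or may not connect them.
random_graph_fixture <- function(n, p, seed, n_receptors = 1, n_trs = 1,
                                 wlo = 0.05, whi = 0.95) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  ti <- rep(seq_len(n), each = n)
  hi <- rep(seq_len(n), times = n)
  keep <- ti != hi
  ti <- ti[keep]; hi <- hi[keep]
  pick <- stats::runif(length(ti)) < p
  ti <- ti[pick]; hi <- hi[pick]
  w <- stats::runif(sum(pick), wlo, whi)
  g <- interactome(data.frame(tail = nodes[ti], head = nodes[hi], weight = w,
                              stringsAsFactors = FALSE),
                   nodes = nodes, quiet = TRUE)
  role_nodes <- sample(nodes, n_receptors + n_trs)
  list(g = g,
       roles = role_set(role_nodes[seq_len(n_receptors)],
                        role_nodes[n_receptors + seq_len(n_trs)]))
}

# Whether an augmented cost graph has any source->sink path at all, by
# reachability (BFS) on the raw edge list.
oracle_has_st_path <- function(cg) {
  reach <- cg$source
  frontier <- cg$source
  while (length(frontier)) {
    nxt <- unique(cg$head[cg$tail %in% frontier])
    nxt <- setdiff(nxt, reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  cg$sink %in% reach
}

# Dense linear-system solution of the RWR stationary distribution:
# (I - (1-q) (M + r d^T)) p = q r, with M column-stochastic over non-dangling
# columns and d the dangling indicator. Base-R solve(); independent of the
# power iteration under test.
oracle_rwr_solve <- function(g, roles, teleport) {
  nodes <- g$nodes
  n <- length(nodes)
  W <- matrix(0, n, n)
  W[cbind(match(g$edges$tail, nodes), match(g$edges$head, nodes))] <-
    g$edges$weight
  outw <- rowSums(W)
  M <- matrix(0, n, n)
  nz <- outw > 0
  M[, nz] <- t(W[nz, , drop = FALSE] / outw[nz])
  r <- numeric(n)
  S <- intersect(roles$receptors, nodes)
  r[match(S, nodes)] <- 1 / length(S)
  d <- as.numeric(!nz)
  A <- diag(n) - (1 - teleport) * (M + r %o% d)
  stats::setNames(solve(A, teleport * r), nodes)
}
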