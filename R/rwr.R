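# Random-walk-with-restarts baseline (network propagation).

#' Random walk with restarts, ranked by edge flux
#'
#' Baseline ranking by network propagation: a walker restarts uniformly on
#' the receptor set with probability `teleport` at each step, and otherwise
#' moves along out-edges with probability proportional to edge weight
#' (dangling nodes always teleport). The stationary node probabilities `p`
#' are found by power iteration to an L1 change below `tol`. Edges are then
#' ranked in descending order of the flux through them,
#' `f(u, v) = p(u) * w(u, v) / sum_x w(u, x)`, with lexicographic
#' tie-breaks, giving a ranked edge list comparable to [ranked_edges()].
#'
#' @param g An [interactome()].
#' @param roles A [role_set()] (only the receptors form the restart set).
#' @param teleport Restart probability in (0, 1]; default 0.5.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Data frame `tail`, `head`, `flux`, `index` (1-based rank), in rank
#'   order, with the stationary probabilities as attribute `"p"` (named
#'   numeric).
#' @export
rwr_baseline <- function(g, roles, teleport = 0.5, tol = 1e-10,
                         max_iter = 10000) {
  stopifnot(inherits(g, "interactome"), inherits(roles, "role_set"),
            teleport > 0, teleport <= 1, tol > 0)
  nodes <- g$nodes
  n <- length(nodes)
  if (!n || !nrow(g$edges)) stop("empty interactome", call. = FALSE)
  ti <- match(g$edges$tail, nodes)
  hi <- match(g$edges$head, nodes)
  w <- g$edges$weight
  outw <- numeric(n)
  agg <- rowsum(w, ti)
  outw[as.integer(rownames(agg))] <- agg[, 1]
  # column-stochastic transition matrix restricted to non-dangling columns
  P <- Matrix::sparseMatrix(i = hi, j = ti, x = w / outw[ti], dims = c(n, n))
  dangling <- outw == 0
  S <- intersect(roles$receptors, nodes)
  if (!length(S)) stop("no receptor in the interactome", call. = FALSE)
  r <- numeric(n)
  r[match(S, nodes)] <- 1 / length(S)
  q <- teleport
  p <- r
  converged <- FALSE
  res <- NA_real_
  for (it in seq_len(max_iter)) {
    pn <- as.numeric((1 - q) * (P %*% p)) +
      (q + (1 - q) * sum(p[dangling])) * r
    res <- sum(abs(pn - p))
    p <- pn
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("RWR did not converge within %d iterations (L1 residual %.3e)",
                 max_iter, res), call. = FALSE)
  }
  flux <- p[ti] * w / outw[ti]
  o <- order_c(-flux, g$edges$tail, g$edges$head)
  out <- data.frame(tail = g$edges$tail[o], head = g$edges$head[o],
                    flux = flux[o], index = seq_along(o),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p") <- stats::setNames(p, nodes)
  out
}
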