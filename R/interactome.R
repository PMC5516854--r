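# Domain containers: interactome, role set, pathway truth.

#' Construct a weighted directed interactome
#'
#' The interactome is the background network of physical and regulatory
#' protein interactions: a directed graph whose edge weights are
#' probability-like reals in (0, 1]. Ingest enforces the container's
#' invariants: self-loops are dropped (with a message), parallel duplicate
#' (tail, head) rows are collapsed keeping the maximum weight, and weights
#' outside (0, 1] are rejected unless `clamp_epsilon` is supplied, in which
#' case weights <= 0 are replaced by that epsilon so that -log(w) stays
#' finite (weights > 1 are always an error).
#'
#' @param edges Data frame with character-coercible columns `tail`, `head`
#'   and numeric `weight`.
#' @param nodes Optional character vector of node identifiers; the node set is
#'   the union of these and all edge endpoints, allowing isolated nodes.
#' @param clamp_epsilon `NULL` (default: reject non-positive weights) or a
#'   small positive number substituted for weights <= 0.
#' @param quiet Suppress ingest messages.
#' @return An object of class `interactome`: a list with `edges` (data frame
#'   sorted lexicographically by tail then head) and `nodes` (sorted character
#'   vector).
#' @examples
#' g <- interactome(data.frame(tail = c("A", "B"), head = c("B", "C"),
#'                             weight = c(0.5, 0.8)))
#' g$nodes
#' @export
interactome <- function(edges, nodes = NULL, clamp_epsilon = NULL,
                        quiet = FALSE) {
  stopifnot(is.data.frame(edges))
  miss <- setdiff(c("tail", "head", "weight"), names(edges))
  if (length(miss)) {
    stop("edge table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tl <- as.character(edges$tail)
  hd <- as.character(edges$head)
  w <- as.numeric(edges$weight)

  self <- tl == hd
  if (any(self)) {
    if (!quiet) message("dropped ", sum(self), " self-loop edge(s)")
    tl <- tl[!self]; hd <- hd[!self]; w <- w[!self]
  }

  if (!is.null(clamp_epsilon)) {
    stopifnot(is.numeric(clamp_epsilon), clamp_epsilon > 0)
    nz <- !is.na(w) & w <= 0
    if (any(nz)) {
      if (!quiet) message("clamped ", sum(nz), " non-positive weight(s) to ",
                          clamp_epsilon)
      w[nz] <- clamp_epsilon
    }
  }
  bad <- !is.finite(w) | w <= 0 | w > 1
  if (any(bad)) {
    stop("invalid edge weight(s) outside (0, 1]: ",
         paste(utils::head(w[bad], 5), collapse = ", "), call. = FALSE)
  }

  key <- paste(tl, hd, sep = "\t")
  if (anyDuplicated(key)) {
    o <- order_c(key, -w)
    keepr <- !duplicated(key[o])
    ndup <- sum(!keepr)
    tl <- tl[o][keepr]; hd <- hd[o][keepr]; w <- w[o][keepr]
    if (!quiet) message("collapsed ", ndup,
                        " duplicate edge(s), keeping maximum weight")
  }

  o <- order_c(tl, hd)
  ed <- data.frame(tail = tl[o], head = hd[o], weight = w[o],
                   stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  structure(
    list(edges = ed,
         nodes = sort_c(unique(c(ed$tail, ed$head, as.character(nodes))))),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed weighted edges\n", sep = "")
  invisible(x)
}

# TRUE for each row of `edges` present in interactome g.
edge_in_graph <- function(edges, g) {
  edge_key(as.character(edges$tail), as.character(edges$head)) %in%
    edge_key(g$edges$tail, g$edges$head)
}

#' Construct a receptor / transcriptional-regulator role set
#'
#' Holds the receptor set S (where signaling originates) and the TR set T
#' (downstream transcriptional regulators) for one pathway. When an
#' interactome is supplied, members absent from its node set are dropped with
#' a warning; an empty surviving set is an error since no receptor-to-TR path
#' could exist.
#'
#' @param receptors,trs Character vectors of node identifiers.
#' @param g Optional [interactome()] to validate membership against.
#' @return Object of class `role_set` with sorted, de-duplicated `receptors`
#'   and `trs`.
#' @export
role_set <- function(receptors, trs, g = NULL) {
  receptors <- sort_c(unique(as.character(receptors)))
  trs <- sort_c(unique(as.character(trs)))
  if (!is.null(g)) {
    drop_r <- setdiff(receptors, g$nodes)
    drop_t <- setdiff(trs, g$nodes)
    for (id in drop_r) warning("receptor '", id, "' not in interactome; dropped",
                               call. = FALSE)
    for (id in drop_t) warning("TR '", id, "' not in interactome; dropped",
                               call. = FALSE)
    receptors <- setdiff(receptors, drop_r)
    trs <- setdiff(trs, drop_t)
  }
  if (!length(receptors)) stop("receptor set is empty", call. = FALSE)
  if (!length(trs)) stop("TR set is empty", call. = FALSE)
  structure(list(receptors = receptors, trs = trs), class = "role_set")
}

#' @export
print.role_set <- function(x, ...) {
  cat("<role_set> ", length(x$receptors), " receptor(s), ", length(x$trs),
      " TR(s)\n", sep = "")
  invisible(x)
}

#' Construct a curated-pathway ground truth
#'
#' The positives for evaluation: the set of directed interactions of a curated
#' pathway, plus the pathway proteins (union of the edge endpoints). When an
#' interactome is supplied, positive edges are restricted to edges present in
#' it, since only those are recoverable.
#'
#' @param edges Data frame with columns `tail`, `head` (extra columns are
#'   ignored). Duplicate rows are collapsed (set semantics).
#' @param g Optional [interactome()]; edges absent from it are dropped with a
#'   message.
#' @return Object of class `pathway_truth` with `edges` (data frame) and
#'   `nodes` (sorted character vector of endpoints).
#' @export
pathway_truth <- function(edges, g = NULL) {
  stopifnot(is.data.frame(edges), all(c("tail", "head") %in% names(edges)))
  ed <- data.frame(tail = as.character(edges$tail),
                   head = as.character(edges$head),
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(edge_key(ed$tail, ed$head)), , drop = FALSE]
  if (!is.null(g)) {
    keep <- edge_in_graph(ed, g)
    if (any(!keep)) {
      message("dropped ", sum(!keep),
              " pathway edge(s) absent from the interactome")
    }
    ed <- ed[keep, , drop = FALSE]
  }
  ed <- ed[order_c(ed$tail, ed$head), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = ed, nodes = sort_c(unique(c(ed$tail, ed$head)))),
            class = "pathway_truth")
}

#' @export
print.pathway_truth <- function(x, ...) {
  cat("<pathway_truth> ", nrow(x$edges), " positive edge(s), ",
      length(x$nodes), " pathway protein(s)\n", sep = "")
  invisible(x)
}
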