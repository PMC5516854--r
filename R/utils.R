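# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness (subsampling, perturbation, fixtures) goes
# through this so results are a pure function of the supplied seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

# C-locale (byte-wise) sort/order, so tie-breaks and output files do not
# depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

#' Canonical string key for a directed edge
#'
#' Evaluation routines treat edges as opaque items; this is the key used
#' throughout (`"tail -> head"`).
#'
#' @param tail,head Character vectors of node identifiers (recycled).
#' @return Character vector of edge keys.
#' @export
edge_key <- function(tail, head) paste(tail, head, sep = " -> ")

# Coerce an edge table / node vector / key vector to item keys for PR code.
as_item_keys <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (all(c("tail", "head") %in% names(x))) {
      return(edge_key(as.character(x$tail), as.character(x$head)))
    }
    if ("node" %in% names(x)) return(as.character(x$node))
    if ("item" %in% names(x)) return(as.character(x$item))
  }
  stop("cannot interpret object as evaluation items ",
       "(expected character vector or data frame with tail/head, node or item)",
       call. = FALSE)
}

# Format doubles so that as.numeric() round-trips exactly.
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
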