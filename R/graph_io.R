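# File formats: tab-separated edge lists, role files, reconstruction outputs.
# All writers emit a '#'-prefixed header naming the columns; all readers skip
# '#' comment lines and blank lines.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a weighted directed interactome from a TSV edge list
#'
#' Expected format: tab-separated columns `tail`, `head`, `weight` with an
#' optional fourth direction-flag column where `"U"` marks an undirected
#' (physical) interaction; `'#'`-prefixed lines are comments. Undirected
#' edges are either expanded to both directions at the same weight
#' (`undirected_policy = "expand"`, the standard reduction) or rejected.
#' Ingest rules are those of [interactome()]: self-loops dropped, parallel
#' duplicates collapsed to the maximum weight, weights validated in (0, 1].
#'
#' @param path File path.
#' @param undirected_policy `"expand"` or `"reject"`.
#' @param clamp_epsilon See [interactome()].
#' @param quiet Suppress ingest messages.
#' @return An [interactome()].
#' @export
read_interactome <- function(path, undirected_policy = c("expand", "reject"),
                             clamp_epsilon = NULL, quiet = FALSE) {
  undirected_policy <- match.arg(undirected_policy)
  tsv <- read_tsv_lines(path)
  if (!length(tsv$lines)) stop("no edges in '", path, "'", call. = FALSE)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    stop("parse error at line ", tsv$lineno[i],
         ": expected at least 3 tab-separated fields, found ", nf[i],
         call. = FALSE)
  }
  tl <- vapply(parts, `[[`, "", 1)
  hd <- vapply(parts, `[[`, "", 2)
  wtxt <- vapply(parts, `[[`, "", 3)
  w <- suppressWarnings(as.numeric(wtxt))
  if (anyNA(w)) {
    i <- which(is.na(w))[1]
    stop("parse error at line ", tsv$lineno[i], ": non-numeric weight '",
         wtxt[i], "'", call. = FALSE)
  }
  flag <- vapply(parts, function(p) if (length(p) >= 4) trimws(p[[4]]) else "",
                 "")
  und <- toupper(flag) == "U"
  if (any(und)) {
    if (undirected_policy == "reject") {
      stop("undirected edge flagged at line ", tsv$lineno[which(und)[1]],
           " (undirected_policy = \"reject\")", call. = FALSE)
    }
    tl2 <- c(tl, hd[und]); hd2 <- c(hd, tl[und]); w <- c(w, w[und])
    tl <- tl2; hd <- hd2
  }
  interactome(data.frame(tail = tl, head = hd, weight = w,
                         stringsAsFactors = FALSE),
              clamp_epsilon = clamp_epsilon, quiet = quiet)
}

#' Write an interactome as a TSV edge list
#'
#' Inverse of [read_interactome()]: weights are printed with full precision so
#' a write/read round trip reproduces the edge set and weights exactly.
#'
#' @param g An [interactome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  writeLines(c("#tail\thead\tweight",
               paste(g$edges$tail, g$edges$head, fmt_num(g$edges$weight),
                     sep = "\t")),
             path)
  invisible(path)
}

read_node_list <- function(path) {
  tsv <- read_tsv_lines(path)
  vapply(strsplit(tsv$lines, "\t", fixed = TRUE), `[[`, "", 1)
}

#' Read receptor and TR role files
#'
#' Each file lists one node identifier per line (`'#'` comments allowed).
#' Members absent from the interactome are dropped with a warning; an empty
#' surviving set is an error.
#'
#' @param receptor_path,tr_path File paths.
#' @param g The [interactome()] the roles belong to.
#' @return A [role_set()].
#' @export
read_roles <- function(receptor_path, tr_path, g) {
  role_set(read_node_list(receptor_path), read_node_list(tr_path), g = g)
}

#' Read a combined two-column role table
#'
#' Alternative role format: tab-separated `node`, `role` with role in
#' `{receptor, tr}` (case-insensitive).
#'
#' @param path File path.
#' @param g The [interactome()] the roles belong to.
#' @return A [role_set()].
#' @export
read_role_table <- function(path, g) {
  tsv <- read_tsv_lines(path)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("parse error at line ", tsv$lineno[which(nf < 2)[1]],
         ": expected node<TAB>role", call. = FALSE)
  }
  node <- vapply(parts, `[[`, "", 1)
  role <- tolower(vapply(parts, `[[`, "", 2))
  bad <- !role %in% c("receptor", "tr")
  if (any(bad)) {
    stop("parse error at line ", tsv$lineno[which(bad)[1]],
         ": role must be 'receptor' or 'tr', found '", role[which(bad)[1]],
         "'", call. = FALSE)
  }
  role_set(node[role == "receptor"], node[role == "tr"], g = g)
}

#' Read a curated pathway edge list (evaluation positives)
#'
#' Tab-separated `tail`, `head` columns (extra columns ignored); restricted to
#' edges present in the interactome, per [pathway_truth()].
#'
#' @param path File path.
#' @param g Optional [interactome()].
#' @return A [pathway_truth()].
#' @export
read_pathway <- function(path, g = NULL) {
  tsv <- read_tsv_lines(path)
  if (!length(tsv$lines)) stop("no edges in '", path, "'", call. = FALSE)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("parse error at line ", tsv$lineno[which(nf < 2)[1]],
         ": expected at least 2 tab-separated fields", call. = FALSE)
  }
  pathway_truth(data.frame(tail = vapply(parts, `[[`, "", 1),
                           head = vapply(parts, `[[`, "", 2),
                           stringsAsFactors = FALSE),
                g = g)
}

#' Write a reconstruction to ranked-edges and paths TSV files
#'
#' Writes `<prefix>-ranked-edges.tsv` (`tail`, `head`, `first_path_index`;
#' ascending by index, ties by position along the path, then lexicographic)
#' and `<prefix>-paths.tsv` (`path_index`, `path_score`, pipe-joined node
#' sequence, artificial source/sink excluded). Scores are printed with full
#' precision; [read_reconstruction()] round-trips both files.
#'
#' @param rec A [reconstruct()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_reconstruction <- function(rec, prefix) {
  stopifnot(inherits(rec, "reconstruction"), length(rec$paths) > 0)
  re <- ranked_edges(rec)
  f_edges <- paste0(prefix, "-ranked-edges.tsv")
  f_paths <- paste0(prefix, "-paths.tsv")
  writeLines(c("#tail\thead\tfirst_path_index",
               paste(re$tail, re$head, re$index, sep = "\t")),
             f_edges)
  writeLines(c("#path_index\tpath_score\tpath_nodes",
               vapply(rec$paths, function(p) {
                 paste(p$index, fmt_num(p$score),
                       paste(p$nodes, collapse = "|"), sep = "\t")
               }, "")),
             f_paths)
  invisible(c(f_edges, f_paths))
}

#' Read a reconstruction written by [write_reconstruction()]
#'
#' Rebuilds the path list from `<prefix>-paths.tsv` and recomputes the
#' first-path-index maps; path costs are recovered as `-log(score)`.
#'
#' @param prefix Path prefix used at write time.
#' @return An object of class `reconstruction`.
#' @export
read_reconstruction <- function(prefix) {
  tsv <- read_tsv_lines(paste0(prefix, "-paths.tsv"))
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  paths <- lapply(parts, function(p) {
    stopifnot(length(p) >= 3)
    score <- as.numeric(p[[2]])
    list(nodes = strsplit(p[[3]], "|", fixed = TRUE)[[1]],
         cost = -log(score), score = score, index = as.integer(p[[1]]))
  })
  paths <- paths[order(vapply(paths, `[[`, 0L, "index"))]
  build_reconstruction(paths, k_requested = length(paths))
}
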