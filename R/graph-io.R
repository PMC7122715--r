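#' Undirected spatial centerline graph
#'
#' The 1-D representation of the airways: vertices are 3-D points in world mm,
#' edges are unordered vertex pairs. This is the input form for inlet
#' detection and conversion to a rooted airway tree.
#'
#' @param nodes data.frame with columns `id` (unique), `x`, `y`, `z` (mm);
#'   extra columns are kept as attributes.
#' @param edges data.frame with columns `from`, `to` referring to node ids;
#'   extra columns are kept as attributes.
#' @return An object of class `centerline_graph`.
#' @export
centerline_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  req <- c("id", "x", "y", "z")
  if (!all(req %in% names(nodes)))
    stop("nodes must have columns id, x, y, z")
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have columns from, to")
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stop(sprintf("duplicate node ids: %s", paste(unique(dup), collapse = ", ")))
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node positions must be finite")
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep))
    stop(sprintf("edge endpoints not in node table: %s",
                 paste(unique(missing_ep), collapse = ", ")))
  if (any(edges$from == edges$to))
    stop(sprintf("self-loop edges not allowed (ids: %s)",
                 paste(unique(edges$from[edges$from == edges$to]), collapse = ", ")))
  structure(list(nodes = nodes, edges = edges), class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat("centerline_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read / write a centerline graph as JSON
#'
#' On-disk schema: a JSON object with a `"nodes"` array (objects with `id`,
#' `x`, `y`, `z` and optional attributes such as `generation` or `diameter`)
#' and an `"edges"` array (objects with `from`, `to` and optional attributes).
#' Positions round-trip losslessly (all digits serialized).
#'
#' @param path file path (`.json`).
#' @return `read_graph()`: a [centerline_graph].
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop(sprintf("graph file not found: %s", path))
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(j$nodes) || is.null(j$edges))
    stop(sprintf("%s: graph JSON must contain \"nodes\" and \"edges\" arrays", path))
  centerline_graph(j$nodes, j$edges)
}

#' @rdname read_graph
#' @param g a [centerline_graph].
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "centerline_graph"))
  jsonlite::write_json(list(nodes = g$nodes, edges = g$edges), path,
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Adjacency list keyed by row index (not id); used by the tree algorithms.
adjacency_list <- function(g) {
  n <- nrow(g$nodes)
  idx <- match(c(g$edges$from, g$edges$to), g$nodes$id)
  from <- idx[seq_len(nrow(g$edges))]
  to <- idx[nrow(g$edges) + seq_len(nrow(g$edges))]
  adj <- vector("list", n)
  pairs <- split(c(to, from), c(from, to))
  adj[as.integer(names(pairs))] <- lapply(pairs, function(v) sort(unique(v)))
  adj[vapply(adj, is.null, logical(1L))] <- list(integer(0L))
  adj
}
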