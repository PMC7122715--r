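#' Rooted directed airway tree
#'
#' Branches are maximal chains between branching points of the centerline.
#' Each branch has a polyline (proximal to distal, world mm), a generation
#' (trachea = 0, incrementing at every branching node), an arc length and an
#' optional diameter. Branch ids are row numbers in `branches`.
#'
#' @param branches data.frame with columns `id`, `parent` (NA for the root),
#'   `generation`, `length`, `diameter`.
#' @param polylines list of k x 3 matrices, one per branch, proximal first.
#' @return An object of class `airway_tree`.
#' @export
airway_tree <- function(branches, polylines) {
  branches <- as.data.frame(branches)
  req <- c("id", "parent", "generation", "length", "diameter")
  if (!all(req %in% names(branches)))
    stop("branches must have columns id, parent, generation, length, diameter")
  if (!identical(branches$id, seq_len(nrow(branches))))
    stop("branch ids must be 1..n in row order")
  nroot <- sum(is.na(branches$parent))
  if (nroot != 1L) stop(sprintf("tree must have exactly one root (found %d)", nroot))
  if (length(polylines) != nrow(branches))
    stop("one polyline per branch required")
  structure(list(branches = branches, polylines = polylines),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  b <- x$branches
  cat("airway_tree:", nrow(b), "branches, generations 0..",
      max(b$generation), ", ", sum(!b$id %in% b$parent), " terminal\n", sep = "")
  invisible(x)
}

branch_prox <- function(tree, i) tree$polylines[[i]][1L, ]
branch_dist <- function(tree, i) {
  p <- tree$polylines[[i]]
  p[nrow(p), ]
}

# Chord direction (proximal -> distal), unit length.
branch_direction <- function(tree, i) {
  p <- tree$polylines[[i]]
  d <- p[nrow(p), ] - p[1L, ]
  if (vec_norm(d) < 1e-12) return(c(0, 0, 1))
  normalize(d)
}

# n x 3 matrices of all proximal / distal endpoints.
all_distal_points <- function(tree) {
  t(vapply(seq_len(nrow(tree$branches)), function(i) branch_dist(tree, i),
           numeric(3L)))
}

children_list <- function(tree) {
  n <- nrow(tree$branches)
  kids <- vector("list", n)
  par <- tree$branches$parent
  byp <- split(tree$branches$id[!is.na(par)], par[!is.na(par)])
  kids[as.integer(names(byp))] <- byp
  kids[vapply(kids, is.null, logical(1L))] <- list(integer(0L))
  kids
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Detect the inlet (trachea end) of an undirected centerline graph
#'
#' Walks every chain of degree-<=2 vertices attached to a branching vertex
#' (degree > 2) and returns the free end of the longest such chain, length
#' measured in chain vertices. This identifies the trachea: the longest
#' unbranched run of the centerline ending at a leaf. Ties are broken by the
#' lowest terminal-vertex id. If the graph has no branching vertex (a pure
#' path), the endpoint on the longer arc side of the path's middle vertex is
#' returned with a warning.
#'
#' @param g a [centerline_graph], connected, with at least 2 vertices.
#' @return The node `id` of the inlet vertex.
#' @export
detect_inlet <- function(g) {
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  n <- length(adj)
  if (n < 2L) stop("graph must have at least 2 vertices")
  branching <- which(deg > 2L)
  pos <- as.matrix(g$nodes[, c("x", "y", "z")])
  if (length(branching) == 0L) {
    warning("no branching vertex; falling back to path endpoint")
    ends <- which(deg == 1L)
    if (length(ends) != 2L) stop("graph is neither branched nor a simple path")
    path <- walk_chain(adj, ends[1L], adj[[ends[1L]]][1L], deg)$chain
    arc <- polyline_length(pos[path, , drop = FALSE])
    # arc length from the middle vertex to each end
    mid <- path[ceiling(length(path) / 2)]
    l1 <- polyline_length(pos[path[seq_len(match(mid, path))], , drop = FALSE])
    l2 <- arc - l1
    best <- if (l1 > l2) path[1L] else if (l2 > l1) path[length(path)]
            else min(path[1L], path[length(path)])
    return(g$nodes$id[best])
  }
  best_len <- -1L
  best_term <- NA_integer_
  for (b in branching) {
    for (nb in adj[[b]]) {
      w <- walk_chain(adj, b, nb, deg)
      if (!w$leaf) next  # chain ends at another branching vertex
      term <- w$chain[length(w$chain)]
      len <- length(w$chain)
      if (len > best_len || (len == best_len && term < best_term)) {
        best_len <- len
        best_term <- term
      }
    }
  }
  if (is.na(best_term)) stop("no leaf-terminated chain found")
  g$nodes$id[best_term]
}

# Walk from `start` into neighbour `nxt` along degree-<=2 vertices.
# Returns the vertex chain (row indices, including both ends) and whether it
# ended at a leaf (TRUE) or at a branching vertex (FALSE).
walk_chain <- function(adj, start, nxt, deg) {
  chain <- c(start, nxt)
  prev <- start
  cur <- nxt
  while (deg[cur] == 2L) {
    nn <- adj[[cur]]
    nx <- nn[nn != prev]
    if (length(nx) == 0L) break
    chain <- c(chain, nx)
    prev <- cur
    cur <- nx
  }
  list(chain = chain, leaf = deg[cur] == 1L)
}

#' Convert an undirected centerline graph to a rooted airway tree
#'
#' Orients all edges away from the inlet vertex `y` (breadth-first), merges
#' chains of degree-2 vertices into branch polylines, computes arc lengths
#' and assigns generations: the root branch is generation 0 and the
#' generation increments by one at every branching node.
#'
#' @param g a [centerline_graph].
#' @param y inlet node id (see [detect_inlet()]); defaults to auto-detection.
#' @return An [airway_tree].
#' @export
to_directed <- function(g, y = detect_inlet(g)) {
  adj <- adjacency_list(g)
  pos <- as.matrix(g$nodes[, c("x", "y", "z")])
  root <- match(y, g$nodes$id)
  if (is.na(root)) stop(sprintf("inlet id %s not in graph", y))
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  order_v <- integer(0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_v <- c(order_v, v)
    for (u in adj[[v]]) {
      if (u == parent[v] && !is.na(parent[v])) next
      if (seen[u]) stop("cycle detected: centerline graph must be a tree")
      seen[u] <- TRUE
      parent[u] <- v
      queue <- c(queue, u)
    }
  }
  if (!all(seen)) stop("graph is not connected")
  kids <- vector("list", n)
  for (v in seq_len(n)) if (!is.na(parent[v]))
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  # branch segmentation by walking from the root
  branches <- list()
  polys <- list()
  # stack entries: (start vertex, generation, parent branch id)
  stack <- list(list(v = root, gen = 0L, par = NA_integer_))
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    chain <- s$v
    cur <- s$v
    while (length(kids[[cur]]) == 1L) {
      cur <- kids[[cur]]
      chain <- c(chain, cur)
    }
    id <- length(branches) + 1L
    poly <- pos[chain, , drop = FALSE]
    branches[[id]] <- data.frame(id = id, parent = s$par, generation = s$gen,
                                 length = polyline_length(poly),
                                 diameter = NA_real_)
    polys[[id]] <- poly
    for (ch in rev(kids[[cur]]))
      stack[[length(stack) + 1L]] <- list(v = ch, gen = s$gen + 1L, par = id)
  }
  br <- do.call(rbind, branches)
  # children branches start at the branching vertex: prepend it to polylines
  for (i in seq_len(nrow(br))) {
    if (!is.na(br$parent[i])) {
      pp <- polys[[br$parent[i]]]
      polys[[i]] <- rbind(pp[nrow(pp), ], polys[[i]])
      br$length[i] <- polyline_length(polys[[i]])
    }
  }
  airway_tree(br, polys)
}

#' Prune an airway tree to a maximum generation
#'
#' Removes all branches with generation greater than `n_keep`, then trims
#' incomplete terminal bifurcations: a terminal branch that is an only child
#' is removed (repeatedly), so every retained distal branch ends either at a
#' true endpoint of the input or at a complete bifurcation. This prepares a
#' seed tree whose distal points can all host volume-filling growth.
#'
#' @param tree an [airway_tree].
#' @param n_keep last generation to keep (>= 0).
#' @return A re-indexed [airway_tree].
#' @export
prune <- function(tree, n_keep) {
  stopifnot_scalar_num(n_keep, "n_keep")
  if (n_keep < 0) stop("'n_keep' must be >= 0")
  b <- tree$branches
  if (n_keep > max(b$generation)) {
    warning("n_keep exceeds tree depth; tree returned unchanged")
    return(tree)
  }
  keep <- b$generation <= n_keep
  tr <- subset_tree(tree, keep)
  # trim dangling only-children until stable
  repeat {
    kids <- children_list(tr)
    nk <- lengths(kids)
    b2 <- tr$branches
    drop <- b2$id[!is.na(b2$parent) & nk[b2$id] == 0L &
                    nk[b2$parent] == 1L]
    if (length(drop) == 0L) break
    tr <- subset_tree(tr, !(b2$id %in% drop))
  }
  tr
}

# Keep branches where `keep` is TRUE (must be ancestor-closed) and re-index.
subset_tree <- function(tree, keep) {
  b <- tree$branches[keep, , drop = FALSE]
  newid <- match(seq_len(nrow(tree$branches)), which(keep))
  b$parent <- newid[b$parent]
  b$id <- seq_len(nrow(b))
  rownames(b) <- NULL
  airway_tree(b, tree$polylines[keep])
}

#' Distal (terminal) branches of an airway tree
#'
#' @param tree an [airway_tree].
#' @return Integer vector of branch ids with no children.
#' @export
distal_branches <- function(tree) {
  kids <- children_list(tree)
  tree$branches$id[lengths(kids) == 0L]
}

#' Flatten an airway tree back to an undirected centerline graph
#'
#' Inverse of [to_directed()] up to vertex indexing: polyline vertices are
#' welded at shared junction coordinates and consecutive polyline points
#' become undirected edges carrying the branch generation as an attribute.
#'
#' @param tree an [airway_tree].
#' @return A [centerline_graph].
#' @export
as_centerline_graph <- function(tree) {
  allp <- do.call(rbind, tree$polylines)
  key <- paste(round(allp[, 1L], 9), round(allp[, 2L], 9), round(allp[, 3L], 9))
  first <- !duplicated(key)
  nid <- match(key, key[first])
  verts <- allp[first, , drop = FALSE]
  efrom <- integer(0L); eto <- integer(0L); egen <- integer(0L)
  off <- 0L
  for (i in seq_along(tree$polylines)) {
    k <- nrow(tree$polylines[[i]])
    if (k >= 2L) {
      idx <- nid[off + seq_len(k)]
      efrom <- c(efrom, idx[-k])
      eto <- c(eto, idx[-1L])
      egen <- c(egen, rep(tree$branches$generation[i], k - 1L))
    }
    off <- off + k
  }
  centerline_graph(
    data.frame(id = seq_len(nrow(verts)), x = verts[, 1L], y = verts[, 2L],
               z = verts[, 3L]),
    data.frame(from = efrom, to = eto, generation = egen))
}

#' Read / write an airway tree as JSON
#'
#' Serializes the branch table and polylines; positions keep full precision.
#'
#' @param tree an [airway_tree].
#' @param path file path (`.json`).
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(
    list(branches = tree$branches,
         polylines = lapply(tree$polylines, unname)),
    path, dataframe = "rows", digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  b <- j$branches
  b$parent <- suppressWarnings(as.integer(b$parent))
  b$id <- as.integer(b$id)
  b$generation <- as.integer(b$generation)
  if (is.null(b$diameter)) b$diameter <- NA_real_
  pl <- j$polylines
  polys <- if (is.array(pl) && length(dim(pl)) == 3L) {
    # uniform polylines simplify to an (n, k, 3) array on read
    lapply(seq_len(dim(pl)[1L]), function(i) pl[i, , , drop = TRUE])
  } else {
    lapply(pl, function(p) {
      if (is.matrix(p)) p else matrix(unlist(p), ncol = 3L, byrow = TRUE)
    })
  }
  airway_tree(b, polys)
}
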