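# Fixtures and independent oracles, all built in code.

# simple "Y": one stem branch and two arms
make_y_tree <- function(stem = 20, arm_dx = 10, arm_dz = -10) {
  airway_tree(
    data.frame(id = 1:3, parent = c(NA, 1L, 1L), generation = c(0L, 1L, 1L),
               length = c(stem, sqrt(arm_dx^2 + arm_dz^2),
                          sqrt(arm_dx^2 + arm_dz^2)),
               diameter = NA_real_),
    list(rbind(c(0, 0, stem), c(0, 0, 0)),
         rbind(c(0, 0, 0), c(arm_dx, 0, arm_dz)),
         rbind(c(0, 0, 0), c(-arm_dx, 0, arm_dz))))
}

# full symmetric binary tree of given depth with clean geometry: every
# branch has the same length, children split symmetrically in alternating
# planes
make_full_tree <- function(depth, len = 10) {
  branches <- list(data.frame(id = 1L, parent = NA_integer_, generation = 0L,
                              length = len, diameter = NA_real_))
  polys <- list(rbind(c(0, 0, 0), c(0, 0, -len)))
  queue <- list(list(id = 1L, tip = c(0, 0, -len), dir = c(0, 0, -1), gen = 0L))
  nid <- 1L
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    if (s$gen >= depth) next
    ax <- if (s$gen %% 2L == 0L) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * s$dir) * s$dir
    if (sqrt(sum(ax^2)) < 1e-9) ax <- c(1, 0, 0)
    ax <- ax / sqrt(sum(ax^2))
    for (sgn in c(1, -1)) {
      d <- s$dir * cos(pi / 5) + sgn * ax * sin(pi / 5)
      d <- d / sqrt(sum(d^2))
      tip <- s$tip + len * d
      nid <- nid + 1L
      branches[[nid]] <- data.frame(id = nid, parent = s$id,
                                    generation = s$gen + 1L, length = len,
                                    diameter = NA_real_)
      polys[[nid]] <- rbind(s$tip, tip)
      queue[[length(queue) + 1L]] <- list(id = nid, tip = tip, dir = d,
                                          gen = s$gen + 1L)
    }
  }
  airway_tree(do.call(rbind, branches), polys)
}

# random rooted binary-ish tree (branch table form) for order oracles
make_random_tree <- function(n_branches, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, integer(n_branches - 1L))
  gen <- integer(n_branches)
  for (i in 2:n_branches) {
    # attach to a branch with < 2 children
    nchild <- tabulate(parent[!is.na(parent)], nbins = n_branches)
    open <- which(nchild < 2L & seq_len(n_branches) < i)
    parent[i] <- sample(open, 1L)
    gen[i] <- gen[parent[i]] + 1L
  }
  polys <- vector("list", n_branches)
  tips <- matrix(0, n_branches, 3L)
  tips[1L, ] <- c(0, 0, -10)
  polys[[1L]] <- rbind(c(0, 0, 0), tips[1L, ])
  for (i in 2:n_branches) {
    d <- rnorm(3L); d <- d / sqrt(sum(d^2))
    tips[i, ] <- tips[parent[i], ] + runif(1L, 2, 10) * d
    polys[[i]] <- rbind(tips[parent[i], ], tips[i, ])
  }
  len <- vapply(polys, function(p) sqrt(sum((p[2L, ] - p[1L, ])^2)), numeric(1L))
  airway_tree(data.frame(id = seq_len(n_branches), parent = parent,
                         generation = gen, length = len,
                         diameter = NA_real_), polys)
}

# random undirected centerline graph: a random topology tree whose branches
# are chains of 1..5 vertices; at least one branching vertex
make_random_centerline <- function(seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0)
  edges <- data.frame(from = integer(0L), to = integer(0L))
  # ends available for extension
  tips <- 1L
  nb <- sample(4:9, 1L)
  for (k in seq_len(nb)) {
    at <- tips[sample.int(length(tips), 1L)]
    chain_len <- sample(1:5, 1L)
    prev <- at
    for (j in seq_len(chain_len)) {
      id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, data.frame(id = id, x = rnorm(1L, nodes$x[prev], 3),
                                       y = rnorm(1L, nodes$y[prev], 3),
                                       z = rnorm(1L, nodes$z[prev], 3)))
      edges <- rbind(edges, data.frame(from = prev, to = id))
      prev <- id
    }
    tips <- c(tips, prev)
  }
  g <- centerline_graph(nodes, edges)
  deg <- lengths(lungtree:::adjacency_list(g))
  if (max(deg) <= 2L) {
    # pure path: attach one extra chain mid-path so a branching vertex exists
    at <- which(deg == 2L)[1L]
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = id, x = nodes$x[at] + 1,
                                     y = nodes$y[at] + 1, z = nodes$z[at]))
    edges <- rbind(edges, data.frame(from = at, to = id))
    g <- centerline_graph(nodes, edges)
  }
  g
}

# independent inlet oracle: for every leaf, hop distance (vertex count of
# the chain) to the nearest branching vertex; pick the longest, ties by
# lowest leaf id
brute_force_inlet <- function(g) {
  adj <- lungtree:::adjacency_list(g)
  deg <- lengths(adj)
  branching <- which(deg > 2L)
  leaves <- which(deg == 1L)
  if (length(branching) == 0L) stop("oracle needs a branching vertex")
  best_len <- -1L; best <- NA_integer_
  for (lf in leaves) {
    # BFS from the leaf until a branching vertex is reached
    dist <- rep(NA_integer_, length(adj))
    dist[lf] <- 1L
    q <- lf
    hit <- NA_integer_
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      if (v %in% branching) { hit <- dist[v]; break }
      for (u in adj[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        q <- c(q, u)
      }
    }
    if (is.na(hit)) next
    if (hit > best_len || (hit == best_len && lf < best)) {
      best_len <- hit; best <- lf
    }
  }
  g$nodes$id[best]
}

# independent recursive order oracles
oracle_orders <- function(tree, scheme) {
  kids <- lungtree:::children_list(tree)
  rec <- function(i) {
    ch <- kids[[i]]
    if (length(ch) == 0L) return(1L)
    co <- vapply(ch, rec, integer(1L))
    m <- max(co)
    if (scheme == "horsfield") return(m + 1L)
    if (sum(co == m) >= 2L) m + 1L else m
  }
  root <- tree$branches$id[is.na(tree$branches$parent)]
  out <- integer(nrow(tree$branches))
  walk <- function(i) {
    out[i] <<- rec(i)
    for (ch in kids[[i]]) walk(ch)
  }
  walk(root)
  out
}

# cached small phantom for the expensive modules
phantom_cache <- new.env()
get_phantom <- function(volume = 2) {
  key <- paste0("v", volume)
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- make_phantom(volume, spacing = 2, depth = 3)
  phantom_cache[[key]]
}
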