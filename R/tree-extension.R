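# Volume-filling bifurcating extension of a seed airway tree.
#
# Each lung subvolume is sampled with uniform points; every point is assigned
# to the nearest distal branch; each seed branch then repeatedly splits its
# point set by a PCA-derived plane through the set's centroid and containing
# the branch axis, and grows one child per half a fixed fraction of the way
# from the branch tip to the half's centroid. Children shorter than the
# terminal length stop growing; children leaving the lung are discarded with
# their points; the process runs until no seed points remain.

#' Distance from points to a segment
#'
#' Euclidean point-to-segment distance in mm, vectorized over points.
#' @param pts n x 3 matrix.
#' @param p0,p1 segment endpoints.
#' @return numeric vector of length n.
#' @keywords internal
dist_point_segment <- function(pts, p0, p1) {
  pts <- rbind_mat(pts)
  v <- p1 - p0
  l2 <- sum(v * v)
  if (l2 < 1e-24) return(sqrt(rowdist2(pts, p0)))
  t <- ((pts[, 1L] - p0[1L]) * v[1L] + (pts[, 2L] - p0[2L]) * v[2L] +
        (pts[, 3L] - p0[3L]) * v[3L]) / l2
  t <- pmin(1, pmax(0, t))
  dx <- pts[, 1L] - (p0[1L] + t * v[1L])
  dy <- pts[, 2L] - (p0[2L] + t * v[2L])
  dz <- pts[, 3L] - (p0[3L] + t * v[3L])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Assign sampled points to the nearest distal branch
#'
#' Every point is attached to the distal branch whose distal point is nearest
#' (Euclidean, mm); ties go to the lowest branch id. The result is the
#' initial growth state for [grow()].
#'
#' @param points a `sampled_points` object, an n x 3 matrix, or a list of
#'   `sampled_points` (one per lung).
#' @param tree a seed [airway_tree].
#' @param branch_subset optional integer vector restricting the candidate
#'   distal branches (e.g. the branches of one lung).
#' @return A `growth_state`: list with the seed `tree`, the pooled point
#'   matrix `points`, per-point lung `labels`, and `seeds`, a list of
#'   (branch id, point index vector) pairs.
#' @export
assign_points_to_distal <- function(points, tree, branch_subset = NULL) {
  stopifnot(inherits(tree, "airway_tree"))
  plist <- if (inherits(points, "sampled_points")) list(points)
           else if (is.list(points) && !is.null(points$points %||% NULL)) list(points)
           else if (is.list(points)) points
           else list(structure(list(points = rbind_mat(points), source_label = 1L),
                               class = "sampled_points"))
  P <- do.call(rbind, lapply(plist, function(s) s$points))
  labels <- unlist(lapply(plist, function(s) rep(s$source_label, nrow(s$points))))
  if (nrow(P) == 0L) stop("no points to assign")
  dist_ids <- distal_branches(tree)
  if (is.null(branch_subset)) branch_subset <- dist_ids
  cand <- intersect(dist_ids, branch_subset)
  if (length(cand) == 0L) stop("no distal branches to assign points to")
  dp <- all_distal_points(tree)[cand, , drop = FALSE]
  # nearest distal point; ties -> lowest branch id (cand is sorted ascending)
  dmin <- rep(Inf, nrow(P))
  best <- rep(cand[1L], nrow(P))
  for (k in seq_along(cand)) {
    dk <- rowdist2(P, dp[k, ])
    upd <- dk < dmin - 1e-12
    dmin[upd] <- dk[upd]
    best[upd] <- cand[k]
  }
  seeds <- lapply(cand, function(b) list(branch = b, idx = which(best == b)))
  structure(list(tree = tree, points = P, labels = labels, seeds = seeds),
            class = "growth_state")
}

#' Splitting plane for a point subdivision
#'
#' The plane passes through the centroid of the points and contains the
#' branch direction: its normal is `d x (d x u_m)`, where `u_m` is the
#' principal eigenvector of the autocorrelation matrix of the centered
#' points (the direction of greatest variance). Splitting perpendicular to
#' the widest spread of the remaining space keeps both halves compact and
#' avoids very long branches.
#'
#' @param points n x 3 matrix (n >= 2; >= 3 non-collinear for a well-defined
#'   principal direction).
#' @param branch_direction unit vector `d` of the distal branch.
#' @return List with `point` (the centroid) and unit `normal`.
#' @export
splitting_plane <- function(points, branch_direction) {
  points <- rbind_mat(points)
  if (nrow(points) < 2L) stop("need at least 2 points to define a splitting plane")
  d <- normalize(branch_direction)
  ctr <- colMeans(points)
  pc <- sweep(points, 2L, ctr)
  um <- eigen(crossprod(pc), symmetric = TRUE)$vectors[, 1L]
  nrm <- plane_normal(d, um)
  if (is.null(nrm)) {
    warning("principal direction parallel to branch; using a fixed perpendicular")
    nrm <- perp_vector(d)
  }
  list(point = ctr, normal = nrm)
}

# d x (d x u), normalized; NULL when degenerate (u parallel to d).
plane_normal <- function(d, u) {
  w <- cross3(d, cross3(d, u))
  n <- vec_norm(w)
  if (n < 1e-8) return(NULL)
  w / n
}

#' Grow the airway tree into the sampled lung volume
#'
#' Runs the volume-filling loop on a growth state from
#' [assign_points_to_distal()]: split each seed's points by
#' [splitting_plane()], grow one child branch per half from the seed's distal
#' point `branch_fraction` of the way to the half centroid, mark children
#' shorter than `terminal_length_mm` as terminal, drop children whose distal
#' point or midpoint leaves the seed's lung label, and repeat until no seed
#' points remain (or the generation cap / its 2^(cap+1) bifurcation safety
#' counter is reached). Points follow their half; points behind terminal or
#' discarded branches leave the pool.
#'
#' @param state a `growth_state`.
#' @param lung_mask labelled [voxel_image] (1 = right, 2 = left).
#' @param branch_fraction fraction of the tip-to-centroid distance a child
#'   spans (default 0.4).
#' @param terminal_length_mm children shorter than this stop growing
#'   (default 2 mm).
#' @param max_generations generation cap; `Inf` grows to the terminal-length
#'   criterion.
#' @param plane_method `"pca"` (default) or `"random"` (random plane through
#'   the centroid containing the branch axis; for ablation studies).
#' @return The extended [airway_tree] (seed tree plus grown branches).
#' @export
grow <- function(state, lung_mask, branch_fraction = 0.4,
                 terminal_length_mm = 2, max_generations = Inf,
                 plane_method = c("pca", "random")) {
  stopifnot(inherits(state, "growth_state"), inherits(lung_mask, "voxel_image"))
  plane_method <- match.arg(plane_method)
  if (branch_fraction <= 0 || branch_fraction >= 1)
    stop("'branch_fraction' must be in (0, 1)")
  if (terminal_length_mm <= 0) stop("'terminal_length_mm' must be positive")
  tree <- state$tree
  P <- state$points
  labels <- state$labels
  n0 <- nrow(tree$branches)
  # fast world -> voxel label lookup
  d3 <- dim(lung_mask$array)
  inv <- solve(lung_mask$direction %*% diag(lung_mask$spacing))
  org <- lung_mask$origin
  arr <- lung_mask$array
  lab_at <- function(p) {
    ix <- round(inv %*% (p - org)) + 1
    if (ix[1L] < 1 || ix[1L] > d3[1L] || ix[2L] < 1 || ix[2L] > d3[2L] ||
        ix[3L] < 1 || ix[3L] > d3[3L]) return(0L)
    arr[ix[1L], ix[2L], ix[3L]]
  }
  cap <- 2e6L
  parent <- integer(cap); gen <- integer(cap)
  prox <- matrix(0, cap, 3L); dst <- matrix(0, cap, 3L)
  nb <- n0
  parent[seq_len(n0)] <- ifelse(is.na(tree$branches$parent), 0L, tree$branches$parent)
  gen[seq_len(n0)] <- tree$branches$generation
  for (i in seq_len(n0)) {
    prox[i, ] <- branch_prox(tree, i)
    dst[i, ] <- branch_dist(tree, i)
  }
  # FIFO queue with head pointer
  qcap <- 65536L
  queue <- vector("list", qcap)
  qhead <- 0L; qtail <- 0L
  push <- function(x) {
    if (qtail == qcap) {
      qcap <<- qcap * 2L
      length(queue) <<- qcap
    }
    qtail <<- qtail + 1L
    queue[[qtail]] <<- x
  }
  for (s in state$seeds)
    if (length(s$idx)) push(list(b = s$branch, idx = s$idx,
                                 lab = labels[s$idx[1L]]))
  bif_count <- 0L
  bif_cap <- if (is.finite(max_generations)) 2^(max_generations + 1) else Inf
  first_iter_children <- 0L
  first_iter_done <- FALSE
  first_iter_seeds <- qtail
  while (qhead < qtail) {
    qhead <- qhead + 1L
    s <- queue[[qhead]]
    queue[qhead] <- list(NULL)
    idx <- s$idx
    np <- length(idx)
    if (np == 0L) next
    b <- s$b
    tip <- dst[b, ]
    dvec <- tip - prox[b, ]
    dn <- vec_norm(dvec)
    dvec <- if (dn < 1e-12) c(0, 0, 1) else dvec / dn
    pts <- P[idx, , drop = FALSE]
    if (np == 1L) {
      halves <- list(idx)
      targets <- list(pts[1L, ])
    } else {
      ctr <- colMeans(pts)
      pc <- sweep(pts, 2L, ctr)
      nrm <- if (plane_method == "pca") {
        um <- eigen(crossprod(pc), symmetric = TRUE)$vectors[, 1L]
        plane_normal(dvec, um) %||% perp_vector(dvec)
      } else {
        e1 <- perp_vector(dvec)
        e2 <- cross3(dvec, e1)
        phi <- stats::runif(1L, 0, 2 * pi)
        cos(phi) * e1 + sin(phi) * e2
      }
      side <- pc %*% nrm > 0
      halves <- list(idx[side], idx[!side])
      targets <- lapply(list(side, !side), function(m)
        if (any(m)) colMeans(pts[m, , drop = FALSE]) else NULL)
    }
    children_made <- 0L
    for (h in seq_along(halves)) {
      hi <- halves[[h]]
      if (length(hi) == 0L) next
      tgt <- targets[[h]]
      child_tip <- tip + branch_fraction * (tgt - tip)
      len <- vec_norm(child_tip - tip)
      if (len < 1e-9) next
      mid <- (tip + child_tip) / 2
      if (lab_at(child_tip) != s$lab || lab_at(mid) != s$lab) next
      child_gen <- gen[b] + 1L
      if (child_gen > max_generations) next
      nb <- nb + 1L
      if (nb > cap) stop("branch capacity exceeded")
      parent[nb] <- b
      gen[nb] <- child_gen
      prox[nb, ] <- tip
      dst[nb, ] <- child_tip
      children_made <- children_made + 1L
      if (!first_iter_done) first_iter_children <- first_iter_children + 1L
      if (len >= terminal_length_mm)
        push(list(b = nb, idx = hi, lab = s$lab))
    }
    if (children_made == 2L) bif_count <- bif_count + 1L
    if (!first_iter_done && qhead >= first_iter_seeds) {
      first_iter_done <- TRUE
      if (first_iter_children == 0L)
        warning("all seeds terminal on the first iteration: lung volume too small for growth")
    }
    if (bif_count >= bif_cap) {
      warning(sprintf("bifurcation safety counter 2^(n+1) = %g reached; growth stopped", bif_cap))
      break
    }
  }
  # assemble the extended tree: original polylines + straight grown branches
  ids <- seq_len(nb)
  polys <- c(tree$polylines,
             lapply((n0 + 1L):nb, function(i) rbind(prox[i, ], dst[i, ])))
  if (nb == n0) polys <- tree$polylines
  lens <- c(tree$branches$length,
            if (nb > n0) sqrt(rowSums((dst[(n0 + 1L):nb, , drop = FALSE] -
                                       prox[(n0 + 1L):nb, , drop = FALSE])^2)))
  br <- data.frame(id = ids,
                   parent = ifelse(parent[ids] == 0L, NA_integer_, parent[ids]),
                   generation = gen[ids],
                   length = lens,
                   diameter = NA_real_)
  airway_tree(br, polys)
}

#' One-call extension of a seed tree into a labelled lung mask
#'
#' Samples `points_per_lung` uniform points in each lung label, assigns them
#' to the distal branches of the corresponding lung (by the label under each
#' branch's distal point) and runs [grow()]. All randomness (sampling and
#' any stochastic tie-breaks) is governed by `seed`.
#'
#' @inheritParams grow
#' @param mask labelled [voxel_image] (1 = right, 2 = left).
#' @param tree seed [airway_tree].
#' @param points_per_lung uniform sample size per lung (default 30000).
#' @param seed integer RNG seed.
#' @return The extended [airway_tree].
#' @export
extend_tree <- function(mask, tree, points_per_lung = 30000,
                        branch_fraction = 0.4, terminal_length_mm = 2,
                        max_generations = Inf, seed = NULL,
                        plane_method = "pca") {
  labs <- sort(unique(mask$array[mask$array > 0]))
  dist_ids <- distal_branches(tree)
  dp <- all_distal_points(tree)
  dlab <- value_at_world(mask, dp[dist_ids, , drop = FALSE])
  with_seed(seed, {
    states <- lapply(labs, function(lg) {
      sub <- dist_ids[dlab == lg]
      if (length(sub) == 0L)
        stop(sprintf("no distal branch lies inside lung label %d", lg))
      pts <- sample_uniform(mask, lg, points_per_lung)
      assign_points_to_distal(pts, tree, branch_subset = sub)
    })
    merged <- structure(list(
      tree = tree,
      points = do.call(rbind, lapply(states, `[[`, "points")),
      labels = unlist(lapply(states, `[[`, "labels")),
      seeds = unsplit_seeds(states)), class = "growth_state")
    grow(merged, mask, branch_fraction = branch_fraction,
         terminal_length_mm = terminal_length_mm,
         max_generations = max_generations, plane_method = plane_method)
  })
}

# merge per-lung growth states, offsetting point indices into the pooled matrix
unsplit_seeds <- function(states) {
  out <- list()
  off <- 0L
  for (st in states) {
    for (s in st$seeds)
      out[[length(out) + 1L]] <- list(branch = s$branch, idx = s$idx + off)
    off <- off + nrow(st$points)
  }
  out
}

# Mean distance from points to the nearest branch segment of a tree
# (space-utilization metric for plane-choice comparisons).
mean_point_tree_distance <- function(points, tree) {
  pts <- if (inherits(points, "sampled_points")) points$points else rbind_mat(points)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(tree$branches))) {
    p <- tree$polylines[[i]]
    for (k in seq_len(nrow(p) - 1L))
      dmin <- pmin(dmin, dist_point_segment(pts, p[k, ], p[k + 1L, ]))
  }
  mean(dmin)
}
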