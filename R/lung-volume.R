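# Lung mask operations: 26-connected labelling, left/right splitting,
# uniform interior point sampling.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Pad a logical/integer array with one layer of `fill`.
pad_array <- function(a, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d + 2L)
  out[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- a
  out
}

neighbor_offsets_26 <- function(dpad) {
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  as.integer(off$di + off$dj * dpad[1L] + off$dk * dpad[1L] * dpad[2L])
}

# 26-connected component labels of a logical array (0 = background).
# Deterministic: components are numbered by their smallest linear index.
label_components_26 <- function(mask) {
  d <- dim(mask)
  p <- pad_array(mask, FALSE)
  dp <- dim(p)
  offs <- neighbor_offsets_26(dp)
  lab <- array(0L, dp)
  unvisited <- which(p)
  nextlab <- 0L
  visited <- array(FALSE, dp)
  while (length(unvisited)) {
    seedv <- unvisited[1L]
    if (visited[seedv]) { unvisited <- unvisited[!visited[unvisited]]; next }
    nextlab <- nextlab + 1L
    frontier <- seedv
    visited[seedv] <- TRUE
    lab[seedv] <- nextlab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[p[nb] & !visited[nb]]
      visited[nb] <- TRUE
      lab[nb] <- nextlab
      frontier <- nb
    }
    unvisited <- unvisited[!visited[unvisited]]
  }
  lab[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)]
}

# Morphological erosion with the full 26-neighbourhood: a voxel survives only
# if none of its 26 neighbours is background.
erode_26 <- function(mask) {
  d <- dim(mask)
  p <- pad_array(mask, FALSE)
  out <- mask
  ii <- 2:(d[1L] + 1L); jj <- 2:(d[2L] + 1L); kk <- 2:(d[3L] + 1L)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- out & p[ii + di, jj + dj, kk + dk]
  }
  out
}

# Propagate labels into unlabeled foreground voxels layer by layer
# (26-neighbourhood); ties take the lowest neighbouring label.
restore_labels <- function(lab, fg) {
  d <- dim(lab)
  ii <- 2:(d[1L] + 1L); jj <- 2:(d[2L] + 1L); kk <- 2:(d[3L] + 1L)
  repeat {
    todo <- fg & lab == 0L
    if (!any(todo)) break
    p <- pad_array(lab, 0L)
    cand <- array(Inf, d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      nb <- p[ii + di, jj + dj, kk + dk]
      upd <- todo & nb > 0L & nb < cand
      cand[upd] <- nb[upd]
    }
    hit <- is.finite(cand)
    if (!any(hit)) stop("unlabeled foreground not reachable from any label")
    lab[hit] <- as.integer(cand[hit])
  }
  lab
}

#' Split a lung mask into left and right lungs
#'
#' Separates the two 26-connected foreground components of a binary lung
#' mask and assigns anatomical sides using the seed airway tree: the
#' topological distance between the first- and second-generation bifurcations
#' (the arc length of each main-bronchus branch) is longer in the left lung,
#' so the component nearest the distal point of the longer main bronchus is
#' labelled left (2) and the other right (1).
#'
#' Internally the foreground is eroded with the 26-neighbourhood rule (a
#' voxel survives only if no neighbour is background), the eroded cores are
#' labelled by deterministic region growing, and the eroded boundary layer is
#' restored by nearest-label propagation, leaving the foreground volume
#' unchanged.
#'
#' @param mask a [voxel_image] with foreground > 0 (binary or pre-labelled).
#' @param tree an [airway_tree] with at least 2 generations below the trachea.
#' @return A [voxel_image] with labels 0 (background), 1 (right), 2 (left).
#' @export
split_lungs <- function(mask, tree) {
  stopifnot(inherits(mask, "voxel_image"), inherits(tree, "airway_tree"))
  fg <- mask$array > 0
  cc <- label_components_26(fg)
  ncomp <- max(cc)
  if (ncomp != 2L)
    stop(sprintf("topology error: expected exactly 2 foreground components, found %d", ncomp))
  if (max(tree$branches$generation) < 2L)
    stop("tree too shallow: left/right rule needs second-generation bifurcations (>= 2 generations)")
  core <- erode_26(fg)
  lab <- label_components_26(core)
  if (max(lab) < 2L) {
    # erosion merged/removed a component; fall back to the plain components
    lab <- cc
  } else if (max(lab) > 2L) {
    # keep the two largest cores, clear the rest, restore will re-attach them
    sizes <- tabulate(lab[lab > 0L])
    keep <- order(sizes, decreasing = TRUE)[1:2]
    lab[!(lab %in% keep)] <- 0L
    lab[lab == keep[1L]] <- -1L
    lab[lab == keep[2L]] <- -2L
    lab <- -lab
  }
  lab <- restore_labels(lab, fg)
  # left/right by the main-bronchus rule
  g1 <- tree$branches$id[tree$branches$generation == 1L]
  if (length(g1) != 2L)
    stop(sprintf("expected 2 first-generation branches, found %d", length(g1)))
  len <- tree$branches$length[g1]
  left_branch <- g1[which.max(len)]
  p_left <- branch_dist(tree, left_branch)
  img_lab <- voxel_image(lab, mask$spacing, mask$origin, mask$direction)
  at <- value_at_world(img_lab, p_left)
  if (at == 0) {
    # distal point outside the mask: nearest labelled voxel decides
    d1 <- min(rowdist2(label_voxel_centers(img_lab, 1L), p_left))
    d2 <- min(rowdist2(label_voxel_centers(img_lab, 2L), p_left))
    at <- if (d1 <= d2) 1L else 2L
  }
  out <- lab
  if (at == 1L) {  # component 1 is the left lung: swap so left = 2
    out[lab == 1L] <- 2L
    out[lab == 2L] <- 1L
  }
  voxel_image(out, mask$spacing, mask$origin, mask$direction)
}

#' Uniformly sample points inside a labelled lung volume
#'
#' Draws `n` i.i.d. points uniformly over the volume of the voxels carrying
#' `label`: a voxel is chosen with probability proportional to its volume
#' (all voxels are equal-sized, so uniformly) and the position is uniform
#' within the voxel. Reproducible for a given `seed`.
#'
#' @param mask a [voxel_image] with integer labels.
#' @param label which label to sample.
#' @param n number of points (>= 1).
#' @param seed integer RNG seed (optional; caller RNG state is preserved).
#' @return A `sampled_points` object: list with `points` (n x 3 mm) and
#'   `source_label`.
#' @export
sample_uniform <- function(mask, label, n, seed = NULL) {
  stopifnot(inherits(mask, "voxel_image"))
  stopifnot_scalar_num(n, "n")
  if (n < 1) stop("'n' must be >= 1")
  vox <- which(mask$array == label)
  if (length(vox) == 0L) stop(sprintf("label %s is empty", label))
  d <- dim(mask$array)
  with_seed(seed, {
    pick <- vox[sample.int(length(vox), n, replace = TRUE)]
    ai <- arrayInd(pick, d)
    jitter <- matrix(stats::runif(3L * n, -0.5, 0.5), ncol = 3L)
    # jitter in [-0.5, 0.5) keeps the containing voxel equal to the picked one
    jitter[jitter >= 0.5] <- 0.49999
    pts <- index_to_world(mask, ai - 1 + jitter)
    structure(list(points = pts, source_label = label),
              class = "sampled_points")
  })
}

#' Center of mass of sampled points
#'
#' @param points a `sampled_points` object or an n x 3 matrix.
#' @return Length-3 numeric, the arithmetic mean position (mm).
#' @export
centroid <- function(points) {
  pts <- if (inherits(points, "sampled_points")) points$points else rbind_mat(points)
  if (is.null(nrow(pts)) || nrow(pts) == 0L) stop("cannot take centroid of an empty point set")
  colMeans(pts)
}
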