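# Per-generation Gaussian spatial probability maps on the image grid.

#' Spatial probability map of an airway generation
#'
#' For every voxel center x of the reference grid the map value is
#' `W_g(x) = exp(-d^2 / (2 sigma^2)) / (sigma * sqrt(2 pi))`, where `d` is
#' the distance (mm) from x to the closest centerline segment of generation
#' `g`. The map peaks at `1 / (sigma * sqrt(2 pi))` on voxels intersecting
#' the centerline and decays monotonically with distance; it expresses where
#' a branch of that generation is likely to be found given the distributional
#' uncertainty of the extension algorithm.
#'
#' Distances are point-to-segment (not point-to-vertex) and exact: every
#' generation-g polyline segment is scanned against every voxel.
#'
#' @param tree an [airway_tree].
#' @param grid a [voxel_image] defining the output geometry (its values are
#'   ignored).
#' @param g generation to map (trachea = 0).
#' @param sigma Gaussian width in mm (default 1).
#' @return A `probability_map`: list with `image` (a [voxel_image] of map
#'   values), `generation` and `sigma`.
#' @export
generation_map <- function(tree, grid, g, sigma = 1.0) {
  stopifnot(inherits(tree, "airway_tree"), inherits(grid, "voxel_image"))
  stopifnot_scalar_num(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be positive")
  sel <- which(tree$branches$generation == g)
  if (length(sel) == 0L)
    stop(sprintf("no branch of generation %s; available generations: %s", g,
                 paste(sort(unique(tree$branches$generation)), collapse = ", ")))
  d <- min_dist_to_branches(tree, grid, sel)
  w <- exp(-d^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  img <- voxel_image(array(w, dim(grid$array)), grid$spacing, grid$origin,
                     grid$direction)
  structure(list(image = img, generation = g, sigma = sigma),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("probability_map: generation", x$generation, ", sigma", x$sigma,
      "mm, max", signif(max(x$image$array), 5), "\n")
  invisible(x)
}

# Exact minimum distance from every voxel center of `grid` to the polyline
# segments of the selected branches. Returns a vector in array order.
min_dist_to_branches <- function(tree, grid, branch_ids) {
  dims <- dim(grid$array)
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims) - 1
  pts <- index_to_world(grid, idx)
  dmin <- rep(Inf, n)
  for (i in branch_ids) {
    p <- tree$polylines[[i]]
    for (k in seq_len(nrow(p) - 1L))
      dmin <- pmin(dmin, dist_point_segment(pts, p[k, ], p[k + 1L, ]))
  }
  dmin
}

#' Rescale a probability map to the unit interval for visualization
#'
#' Divides by the analytic maximum `1 / (sigma sqrt(2 pi))`. Only intended
#' for overlay export; the unscaled map is the per-generation density.
#'
#' @param pmap a `probability_map`.
#' @return A [voxel_image] with values in (0, 1].
#' @export
normalize_map <- function(pmap) {
  stopifnot(inherits(pmap, "probability_map"))
  peak <- 1 / (pmap$sigma * sqrt(2 * pi))
  voxel_image(pmap$image$array / peak, pmap$image$spacing,
              pmap$image$origin, pmap$image$direction)
}
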