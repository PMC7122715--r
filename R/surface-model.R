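# Tubular point-cloud sampling along a diametered tree, inner-point cleanup,
# bilateral normal smoothing and implicit surface reconstruction.

#' Sample an oriented tubular point cloud along an airway tree
#'
#' Points are drawn uniformly at random on each branch's cylindrical surface
#' of radius `diameter / 2` about its polyline (count proportional to the
#' lateral area `pi * d * L` at the requested density), with outward radial
#' normals. Optionally the trachea inlet and every terminal outlet are capped
#' with sampled disks (axial normals) so the cloud bounds a closed volume.
#'
#' @param tree an [airway_tree] with diameters assigned
#'   (see [assign_diameters()]).
#' @param density points per mm^2 of tube surface (default 40).
#' @param seed RNG seed (optional; caller RNG state preserved).
#' @param cap_ends sample end-cap disks (default TRUE).
#' @return An `oriented_point_cloud`: list with `points` (n x 3 mm), unit
#'   `normals` (n x 3) and `branch` (generating branch id per point).
#' @export
sample_tube_cloud <- function(tree, density = 40, seed = NULL,
                              cap_ends = TRUE) {
  stopifnot(inherits(tree, "airway_tree"))
  diam <- tree$branches$diameter
  if (anyNA(diam) || any(diam <= 0))
    stop("all branches need a positive diameter; run assign_diameters() first")
  with_seed(seed, {
    pts <- list(); nrm <- list(); src <- list()
    root <- tree$branches$id[is.na(tree$branches$parent)]
    term <- distal_branches(tree)
    for (i in seq_len(nrow(tree$branches))) {
      r <- diam[i] / 2
      p <- tree$polylines[[i]]
      for (k in seq_len(nrow(p) - 1L)) {
        p0 <- p[k, ]; p1 <- p[k + 1L, ]
        axis <- p1 - p0
        len <- vec_norm(axis)
        if (len < 1e-9) next
        axis <- axis / len
        n <- round(density * pi * diam[i] * len)
        if (n < 1L) next
        e1 <- perp_vector(axis)
        e2 <- cross3(axis, e1)
        tpar <- stats::runif(n)
        phi <- stats::runif(n, 0, 2 * pi)
        rad <- outer(cos(phi), e1) + outer(sin(phi), e2)
        pts[[length(pts) + 1L]] <-
          sweep(outer(tpar * len, axis), 2L, p0, "+") + r * rad
        nrm[[length(nrm) + 1L]] <- rad
        src[[length(src) + 1L]] <- rep(i, n)
      }
      # end caps: inlet disk on the root, outlet disk on terminals
      capspec <- list()
      if (cap_ends && i == root)
        capspec[[1L]] <- list(at = p[1L, ], out = normalize(p[1L, ] - p[2L, ]))
      if (cap_ends && i %in% term)
        capspec[[length(capspec) + 1L]] <-
          list(at = p[nrow(p), ], out = normalize(p[nrow(p), ] - p[nrow(p) - 1L, ]))
      for (cp in capspec) {
        n <- max(8L, round(density * pi * r^2))
        e1 <- perp_vector(cp$out)
        e2 <- cross3(cp$out, e1)
        rr <- r * sqrt(stats::runif(n))
        phi <- stats::runif(n, 0, 2 * pi)
        pts[[length(pts) + 1L]] <-
          sweep(outer(rr * cos(phi), e1) + outer(rr * sin(phi), e2),
                2L, cp$at, "+")
        nrm[[length(nrm) + 1L]] <- matrix(cp$out, n, 3L, byrow = TRUE)
        src[[length(src) + 1L]] <- rep(i, n)
      }
    }
    structure(list(points = do.call(rbind, pts),
                   normals = do.call(rbind, nrm),
                   branch = unlist(src)),
              class = "oriented_point_cloud")
  })
}

#' @export
print.oriented_point_cloud <- function(x, ...) {
  cat("oriented_point_cloud:", nrow(x$points), "points\n")
  invisible(x)
}

#' Remove cloud points lying inside other branches' tubes
#'
#' A sampled point is deleted when it lies strictly inside the tube of a
#' branch other than the one that generated it (distance to that branch's
#' centerline below its radius minus a 1e-6 mm tolerance). This opens the
#' junctions: what remains is the outer envelope of the union of tubes,
#' which is what the normal estimation and reconstruction need.
#'
#' @param cloud an `oriented_point_cloud` from [sample_tube_cloud()].
#' @param tree the same diametered [airway_tree].
#' @param tol containment tolerance in mm (default 1e-6).
#' @return The filtered `oriented_point_cloud`.
#' @export
cleanup_inner_points <- function(cloud, tree, tol = 1e-6) {
  stopifnot(inherits(cloud, "oriented_point_cloud"),
            inherits(tree, "airway_tree"))
  pts <- cloud$points
  keep <- rep(TRUE, nrow(pts))
  diam <- tree$branches$diameter
  for (i in seq_len(nrow(tree$branches))) {
    r <- diam[i] / 2
    p <- tree$polylines[[i]]
    lo <- apply(p, 2L, min) - r; hi <- apply(p, 2L, max) + r
    cand <- which(keep & cloud$branch != i &
                  pts[, 1L] >= lo[1L] & pts[, 1L] <= hi[1L] &
                  pts[, 2L] >= lo[2L] & pts[, 2L] <= hi[2L] &
                  pts[, 3L] >= lo[3L] & pts[, 3L] <= hi[3L])
    if (length(cand) == 0L) next
    dmin <- rep(Inf, length(cand))
    for (k in seq_len(nrow(p) - 1L))
      dmin <- pmin(dmin, dist_point_segment(pts[cand, , drop = FALSE],
                                            p[k, ], p[k + 1L, ]))
    keep[cand[dmin < r - tol]] <- FALSE
  }
  structure(list(points = pts[keep, , drop = FALSE],
                 normals = cloud$normals[keep, , drop = FALSE],
                 branch = cloud$branch[keep]),
            class = "oriented_point_cloud")
}

#' Bilateral smoothing of point-cloud normals
#'
#' Each normal is replaced by the renormalized Gaussian-weighted sum of its
#' neighbours' normals within `radius`, weighted both by spatial distance
#' (`sigma_spatial`) and by normal similarity (`sigma_normal` acting on
#' `1 - cos` of the normal angle); neighbours facing the opposite way (e.g.
#' across a thin tube) are ignored. Smoothing regularizes the field across
#' bifurcation junctions before reconstruction while the similarity term
#' preserves genuine creases.
#'
#' @param cloud an `oriented_point_cloud`.
#' @param radius neighbourhood radius mm (default: 6x the median
#'   nearest-neighbour spacing).
#' @param sigma_spatial spatial Gaussian width (default `radius / 2`).
#' @param sigma_normal normal-similarity width (default 0.35).
#' @param iterations smoothing passes (default 2).
#' @return The cloud with smoothed unit normals.
#' @export
smooth_normals <- function(cloud, radius = NULL, sigma_spatial = NULL,
                           sigma_normal = 0.35, iterations = 2L) {
  stopifnot(inherits(cloud, "oriented_point_cloud"))
  if (is.null(radius)) radius <- 6 * median_nn_spacing(cloud$points)
  if (is.null(sigma_spatial)) sigma_spatial <- radius / 2
  nrm <- cloud$normals
  for (it in seq_len(iterations))
    nrm <- cpp_smooth_normals(cloud$points, nrm, radius, sigma_spatial,
                              sigma_normal)
  cloud$normals <- nrm
  cloud
}

# Median distance to the nearest other point, from a subsample.
median_nn_spacing <- function(pts, nsub = 400L) {
  n <- nrow(pts)
  sub <- if (n > nsub) pts[seq(1L, n, length.out = nsub), , drop = FALSE] else pts
  idx <- cpp_nearest_index(sub + 1e-9, pts)  # tiny shift so a point can see itself out
  d <- sqrt(rowSums((sub - pts[idx, , drop = FALSE])^2))
  # points that found themselves: fall back to brute force second-nearest
  bad <- d < 1e-8
  if (any(bad)) {
    for (i in which(bad)) {
      dd <- sqrt(rowdist2(pts, sub[i, ]))
      d[i] <- min(dd[dd > 1e-8])
    }
  }
  stats::median(d)
}

#' Reconstruct a watertight surface from an oriented point cloud
#'
#' Smooths the normals (bilateral, see [smooth_normals()]), evaluates the
#' signed distance to the nearest oriented surfel on a regular grid spanning
#' the cloud's bounding box, polygonizes the zero level set by marching
#' tetrahedra and keeps the largest connected component. The signed field is
#' positive outside the cloud, so the output normals point outward and the
#' mesh is watertight by construction of the polygonizer; an error is raised
#' if cleanup breaks that.
#'
#' @param cloud an `oriented_point_cloud` (>= 1000 points).
#' @param grid_spacing iso-grid step in mm (default: 1/80 of the largest
#'   bounding-box extent, capped below by half the median point spacing).
#' @param smooth passes of bilateral normal smoothing (default 2; 0 disables).
#' @param padding grid margin around the cloud in mm (default
#'   `3 * grid_spacing`).
#' @return A watertight [surface_mesh].
#' @export
reconstruct_surface <- function(cloud, grid_spacing = NULL, smooth = 2L,
                                padding = NULL) {
  stopifnot(inherits(cloud, "oriented_point_cloud"))
  if (nrow(cloud$points) < 1000L)
    stop("need at least 1000 oriented points for reconstruction")
  if (smooth > 0L) cloud <- smooth_normals(cloud, iterations = smooth)
  if (is.null(grid_spacing)) {
    ext <- apply(cloud$points, 2L, function(v) diff(range(v)))
    grid_spacing <- max(max(ext) / 80, median_nn_spacing(cloud$points) / 2)
  }
  if (is.null(padding)) padding <- 3 * grid_spacing
  lo <- apply(cloud$points, 2L, min) - padding
  hi <- apply(cloud$points, 2L, max) + padding
  dims <- pmax(2L, ceiling((hi - lo) / grid_spacing) + 1L)
  gx <- lo[1L] + (seq_len(dims[1L]) - 1) * grid_spacing
  gy <- lo[2L] + (seq_len(dims[2L]) - 1) * grid_spacing
  gz <- lo[3L] + (seq_len(dims[3L]) - 1) * grid_spacing
  grid <- cbind(rep(gx, times = dims[2L] * dims[3L]),
                rep(rep(gy, each = dims[1L]), times = dims[3L]),
                rep(gz, each = dims[1L] * dims[2L]))
  fld <- cpp_signed_distance(grid, cloud$points, cloud$normals)
  farr <- array(fld, dims)
  # the outermost layer lies beyond the padding, hence outside the cloud;
  # pin it positive so single-surfel sign errors in the far field cannot
  # leave open shells at the grid boundary
  farr[c(1L, dims[1L]), , ] <- pmax(farr[c(1L, dims[1L]), , ], grid_spacing)
  farr[, c(1L, dims[2L]), ] <- pmax(farr[, c(1L, dims[2L]), ], grid_spacing)
  farr[, , c(1L, dims[3L])] <- pmax(farr[, , c(1L, dims[3L])], grid_spacing)
  mesh <- polygonize_field(farr, origin = lo, spacing = grid_spacing)
  if (nrow(mesh$faces) == 0L)
    stop("reconstruction produced no surface; check normals and grid spacing")
  mesh <- largest_component(mesh)
  if (!is_watertight(mesh))
    stop(sprintf(paste0("reconstructed surface is not watertight ",
                        "(%d vertices, %d faces); try a finer grid_spacing ",
                        "than %g mm or more smoothing"),
                 nrow(mesh$vertices), nrow(mesh$faces), grid_spacing))
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}
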