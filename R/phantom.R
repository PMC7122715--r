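#' Synthetic two-lung phantom with a seed airway tree
#'
#' Builds a test anatomy entirely in code: two half-ellipsoid lung volumes
#' (flat faces medial, separated by a mediastinal gap) whose summed voxel
#' volume matches `total_volume` within 2%, plus a seed airway tree with a
#' trachea (generation 0) and bifurcating generations 1..`depth`. The left
#' main bronchus path from the carina to its first bifurcation is longer than
#' the right, reproducing the anatomical asymmetry used to tell the lungs
#' apart, and every distal point of the seed tree lies inside its lung.
#'
#' Proportions follow adult anatomy loosely: craniocaudal semi-axis 1.85x
#' and anteroposterior 1.35x the lateral semi-axis, 30 mm mediastinal gap,
#' ~100 mm trachea. The mask is labelled 1 (right) / 2 (left); the left lung
#' lies on the +x side.
#'
#' @param total_volume total lung volume in litres, in (0.5, 10].
#' @param spacing isotropic voxel spacing in mm (default 2).
#' @param depth deepest seed-tree generation (default 3, i.e. trachea + 3
#'   bifurcating generations, 2^(depth+1) - 1 branches).
#' @return List with `mask` (a [voxel_image] labelled 0/1/2) and `tree`
#'   (an [airway_tree]).
#' @export
make_phantom <- function(total_volume = 6, spacing = 2, depth = 3) {
  stopifnot_scalar_num(total_volume, "total_volume")
  if (total_volume <= 0.5 || total_volume > 10)
    stop("'total_volume' must be in (0.5, 10] litres")
  if (depth < 1L || depth > 4L) stop("'depth' must be in 1..4")
  vmm <- total_volume * 1e6
  gap <- 30
  # half-ellipsoid volume (2/3) pi a b c per lung, b = 1.35 a, c = 1.85 a
  a <- (vmm / 2 * 3 / (2 * pi * 1.35 * 1.85))^(1 / 3)
  b <- 1.35 * a
  c_ax <- 1.85 * a
  cx <- gap / 2 + 0  # |x| of each lung's flat (medial) face / ellipsoid centre
  margin <- 2 * spacing
  xr <- c(-(cx + a) - margin, cx + a + margin)
  yr <- c(-b - margin, b + margin)
  zr <- c(-c_ax - margin, c_ax + margin)
  dims <- ceiling(c(diff(xr), diff(yr), diff(zr)) / spacing)
  origin <- c(xr[1L], yr[1L], zr[1L]) + spacing / 2
  xs <- origin[1L] + (seq_len(dims[1L]) - 1) * spacing
  ys <- origin[2L] + (seq_len(dims[2L]) - 1) * spacing
  zs <- origin[3L] + (seq_len(dims[3L]) - 1) * spacing
  lab <- array(0L, dims)
  # vectorized over x-slices to keep memory flat
  e2 <- outer((ys / b)^2, (zs / c_ax)^2, "+")
  for (i in seq_len(dims[1L])) {
    x <- xs[i]
    if (x <= -cx) {            # right lung: centre (-cx,0,0), keep x <= -cx
      inside <- ((x + cx) / a)^2 + e2 <= 1
      if (any(inside)) {
        sl <- lab[i, , ]; sl[inside] <- 1L; lab[i, , ] <- sl
      }
    } else if (x >= cx) {      # left lung: centre (+cx,0,0), keep x >= cx
      inside <- ((x - cx) / a)^2 + e2 <= 1
      if (any(inside)) {
        sl <- lab[i, , ]; sl[inside] <- 2L; lab[i, , ] <- sl
      }
    }
  }
  vol <- sum(lab > 0L) * spacing^3
  if (abs(vol - vmm) / vmm > 0.02)
    stop(sprintf(paste0("voxelized volume %.3f L deviates more than 2%% from ",
                        "requested %.3f L; use a finer spacing than %g mm"),
                 vol / 1e6, total_volume, spacing))
  mask <- voxel_image(lab, rep(spacing, 3L), origin)
  tree <- phantom_seed_tree(mask, a, b, c_ax, cx, depth)
  list(mask = mask, tree = tree)
}

# Seed tree in fractional ellipsoid coordinates: f = (f_lat, f_y, f_z) maps
# to world (sign * (cx + f_lat * a), f_y * b, f_z * c). f_lat >= 0 keeps
# points on the lung side of the medial cut; |f| < 1 keeps them inside.
phantom_seed_tree <- function(mask, a, b, c_ax, cx, depth) {
  to_world <- function(f, side) c(side * (cx + f[1L] * a), f[2L] * b, f[3L] * c_ax)
  carina <- c(0, 0, 0.55 * c_ax)
  inlet <- carina + c(0, 0, 100)
  branches <- list(data.frame(id = 1L, parent = NA_integer_, generation = 0L,
                              length = 100, diameter = NA_real_))
  polys <- list(rbind(inlet, carina))
  # main bronchi: left (+x, side 2) deliberately longer than right
  ends <- list(`1` = c(0.28, 0, 0.46), `2` = c(0.34, 0, 0.36))
  queue <- list()
  nid <- 1L
  for (side_lab in c(1L, 2L)) {
    side <- if (side_lab == 1L) -1 else 1
    f <- ends[[as.character(side_lab)]]
    p <- to_world(f, side)
    nid <- nid + 1L
    branches[[nid]] <- data.frame(id = nid, parent = 1L, generation = 1L,
                                  length = vec_norm(p - carina),
                                  diameter = NA_real_)
    polys[[nid]] <- rbind(carina, p)
    queue[[length(queue) + 1L]] <- list(id = nid, f = f, side = side, gen = 1L)
  }
  # recursive bifurcation in fractional coordinates; split axis alternates
  # z (lobar) then y (anterior/posterior), offsets shrink with depth
  while (length(queue)) {
    s <- queue[[1L]]
    queue <- queue[-1L]
    if (s$gen >= depth) next
    step <- 0.5^(s$gen - 1L)
    if (s$gen %% 2L == 1L) {
      d1 <- c(0.16, 0.06, 0.26) * step
      d2 <- c(0.20, -0.06, -0.30) * step
    } else {
      d1 <- c(0.12, 0.26, 0.06) * step
      d2 <- c(0.14, -0.26, -0.04) * step
    }
    for (dlt in list(d1, d2)) {
      f <- s$f + dlt
      f[1L] <- max(f[1L], 0.06)
      r <- sqrt(sum(f^2))
      if (r > 0.88) f <- f * (0.88 / r)
      p0 <- to_world(s$f, s$side)
      p1 <- to_world(f, s$side)
      nid <- nid + 1L
      branches[[nid]] <- data.frame(id = nid, parent = s$id,
                                    generation = s$gen + 1L,
                                    length = vec_norm(p1 - p0),
                                    diameter = NA_real_)
      polys[[nid]] <- rbind(p0, p1)
      queue[[length(queue) + 1L]] <- list(id = nid, f = f, side = s$side,
                                          gen = s$gen + 1L)
    }
  }
  tree <- airway_tree(do.call(rbind, branches), polys)
  dist_pts <- all_distal_points(tree)
  term <- distal_branches(tree)
  inside <- value_at_world(mask, dist_pts[term, , drop = FALSE]) > 0
  if (!all(inside))
    stop("internal error: phantom seed tree has distal points outside the mask")
  tree
}
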