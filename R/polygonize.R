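# Iso-surface polygonization of a scalar field on a regular grid by
# marching tetrahedra: each cube is split into the six tetrahedra around its
# main diagonal (a decomposition whose face diagonals match between
# neighbouring cubes), each tetrahedron crossed by the level set emits one
# or two triangles, and iso-vertices are shared exactly through grid-edge
# keys, so the result is watertight whenever the level set stays inside the
# grid.

# cube vertex numbering: bit 0 = +x, bit 1 = +y, bit 2 = +z
tet_decomposition <- matrix(c(
  0L, 1L, 5L, 7L,
  0L, 5L, 4L, 7L,
  0L, 4L, 6L, 7L,
  0L, 6L, 2L, 7L,
  0L, 2L, 3L, 7L,
  0L, 3L, 1L, 7L), ncol = 4L, byrow = TRUE)

#' Polygonize the zero level set of a gridded scalar field
#'
#' @param field 3-D numeric array (negative = inside).
#' @param origin world position (mm) of grid point (1,1,1).
#' @param spacing scalar or length-3 grid step (mm).
#' @param level iso-level (default 0).
#' @return A [surface_mesh] with outward-oriented faces.
#' @keywords internal
polygonize_field <- function(field, origin = c(0, 0, 0), spacing = 1,
                             level = 0) {
  d <- dim(field)
  spacing <- rep(spacing, length.out = 3L)
  f <- as.vector(field) - level
  eps <- 1e-10 * max(abs(f), 1)
  f[f == 0] <- eps
  s <- f < 0
  n1 <- d[1L]; n12 <- d[1L] * d[2L]
  voff <- c(0L, 1L, n1, n1 + 1L, n12, n12 + 1L, n12 + n1, n12 + n1 + 1L)
  # linear ids of cube corner (i,j,k) with i<n1, j<n2, k<n3
  ci <- seq_len(n1 - 1L)
  cj <- seq_len(d[2L] - 1L)
  ck <- seq_len(d[3L] - 1L)
  cub <- as.vector(outer(outer(ci, (cj - 1L) * n1, "+"), (ck - 1L) * n12, "+"))
  # active cubes: mixed corner signs
  any_in <- rep(FALSE, length(cub)); all_in <- rep(TRUE, length(cub))
  for (o in voff) {
    sv <- s[cub + o]
    any_in <- any_in | sv
    all_in <- all_in & sv
  }
  cub <- cub[any_in & !all_in]
  if (length(cub) == 0L)
    return(surface_mesh(matrix(0, 0L, 3L), matrix(0L, 0L, 3L)))
  # collected triangles: grid-edge pairs per corner + outward reference
  tri_e <- vector("list", 0L)
  emit <- function(e1a, e1b, e2a, e2b, e3a, e3b, ref_in, ref_out) {
    tri_e[[length(tri_e) + 1L]] <<- cbind(e1a, e1b, e2a, e2b, e3a, e3b,
                                          ref_in, ref_out)
  }
  for (t in seq_len(nrow(tet_decomposition))) {
    vg <- lapply(tet_decomposition[t, ], function(v) cub + voff[v + 1L])
    sg <- lapply(vg, function(g) s[g])
    cnt <- sg[[1L]] + sg[[2L]] + sg[[3L]] + sg[[4L]]
    # one vertex separated from the other three
    for (solo in 1:4) {
      others <- setdiff(1:4, solo)
      for (solo_in in c(TRUE, FALSE)) {
        m <- if (solo_in) cnt == 1L & sg[[solo]] else cnt == 3L & !sg[[solo]]
        if (!any(m)) next
        a <- vg[[solo]][m]
        b <- vg[[others[1L]]][m]; cc <- vg[[others[2L]]][m]; dd <- vg[[others[3L]]][m]
        if (solo_in) emit(a, b, a, cc, a, dd, a, b)
        else emit(a, b, a, cc, a, dd, b, a)
      }
    }
    # two-two split: pairs (12|34), (13|24), (14|23)
    for (pr in list(c(1L, 2L), c(1L, 3L), c(1L, 4L))) {
      q <- setdiff(1:4, pr)
      m <- cnt == 2L & (sg[[pr[1L]]] == sg[[pr[2L]]]) &
           (sg[[pr[1L]]] != sg[[q[1L]]])
      if (!any(m)) next
      # inside pair (a,b), outside pair (c,d) -- swap so a,b inside
      ins <- sg[[pr[1L]]][m]
      a <- ifelse(ins, vg[[pr[1L]]][m], vg[[q[1L]]][m])
      b <- ifelse(ins, vg[[pr[2L]]][m], vg[[q[2L]]][m])
      cc <- ifelse(ins, vg[[q[1L]]][m], vg[[pr[1L]]][m])
      dd <- ifelse(ins, vg[[q[2L]]][m], vg[[pr[2L]]][m])
      # quad on edges ac, ad, bd, bc -> triangles (ac, ad, bd), (ac, bd, bc)
      emit(a, cc, a, dd, b, dd, a, cc)
      emit(a, cc, b, dd, b, cc, a, cc)
    }
  }
  tri <- do.call(rbind, tri_e)
  epairs <- rbind(tri[, 1:2], tri[, 3:4], tri[, 5:6])
  ekey <- paste(pmin(epairs[, 1L], epairs[, 2L]),
                pmax(epairs[, 1L], epairs[, 2L]))
  ufirst <- !duplicated(ekey)
  uid <- match(ekey, ekey[ufirst])
  ue <- epairs[ufirst, , drop = FALSE]
  # interpolate iso-vertices on unique grid edges
  g1 <- ue[, 1L]; g2 <- ue[, 2L]
  tt <- f[g1] / (f[g1] - f[g2])
  # keep iso-vertices strictly inside their grid edge so that vertices of
  # different edges never coincide (zero-area faces would open the surface)
  tt <- pmin(pmax(tt, 1e-3), 1 - 1e-3)
  p1 <- grid_pos(g1, d, origin, spacing)
  p2 <- grid_pos(g2, d, origin, spacing)
  verts <- p1 + tt * (p2 - p1)
  nt <- nrow(tri)
  faces <- cbind(uid[seq_len(nt)], uid[nt + seq_len(nt)], uid[2L * nt + seq_len(nt)])
  # orient: normal must point from the inside reference to the outside one
  v1 <- verts[faces[, 1L], , drop = FALSE]
  v2 <- verts[faces[, 2L], , drop = FALSE]
  v3 <- verts[faces[, 3L], , drop = FALSE]
  u <- v2 - v1; w <- v3 - v1
  nx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
  ny <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
  nz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  refv <- grid_pos(tri[, 8L], d, origin, spacing) -
          grid_pos(tri[, 7L], d, origin, spacing)
  flip <- nx * refv[, 1L] + ny * refv[, 2L] + nz * refv[, 3L] < 0
  faces[flip, ] <- faces[flip, c(1L, 3L, 2L), drop = FALSE]
  surface_mesh(verts, faces)
}

grid_pos <- function(gid, d, origin, spacing) {
  idx <- arrayInd(gid, d) - 1L
  cbind(origin[1L] + idx[, 1L] * spacing[1L],
        origin[2L] + idx[, 2L] * spacing[2L],
        origin[3L] + idx[, 3L] * spacing[3L])
}
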