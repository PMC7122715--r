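# Closed primitive meshes, used in examples and as analytic test shapes.

#' Closed cylinder and icosphere meshes
#'
#' `cylinder_mesh()` builds a closed cylinder of given radius and length
#' along +z (capped with triangle fans); `icosphere_mesh()` builds a unit
#' icosahedron subdivided `subdiv` times and projected to radius `radius`.
#' Both are watertight with outward normals.
#'
#' @param radius radius in mm.
#' @param length cylinder length in mm.
#' @param n_around vertices per ring.
#' @param n_along rings along the axis.
#' @param center length-3 world offset.
#' @return A [surface_mesh].
#' @export
cylinder_mesh <- function(radius = 1, length = 10, n_around = 32L,
                          n_along = 16L, center = c(0, 0, 0)) {
  phi <- 2 * pi * (seq_len(n_around) - 1L) / n_around
  zs <- seq(0, length, length.out = n_along + 1L)
  ring <- cbind(radius * cos(phi), radius * sin(phi))
  verts <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  nv <- n_around
  faces <- list()
  for (iz in seq_len(n_along)) {
    a <- (iz - 1L) * nv + seq_len(nv)
    b <- a %% nv + (iz - 1L) * nv + 1L   # next vertex around the ring
    a2 <- a + nv
    b2 <- b + nv
    faces[[length(faces) + 1L]] <- cbind(a, b, b2)
    faces[[length(faces) + 1L]] <- cbind(a, b2, a2)
  }
  # caps: fan around the two center vertices
  c0 <- nrow(verts) + 1L
  c1 <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, length))
  bot <- seq_len(nv)
  top <- n_along * nv + seq_len(nv)
  faces[[length(faces) + 1L]] <- cbind(c0, bot %% nv + 1L, bot)
  faces[[length(faces) + 1L]] <- cbind(c1, top, (top - n_along * nv) %% nv +
                                         1L + n_along * nv)
  m <- surface_mesh(sweep(verts, 2L, center, "+"), do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' @rdname cylinder_mesh
#' @param subdiv icosahedron subdivision levels (default 3).
#' @export
icosphere_mesh <- function(radius = 1, subdiv = 3L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v / sqrt(1 + t^2), f)
  for (s in seq_len(subdiv)) {
    nf <- nrow(mesh$faces)
    verts <- mesh$vertices
    faces <- matrix(0L, 4L * nf, 3L)
    mid_env <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      verts <<- rbind(verts, normalize(verts[a, ] + verts[b, ]))
      id <- nrow(verts)
      mid_env[[key]] <- id
      id
    }
    for (i in seq_len(nf)) {
      tr <- mesh$faces[i, ]
      ab <- midpoint(tr[1L], tr[2L])
      bc <- midpoint(tr[2L], tr[3L])
      ca <- midpoint(tr[3L], tr[1L])
      faces[4L * i - 3L, ] <- c(tr[1L], ab, ca)
      faces[4L * i - 2L, ] <- c(tr[2L], bc, ab)
      faces[4L * i - 1L, ] <- c(tr[3L], ca, bc)
      faces[4L * i, ] <- c(ab, bc, ca)
    }
    mesh <- surface_mesh(verts, faces)
  }
  m <- surface_mesh(sweep(mesh$vertices * radius, 2L, center, "+"), mesh$faces)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}
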