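#' Triangular surface mesh
#'
#' A triangulated 2-manifold surface: `vertices` is an n x 3 matrix of world
#' positions (mm) and `faces` an m x 3 integer matrix of 1-based vertex
#' indices with counter-clockwise (outward-normal) winding.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L)
    stop("unsupported element: only triangular faces are supported")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Mesh measures
#'
#' Per-face centroids, outward unit normals and areas; per-vertex one-ring
#' areas (one third of incident face area); signed enclosed volume by the
#' divergence theorem; Euler characteristic V - E + F; and a watertightness
#' test (every edge shared by exactly two faces).
#'
#' @param mesh a [surface_mesh].
#' @return See individual functions.
#' @name mesh-measures
NULL

#' @rdname mesh-measures
#' @export
face_centroids <- function(mesh) {
  (face_corner(mesh, 1L) + face_corner(mesh, 2L) + face_corner(mesh, 3L)) / 3
}

face_cross <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L); c <- face_corner(mesh, 3L)
  u <- b - a; v <- c - a
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' @rdname mesh-measures
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  n[n < 1e-300] <- 1
  cr / n
}

#' @rdname mesh-measures
#' @export
face_areas <- function(mesh) sqrt(rowSums(face_cross(mesh)^2)) / 2

#' @rdname mesh-measures
#' @export
vertex_areas <- function(mesh) {
  ar <- rep(face_areas(mesh) / 3, 3L)
  va <- numeric(nrow(mesh$vertices))
  rs <- rowsum(ar, as.vector(mesh$faces))
  va[as.integer(rownames(rs))] <- rs[, 1L]
  va
}

#' @rdname mesh-measures
#' @export
mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L); c <- face_corner(mesh, 3L)
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
      a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

mesh_edge_keys <- function(mesh) {
  e <- rbind(mesh$faces[, c(1L, 2L)], mesh$faces[, c(2L, 3L)],
             mesh$faces[, c(3L, 1L)])
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' @rdname mesh-measures
#' @export
euler_characteristic <- function(mesh) {
  nE <- length(unique(mesh_edge_keys(mesh)))
  nrow(mesh$vertices) - nE + nrow(mesh$faces)
}

#' @rdname mesh-measures
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(table(mesh_edge_keys(mesh)) == 2L)
}

# Merge coincident vertices (exact match after rounding to `digits`),
# drop degenerate faces and unreferenced vertices.
weld_vertices <- function(mesh, digits = 9L) {
  key <- paste(round(mesh$vertices[, 1L], digits),
               round(mesh$vertices[, 2L], digits),
               round(mesh$vertices[, 3L], digits))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  verts <- mesh$vertices[first, , drop = FALSE]
  faces <- matrix(newid[mesh$faces], ncol = 3L)
  deg <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
         faces[, 1L] == faces[, 3L]
  faces <- faces[!deg, , drop = FALSE]
  drop_unused_vertices(surface_mesh(verts, faces))
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(match(mesh$faces, used), ncol = 3L))
}

# Keep the connected component (faces sharing vertices) with the most faces.
largest_component <- function(mesh) {
  nf <- nrow(mesh$faces)
  if (nf == 0L) return(mesh)
  comp <- seq_len(nrow(mesh$vertices))
  # label vertices by iterative min-label propagation across faces
  repeat {
    m <- pmin(comp[mesh$faces[, 1L]], comp[mesh$faces[, 2L]], comp[mesh$faces[, 3L]])
    nc <- comp
    for (k in 1:3) {
      mn <- rowsum_min(m, mesh$faces[, k])
      nc[mn$ids] <- pmin(nc[mn$ids], mn$val)
    }
    if (identical(nc, comp)) break
    comp <- nc
  }
  fc <- comp[mesh$faces[, 1L]]
  tab <- table(fc)
  keep <- fc == as.integer(names(tab)[which.max(tab)])
  drop_unused_vertices(surface_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE]))
}

rowsum_min <- function(vals, groups) {
  o <- order(groups, vals)
  g <- groups[o]
  first <- !duplicated(g)
  list(ids = g[first], val = vals[o][first])
}
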