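# Cotangent Laplacian, constrained contraction, shape diameter function.

flat_patch <- function(n = 7) {
  xy <- expand.grid(x = 0:n, y = 0:n)
  vv <- cbind(xy$x, xy$y, 0)
  ff <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, lapply(seq_len(n), function(j) {
      a <- (j - 1L) * (n + 1L) + i
      rbind(c(a, a + 1L, a + n + 2L), c(a, a + n + 2L, a + n + 1L))
    }))))
  list(mesh = surface_mesh(vv, ff),
       interior = which(xy$x > 0 & xy$x < n & xy$y > 0 & xy$y < n))
}

test_that("Laplacian rows sum to zero and vanish on a flat patch", {
  fp <- flat_patch()
  L <- curvature_laplacian(fp$mesh)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-8)
  delta <- as.matrix(L %*% fp$mesh$vertices)
  expect_lt(max(abs(delta[fp$interior, ])), 1e-10)
})

test_that("Laplacian recovers unit-sphere curvature within 5%", {
  sp <- icosphere_mesh(radius = 1, subdiv = 4)
  expect_gte(nrow(sp$faces), 5000)
  L <- curvature_laplacian(sp)
  delta <- as.matrix(L %*% sp$vertices)
  kap <- sqrt(rowSums(delta^2)) / (4 * vertex_areas(sp))
  # valence-5 vertices of the base icosahedron carry a small one-ring-area
  # bias, so the bulk statistics carry the 5% contract
  expect_lt(abs(mean(kap) - 1), 0.05)
  expect_lt(abs(stats::median(kap) - 1), 0.05)
  expect_lt(stats::sd(kap), 0.05)
  # delta points radially inward
  align <- rowSums(delta * sp$vertices) / sqrt(rowSums(delta^2))
  expect_lt(max(align), -0.99)
})

test_that("curvature estimates are insensitive to mesh density", {
  kap_at <- function(n_around, n_along) {
    m <- cylinder_mesh(radius = 2, length = 20, n_around = n_around,
                       n_along = n_along)
    L <- curvature_laplacian(m)
    delta <- as.matrix(L %*% m$vertices)
    lat <- which(abs(sqrt(m$vertices[, 1L]^2 + m$vertices[, 2L]^2) - 2) < 1e-6 &
                   m$vertices[, 3L] > 5 & m$vertices[, 3L] < 15)
    mean(sqrt(rowSums(delta[lat, , drop = FALSE]^2)) / (4 * vertex_areas(m)[lat]))
  }
  coarse <- kap_at(24L, 12L)
  fine <- kap_at(48L, 48L)     # 8x the face count
  expect_lt(abs(fine - coarse) / coarse, 0.02)
  expect_equal(coarse, 1 / (2 * 2), tolerance = 0.02)  # kappa_H = 1/(2r)
})

test_that("degenerate triangles are clamped with a warning", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 1e-13), c(1, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)))
  expect_warning(L <- curvature_laplacian(m), "degenerate")
  expect_true(all(is.finite(as.matrix(L))))
})

test_that("a huge attachment weight freezes the mesh", {
  m <- cylinder_mesh(radius = 2, length = 10, n_around = 16, n_along = 8)
  st <- contraction_state(m, pinned = seq_len(nrow(m$vertices)),
                          pin_weight = 1e9)
  out <- contract_step(m, st)
  expect_lt(max(abs(out$mesh$vertices - m$vertices)), 1e-8)
})

test_that("contraction monotonically shrinks a closed cylinder", {
  m <- cylinder_mesh(radius = 2, length = 20, n_around = 24, n_along = 12)
  st <- contraction_state(m, k = 0.3)  # visible steps for the volume trace
  vols <- mesh_volume(m)
  for (i in 1:5) {
    s <- contract_step(m, st)
    m <- s$mesh; st <- s$state
    vols <- c(vols, mesh_volume(m))
  }
  expect_true(all(diff(vols) < 0))
})

test_that("the contraction step solves its normal equations", {
  m <- cylinder_mesh(radius = 1, length = 5, n_around = 12, n_along = 6)
  st <- contraction_state(m, k = 0.1)
  L <- curvature_laplacian(m)
  out <- contract_step(m, st)
  n <- nrow(m$vertices)
  M <- st$wl^2 * Matrix::crossprod(L) + Matrix::Diagonal(n, st$wh^2)
  resid <- M %*% out$mesh$vertices - m$vertices * st$wh^2
  expect_lt(max(abs(as.matrix(resid))), 1e-8)
})

test_that("SDF matches analytic diameters of cylinder and sphere", {
  cyl <- cylinder_mesh(radius = 2, length = 30, n_around = 48, n_along = 30)
  ctr <- face_centroids(cyl)
  lat <- which(ctr[, 3L] > 8 & ctr[, 3L] < 22 &
                 sqrt(ctr[, 1L]^2 + ctr[, 2L]^2) > 1.9)
  expect_equal(measure_sdf(cyl, lat)$aggregate, 4, tolerance = 0.05)
  expect_equal(measure_sdf(icosphere_mesh(1, 3))$aggregate, 2,
               tolerance = 0.05)
})

test_that("a zero-opening cone reduces to the axial chord", {
  cyl <- cylinder_mesh(radius = 2, length = 30, n_around = 64, n_along = 30)
  ctr <- face_centroids(cyl)
  lat <- which(ctr[, 3L] > 10 & ctr[, 3L] < 20 &
                 sqrt(ctr[, 1L]^2 + ctr[, 2L]^2) > 1.9)
  sdf <- measure_sdf(cyl, lat[1:20], cone_deg = 0, n_rays = 1L)
  # single inward ray: the chord through the section, close to the diameter
  nrm <- face_normals(cyl)[lat[1:20], , drop = FALSE]
  o <- ctr[lat[1:20], , drop = FALSE]
  expected <- vapply(seq_len(20L), function(i) {
    d <- -nrm[i, ]
    a <- d[1L]^2 + d[2L]^2
    b <- 2 * (o[i, 1L] * d[1L] + o[i, 2L] * d[2L])
    cc <- o[i, 1L]^2 + o[i, 2L]^2 - 4
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }, numeric(1L))
  expect_equal(sdf$values, expected, tolerance = 0.02)
})

test_that("open meshes with too many escaping rays raise an error", {
  fp <- flat_patch()$mesh
  expect_error(measure_sdf(fp), "missed")
})

test_that("region constriction pins the rest of the mesh", {
  cyl <- cylinder_mesh(radius = 2, length = 30, n_around = 24, n_along = 18)
  ctr <- face_centroids(cyl)
  region <- which(ctr[, 3L] > 10 & ctr[, 3L] < 20 &
                    sqrt(ctr[, 1L]^2 + ctr[, 2L]^2) > 1.9)
  out <- constrict(cyl, region, target_fraction = 0.7, max_iters = 30)
  pinned <- setdiff(seq_len(nrow(cyl$vertices)),
                    unique(as.vector(cyl$faces[region, ])))
  expect_lt(max(abs(out$vertices[pinned, ] - cyl$vertices[pinned, ])), 1e-6)
  expect_lt(attr(out, "achieved_fraction"), 0.75)
  vt <- attr(out, "volume_trace")
  expect_true(all(diff(vt) <= 1e-9))
})

test_that("a near-unity target leaves the shape nearly unchanged", {
  cyl <- cylinder_mesh(radius = 2, length = 20, n_around = 20, n_along = 10)
  ctr <- face_centroids(cyl)
  region <- which(ctr[, 3L] > 5 & ctr[, 3L] < 15 &
                    sqrt(ctr[, 1L]^2 + ctr[, 2L]^2) > 1.9)
  out <- constrict(cyl, region, target_fraction = 0.99, max_iters = 12)
  moved <- sqrt(rowSums((out$vertices - cyl$vertices)^2))
  # a 1% diameter reduction moves the wall by ~1% of the radius; allow 2%
  expect_lt(max(moved), 0.04)
  expect_gte(attr(out, "achieved_fraction"), 0.95)
})
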