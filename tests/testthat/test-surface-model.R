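# Diameter laws, tubular cloud sampling, cleanup, reconstruction.

test_that("power-law diameters take their closed-form values", {
  expect_equal(murray_diameter(18, 0), 18)
  expect_equal(murray_diameter(18, 3), 9)
  expect_equal(murray_diameter(18, 1), 18 * 2^(-1 / 3), tolerance = 1e-12)
  # log-space cross-check
  expect_equal(log(murray_diameter(18, 1)), log(18) - log(2) / 3,
               tolerance = 1e-12)
  z <- 0:12
  dz <- murray_diameter(16, z)
  expect_equal(dz[-length(dz)] / dz[-1L], rep(2^(1 / 3), 12), tolerance = 1e-12)
})

test_that("child diameters conserve the parent cross-section law", {
  kc <- suppressWarnings(kamiya_children(10, r = 8 / 6))
  expect_equal(kc$d1, 8, tolerance = 1e-12)
  expect_equal(kc$d2, 6, tolerance = 1e-12)
  expect_equal(kc$d1^2 + kc$d2^2, 100, tolerance = 1e-9)
  sym <- suppressWarnings(kamiya_children(10, r = 1))
  expect_equal(sym$d1, sym$d2)
  expect_equal(sym$d1, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(sym$theta1, sym$theta2)
})

test_that("branching angles satisfy both sine-relation equalities", {
  ang <- solve_branching_angles(10, 9, 7)
  t1 <- ang$theta1 * pi / 180; t2 <- ang$theta2 * pi / 180
  lhs <- 10^2 / sin(t1 + t2)
  expect_lt(abs(lhs - 9^2 / sin(t1)), 1e-9)
  expect_lt(abs(9^2 / sin(t1) - 7^2 / sin(t2) * (9 / 9)^2), 1e-9 * lhs)
  expect_gt(ang$theta1, ang$theta2)  # printed relation: larger child, larger angle
  # exact area conservation makes the angle triangle degenerate
  expect_error(solve_branching_angles(10, 8, 6), "no branching angles")
  expect_warning(kamiya_children(10, 8 / 6), "no branching angles")
})

test_that("diameter assignment follows generation or subtree asymmetry", {
  tr <- assign_diameters(make_full_tree(6), d0 = 16, mode = "murray")
  expect_equal(unique(tr$branches$diameter[tr$branches$generation == 6L]), 4)
  # kamiya with equal subtrees on a symmetric tree: cube-law exponent
  # reproduces the power law exactly at every generation
  trk <- assign_diameters(make_full_tree(5), d0 = 16, mode = "kamiya",
                          exponent = 3)
  trm <- assign_diameters(make_full_tree(5), d0 = 16, mode = "murray")
  expect_equal(trk$branches$diameter, trm$branches$diameter, tolerance = 1e-9)
  # area-conserving default: d0^2 = d1^2 + d2^2 at every bifurcation
  rnd <- suppressWarnings(
    assign_diameters(make_random_tree(60, 3), d0 = 12, mode = "kamiya"))
  kids <- lungtree:::children_list(rnd)
  for (i in seq_len(nrow(rnd$branches))) {
    ch <- kids[[i]]
    if (length(ch) == 2L)
      expect_lt(abs(sum(rnd$branches$diameter[ch]^2) -
                    rnd$branches$diameter[i]^2), 1e-9)
  }
  # children never exceed the parent
  nr <- !is.na(rnd$branches$parent)
  expect_true(all(rnd$branches$diameter[nr] <=
                  rnd$branches$diameter[rnd$branches$parent[nr]] + 1e-12))
  expect_error(assign_diameters(make_y_tree(), NULL), "d0")
})

test_that("tube cloud matches area, radius and normal contracts", {
  cyl <- airway_tree(data.frame(id = 1L, parent = NA_integer_,
                                generation = 0L, length = 10, diameter = 2),
                     list(rbind(c(0, 0, 0), c(0, 0, 10))))
  cl <- sample_tube_cloud(cyl, density = 60, seed = 4, cap_ends = FALSE)
  expect_equal(nrow(cl$points), 60 * pi * 2 * 10, tolerance = 0.05)
  # least-squares cylinder radius about the known axis
  rad <- sqrt(cl$points[, 1L]^2 + cl$points[, 2L]^2)
  expect_equal(mean(rad), 1, tolerance = 0.02)
  # normals unit and perpendicular to the axis
  expect_equal(max(abs(sqrt(rowSums(cl$normals^2)) - 1)), 0, tolerance = 1e-6)
  expect_lt(max(abs(cl$normals[, 3L])), 1e-6)
  expect_error(sample_tube_cloud(make_y_tree()), "diameter")
})

test_that("cleanup removes points inside other branches only", {
  # two orthogonal intersecting tubes
  cross_tree <- airway_tree(
    data.frame(id = 1:2, parent = c(NA, 1L), generation = c(0L, 1L),
               length = c(20, 20), diameter = c(3, 3)),
    list(rbind(c(-10, 0, 0), c(10, 0, 0)),
         rbind(c(0, 0, -10), c(0, 0, 10))))
  cl <- sample_tube_cloud(cross_tree, density = 30, seed = 8, cap_ends = FALSE)
  kept <- cleanup_inner_points(cl, cross_tree)
  expect_lt(nrow(kept$points), nrow(cl$points))
  # brute-force check: no survivor strictly inside the other tube
  for (i in 1:2) {
    others <- kept$branch != i
    p <- cross_tree$polylines[[i]]
    d <- lungtree:::dist_point_segment(kept$points[others, , drop = FALSE],
                                       p[1L, ], p[2L, ])
    expect_true(all(d >= 1.5 - 1e-6))
  }
  # a single branch is untouched
  solo <- airway_tree(data.frame(id = 1L, parent = NA_integer_,
                                 generation = 0L, length = 10, diameter = 2),
                      list(rbind(c(0, 0, 0), c(0, 0, 10))))
  cls <- sample_tube_cloud(solo, density = 40, seed = 1)
  expect_equal(nrow(cleanup_inner_points(cls, solo)$points), nrow(cls$points))
  # a child tube overlapping the parent near the junction loses its points
  nested <- airway_tree(
    data.frame(id = 1:2, parent = c(NA, 1L), generation = c(0L, 1L),
               length = c(20, 4), diameter = c(6, 2)),
    list(rbind(c(0, 0, 0), c(0, 0, 20)),
         rbind(c(0, 0, 20), c(0, 0, 24))))
  cln <- sample_tube_cloud(nested, density = 40, seed = 2, cap_ends = FALSE)
  inner <- cln$branch == 2L & cln$points[, 3L] < 20
  if (any(inner)) {
    keptn <- cleanup_inner_points(cln, nested)
    expect_false(any(keptn$branch == 2L & keptn$points[, 3L] < 20 - 1e-9 &
                       sqrt(keptn$points[, 1L]^2 + keptn$points[, 2L]^2) < 3 - 1e-6))
  }
})

test_that("reconstruction recovers a cylinder within 5% radial error", {
  cyl <- airway_tree(data.frame(id = 1L, parent = NA_integer_,
                                generation = 0L, length = 20, diameter = 2),
                     list(rbind(c(0, 0, 0), c(0, 0, 20))))
  cl <- sample_tube_cloud(cyl, density = 80, seed = 3)
  m <- reconstruct_surface(cl, grid_spacing = 0.3)
  expect_true(is_watertight(m))
  lat <- m$vertices[m$vertices[, 3L] > 4 & m$vertices[, 3L] < 16, , drop = FALSE]
  rad <- sqrt(lat[, 1L]^2 + lat[, 2L]^2)
  expect_lt(mean(abs(rad - 1)), 0.05)
})

test_that("a Y tree reconstructs to a closed genus-0 surface", {
  y <- assign_diameters(make_y_tree(), d0 = 4)
  cl <- cleanup_inner_points(sample_tube_cloud(y, density = 60, seed = 2), y)
  m <- reconstruct_surface(cl, grid_spacing = 0.5)
  expect_true(is_watertight(m))
  expect_equal(euler_characteristic(m), 2L)
  expect_gt(mesh_volume(m), 0)
})

test_that("normal smoothing reduces junction roughness", {
  y <- assign_diameters(make_y_tree(), d0 = 4)
  cl <- cleanup_inner_points(sample_tube_cloud(y, density = 60, seed = 6), y)
  m_raw <- reconstruct_surface(cl, grid_spacing = 0.5, smooth = 0L)
  m_smooth <- reconstruct_surface(cl, grid_spacing = 0.5, smooth = 2L)
  rough <- function(m) {
    # mean dihedral deviation across edges near the junction
    ctr <- face_centroids(m)
    near <- which(rowSums(ctr^2) < 16)
    nrm <- face_normals(m)
    e <- rbind(m$faces[near, c(1L, 2L)], m$faces[near, c(2L, 3L)],
               m$faces[near, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    fidx <- rep(near, 3L)
    first <- match(key, key)
    pair <- cbind(fidx[first], fidx)[first != seq_along(key), , drop = FALSE]
    mean(1 - rowSums(nrm[pair[, 1L], , drop = FALSE] *
                       nrm[pair[, 2L], , drop = FALSE]))
  }
  expect_lte(rough(m_smooth), rough(m_raw) + 1e-9)
})
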