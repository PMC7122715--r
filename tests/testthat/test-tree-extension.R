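# Volume-filling growth: point assignment, splitting planes, the growth loop.

test_that("points go to the nearest distal branch, ties to the lowest id", {
  y <- make_y_tree()  # distal points at (10,0,-10) and (-10,0,-10)
  st <- assign_points_to_distal(matrix(c(9, 0, -10), 1L), y)
  expect_equal(st$seeds[[which(sapply(st$seeds, function(s) length(s$idx)) > 0)]]$branch, 2L)
  # equidistant point: lowest branch id wins
  st <- assign_points_to_distal(matrix(c(0, 0, 0), 1L), y)
  got <- Filter(function(s) length(s$idx) > 0, st$seeds)
  expect_equal(got[[1L]]$branch, 2L)
})

test_that("assignment matches an exhaustive nearest-neighbour scan", {
  tr <- make_full_tree(3)
  dist_ids <- distal_branches(tr)
  dp <- all_distal_points(tr)[dist_ids, , drop = FALSE]
  set.seed(7)
  pts <- matrix(rnorm(3000, sd = 30), ncol = 3L)
  st <- assign_points_to_distal(pts, tr)
  got <- integer(nrow(pts))
  for (s in st$seeds) got[s$idx] <- s$branch
  want <- dist_ids[apply(pts, 1L, function(p)
    which.min(colSums((t(dp) - p)^2)))]
  expect_identical(got, want)
})

test_that("splitting plane is PCA-derived, centered and mirror-consistent", {
  # points along x, branch direction +z: normal parallel to x
  pts <- cbind(seq(-5, 5, by = 0.5), 0.001 * sin(1:21), 0)
  pl <- splitting_plane(pts, c(0, 0, 1))
  expect_equal(pl$point, colMeans(pts))
  expect_gt(abs(pl$normal[1L]), 1 - 1e-4)
  # mirror the cloud through the plane: the half sets swap exactly
  set.seed(1)
  cloud <- matrix(rnorm(300), ncol = 3L) %*% diag(c(4, 2, 1))
  pl <- splitting_plane(cloud, c(0, 0, 1))
  side <- (sweep(cloud, 2L, pl$point) %*% pl$normal)[, 1L]
  mirrored <- cloud - 2 * outer(side, pl$normal)
  side_m <- (sweep(mirrored, 2L, pl$point) %*% pl$normal)[, 1L]
  expect_equal(side_m, -side, tolerance = 1e-9)
  # degenerate: principal direction parallel to the branch
  expect_warning(pl <- splitting_plane(cbind(0, 0, -5:5), c(0, 0, 1)),
                 "perpendicular")
  expect_lt(abs(sum(pl$normal * c(0, 0, 1))), 1e-9)
})

test_that("growth fills the phantom and respects its contracts", {
  ph <- get_phantom(2)
  tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 4000, seed = 5)
  b <- tr$branches
  expect_gt(nrow(b), 1000)
  # generations contiguous from the seed depth
  expect_identical(sort(unique(b$generation)), seq(0L, max(b$generation)))
  # every grown distal point inside the lung mask
  term <- distal_branches(tr)
  tp <- all_distal_points(tr)[term, , drop = FALSE]
  expect_true(all(lungtree:::value_at_world(ph$mask, tp) > 0))
  # child generation = parent generation + 1
  nr <- !is.na(b$parent)
  expect_true(all(b$generation[nr] == b$generation[b$parent[nr]] + 1L))
})

test_that("growth is reproducible per seed and stable across seeds", {
  ph <- get_phantom(2)
  t1 <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000, seed = 9)
  t2 <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000, seed = 9)
  expect_identical(t1$branches, t2$branches)
  counts <- vapply(1:5, function(s) {
    tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000, seed = s)
    length(distal_branches(tr))
  }, numeric(1L))
  expect_false(all(counts == counts[1L]))
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.1)
})

test_that("an oversized terminal length stops growth after one generation", {
  ph <- get_phantom(2)
  tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 2000,
                    terminal_length_mm = 500, seed = 2)
  expect_lte(max(tr$branches$generation), max(ph$tree$branches$generation) + 1L)
})

test_that("generation cap limits depth", {
  ph <- get_phantom(2)
  tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000,
                    max_generations = 6, seed = 4)
  expect_lte(max(tr$branches$generation), 6L)
})

test_that("sibling targets lie on opposite sides of the splitting plane", {
  set.seed(3)
  pts <- matrix(rnorm(600, sd = 10), ncol = 3L)
  pl <- splitting_plane(pts, c(0, 0, 1))
  side <- (sweep(pts, 2L, pl$point) %*% pl$normal)[, 1L] > 0
  c1 <- colMeans(pts[side, , drop = FALSE])
  c2 <- colMeans(pts[!side, , drop = FALSE])
  expect_gt(sum((c1 - pl$point) * pl$normal), 0)
  expect_lt(sum((c2 - pl$point) * pl$normal), 0)
})

test_that("terminal counts grow with lung volume", {
  nt <- vapply(c(2, 4), function(v) {
    ph <- get_phantom(v)
    tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 5000, seed = 1)
    length(distal_branches(tr))
  }, numeric(1L))
  expect_gt(nt[2L], nt[1L])
})

test_that("the PCA plane suppresses long branches relative to a random plane", {
  # splitting across the direction of greatest variance keeps both halves
  # compact; random planes through the branch axis let elongated point sets
  # survive and grow long branches
  ph <- get_phantom(2)
  n0 <- nrow(ph$tree$branches)
  mean_pca <- mean_rnd <- tail_pca <- tail_rnd <- numeric(3L)
  for (s in 1:3) {
    tp <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000, seed = s,
                      plane_method = "pca")
    tr <- extend_tree(ph$mask, ph$tree, points_per_lung = 3000, seed = s,
                      plane_method = "random")
    mean_pca[s] <- mean(tp$branches$length[-seq_len(n0)])
    mean_rnd[s] <- mean(tr$branches$length[-seq_len(n0)])
    tail_pca[s] <- stats::quantile(tp$branches$length[-seq_len(n0)], 0.99)
    tail_rnd[s] <- stats::quantile(tr$branches$length[-seq_len(n0)], 0.99)
  }
  expect_gt(mean(mean_rnd), mean(mean_pca))
  expect_gt(mean(tail_rnd), mean(tail_pca))
})
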