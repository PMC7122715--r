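# Inlet detection, directed conversion, pruning, distal extraction.

test_that("inlet is the free end of the longest chain at a branching vertex", {
  # stem of 10 unit-spaced vertices into two arms of 3
  nodes <- data.frame(id = 1:16,
                      x = c(rep(0, 10), 1:3, -(1:3)), y = 0,
                      z = c(9:0, -(1:3), -(1:3)))
  edges <- data.frame(from = c(1:9, 10, 11, 12, 10, 14, 15),
                      to = c(2:10, 11, 12, 13, 14, 15, 16))
  g <- centerline_graph(nodes, edges)
  expect_identical(detect_inlet(g), 1L)
  expect_identical(detect_inlet(g), brute_force_inlet(g))
})

test_that("equal chains tie-break to the lowest terminal id", {
  # symmetric Y: three chains of equal vertex count
  nodes <- data.frame(id = 1:7, x = c(0, 0, 1, 2, -1, -2, 0),
                      y = 0, z = c(1, 0, -1, -2, -1, -2, 2))
  edges <- data.frame(from = c(1, 2, 3, 2, 5, 1), to = c(2, 3, 4, 5, 6, 7))
  g <- centerline_graph(nodes, edges)
  # chains end at ids 4, 6, 7 with equal vertex counts -> lowest wins
  expect_identical(detect_inlet(g), 4L)
})

test_that("a pure path falls back to the longer-side endpoint with a warning", {
  g <- centerline_graph(data.frame(id = 1:3, x = c(0, 1, 5), y = 0, z = 0),
                        data.frame(from = 1:2, to = 2:3))
  expect_warning(y <- detect_inlet(g), "path")
  expect_identical(y, 3L)  # longer arc side of the middle vertex
})

test_that("detect_inlet is invariant under vertex relabelling", {
  for (s in 1:10) {
    g <- make_random_centerline(s)
    y0 <- detect_inlet(g)
    pos0 <- g$nodes[match(y0, g$nodes$id), c("x", "y", "z")]
    set.seed(s + 100)
    perm <- sample.int(nrow(g$nodes))
    g2 <- centerline_graph(
      data.frame(id = perm[seq_len(nrow(g$nodes))], x = g$nodes$x,
                 y = g$nodes$y, z = g$nodes$z),
      data.frame(from = perm[g$edges$from], to = perm[g$edges$to]))
    y2 <- detect_inlet(g2)
    pos2 <- g2$nodes[match(y2, g2$nodes$id), c("x", "y", "z")]
    # same chain-length maximum: the chosen vertex is a free chain end of
    # maximal length in both labellings (position may differ only on ties)
    adj0 <- lungtree:::adjacency_list(g)
    adj2 <- lungtree:::adjacency_list(g2)
    expect_identical(lengths(adj2)[match(y2, g2$nodes$id)],
                     lengths(adj0)[match(y0, g$nodes$id)])
  }
})

test_that("to_directed builds branches, generations and arc lengths", {
  nodes <- data.frame(id = 1:6, x = c(0, 0, 0, 1, 2, -1),
                      y = c(0, 0, 1, 1, 1, 2), z = c(2, 1, 0, 0, 1, 0))
  edges <- data.frame(from = c(1, 2, 3, 4, 3), to = c(2, 3, 4, 5, 6))
  g <- centerline_graph(nodes, edges)
  tr <- to_directed(g, 1L)
  expect_equal(nrow(tr$branches), 3L)
  expect_setequal(tr$branches$generation, c(0L, 1L, 1L))
  # root branch polyline 1-2-3: arc = |(0,0,2)-(0,0,1)| + |(0,0,1)-(0,1,0)|
  root <- tr$branches$id[is.na(tr$branches$parent)]
  expect_equal(tr$branches$length[root], 1 + sqrt(2), tolerance = 1e-12)
  # child branch 3-4-5: starts at the branching vertex
  lens <- sort(tr$branches$length[-root])
  expect_equal(lens, sort(c(sqrt(2), 1 + sqrt(2))), tolerance = 1e-12)
})

test_that("full binary depth-3 centerline yields 7 branches, generations 0..2", {
  tr0 <- make_full_tree(2)
  g <- as_centerline_graph(tr0)
  tr <- to_directed(g, detect_inlet(g))
  expect_equal(nrow(tr$branches), 7L)
  expect_equal(sort(unique(tr$branches$generation)), 0:2)
  expect_equal(tabulate(tr$branches$generation + 1L), c(1L, 2L, 4L))
})

test_that("cycles are rejected", {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  edges <- data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1))
  expect_error(to_directed(centerline_graph(nodes, edges), 1L), "cycle")
})

test_that("flattening a directed tree restores vertices and edge multiset", {
  tr <- make_full_tree(3)
  g <- as_centerline_graph(tr)
  tr2 <- to_directed(g, detect_inlet(g))
  g2 <- as_centerline_graph(tr2)
  key <- function(gg) {
    pos <- round(as.matrix(gg$nodes[, c("x", "y", "z")]), 9)
    rownames(pos) <- NULL
    pos[order(pos[, 1L], pos[, 2L], pos[, 3L]), ]
  }
  expect_equal(key(g2), key(g))
  expect_equal(nrow(g2$edges), nrow(g$edges))
})

test_that("branch counts per generation never exceed 2^g", {
  for (s in 1:5) {
    tr <- make_random_tree(40, s)
    cnt <- table(tr$branches$generation)
    expect_true(all(cnt <= 2^as.integer(names(cnt))))
  }
})

test_that("prune keeps complete bifurcations and trims lone children", {
  tr <- make_full_tree(4)
  expect_equal(nrow(prune(tr, 2)$branches), 7L)
  expect_equal(nrow(prune(tr, 0)$branches), 1L)
  expect_warning(out <- prune(tr, 9), "unchanged")
  expect_equal(nrow(out$branches), nrow(tr$branches))
  # give one generation-2 branch a single generation-3 child: child trimmed
  tr2 <- make_full_tree(2)
  nb <- nrow(tr2$branches)
  g2 <- tr2$branches$id[tr2$branches$generation == 2L][1L]
  tip <- all_distal_points(tr2)[g2, ]
  tr2$branches <- rbind(tr2$branches,
                        data.frame(id = nb + 1L, parent = g2, generation = 3L,
                                   length = 5, diameter = NA_real_))
  tr2$polylines[[nb + 1L]] <- rbind(tip, tip + c(0, 0, -5))
  pruned <- prune(tr2, 3)
  expect_equal(nrow(pruned$branches), nb)
  expect_false(any(pruned$branches$generation == 3L))
})

test_that("distal branches are exactly the childless ones", {
  y <- make_y_tree()
  expect_setequal(distal_branches(y), 2:3)
  solo <- airway_tree(data.frame(id = 1L, parent = NA_integer_,
                                 generation = 0L, length = 10,
                                 diameter = NA_real_),
                      list(rbind(c(0, 0, 10), c(0, 0, 0))))
  expect_identical(distal_branches(solo), 1L)
  expect_length(distal_branches(prune(make_full_tree(4), 2)), 4L)
})

test_that("inlet detection matches the brute-force oracle on random graphs", {
  for (s in 1:30)
    expect_identical(detect_inlet(make_random_centerline(s)),
                     brute_force_inlet(make_random_centerline(s)),
                     info = paste("seed", s))
})

test_that("airway trees round-trip through JSON", {
  tr <- assign_diameters(make_full_tree(3), 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, f)
  back <- read_tree(f)
  expect_equal(back$branches, tr$branches, tolerance = 1e-12)
  expect_equal(do.call(rbind, back$polylines), do.call(rbind, tr$polylines),
               ignore_attr = TRUE, tolerance = 1e-12)
})
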