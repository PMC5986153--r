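mk_mask <- function(nr, nc, pts) {
  m <- matrix(FALSE, nr, nc)
  for (p in pts) m[p[1] + 1, p[2] + 1] <- TRUE
  m
}

test_that("edge pixel grouping partitions chains and splits junctions", {
  expect_equal(group_edge_pixels(matrix(FALSE, 10, 10)), list())

  # two disjoint horizontal segments
  m <- matrix(FALSE, 10, 20)
  m[5, 2:6] <- TRUE; m[8, 10:15] <- TRUE
  g <- group_edge_pixels(m)
  expect_length(g, 2)
  ends <- lapply(g, function(x) c(x$left[["col"]], x$right[["col"]]))
  expect_setequal(vapply(ends, paste, "", collapse = "-"), c("1-5", "9-14"))

  # T-shaped set: three chains after junction splitting, matching the
  # brute-force adjacency oracle
  tmask <- mk_mask(6, 6, list(c(0, 0), c(0, 1), c(0, 2), c(1, 1)))
  gt <- group_edge_pixels(tmask)
  expect_length(gt, oracle_chain_count(tmask))
  expect_length(gt, 3)

  # random sparse masks agree with the oracle
  octretina:::with_seed(11, {
    for (trial in 1:20) {
      m <- matrix(runif(80) < 0.25, 8, 10)
      expect_equal(length(group_edge_pixels(m)), oracle_chain_count(m))
    }
  })
})

test_that("run-collapsed grouping keeps steep chains connected", {
  # a staircase dropping 2 rows per column: pixel-mode breaks it, run mode
  # (with the 2-pixel verticals NMS would leave) keeps one chain
  m <- matrix(FALSE, 20, 6)
  for (j in 0:5) { m[2 * j + 1, j + 1] <- TRUE; m[2 * j + 2, j + 1] <- TRUE }
  expect_length(group_edge_pixels(m, collapse_runs = TRUE), 1)
})

test_that("boundary graph weights follow the stated formula", {
  W <- list(w_d = 1, w_s = 2, w_a = 5, w_p = 5)
  roi <- list(min = rep(0, 30), max = rep(29, 30))

  # single group spanning all columns: path weight = the two terminal
  # connection weights only
  g1 <- list(list(rows = rep(10L, 30), cols = 0:29,
                  left = c(row = 10, col = 0), right = c(row = 10, col = 29),
                  size = 30L))
  gr <- build_boundary_graph(g1, roi, NULL, width = 30, weights = W)
  sp <- shortest_boundary_path(gr)
  expect_equal(sp$weight, 1 + 1)

  # two collinear groups with a 3-px horizontal gap, flat reference:
  # connecting weight w_d * 3
  g2 <- list(
    list(rows = rep(10L, 10), cols = 0:9, left = c(row = 10, col = 0),
         right = c(row = 10, col = 9), size = 10L),
    list(rows = rep(10L, 10), cols = 12:21, left = c(row = 10, col = 12),
         right = c(row = 10, col = 21), size = 10L))
  gr2 <- build_boundary_graph(g2, roi, NULL, width = 30, weights = W)
  e <- gr2$edges
  expect_equal(e$w[e$from == 1 & e$to == 2], 3)

  # brute-force check of the full pairwise edge list for 4 groups with a
  # sloped reference and nonassoc scores
  octretina:::with_seed(4, {
    groups <- lapply(1:4, function(i) {
      c1 <- (i - 1) * 8; c2 <- c1 + 4
      r1 <- sample.int(20, 1); r2 <- sample.int(20, 1)
      list(rows = c(r1, r2), cols = c(c1, c2),
           left = c(row = r1, col = c1), right = c(row = r2, col = c2),
           size = 2L)
    })
    na <- runif(4)
    ref <- seq(0, 14.5, by = 0.5)
    gr4 <- build_boundary_graph(groups, roi, ref, width = 30, weights = W,
                                nonassoc = na)
    e <- gr4$edges
    for (i in 1:4) for (j in 1:4) {
      a <- groups[[i]]; b <- groups[[j]]
      dc <- b$left[["col"]] - a$right[["col"]]
      wij <- e$w[e$from == i & e$to == j]
      if (i == j || dc <= 0) { expect_length(wij, 0); next }
      dr <- b$left[["row"]] - a$right[["row"]]
      slope_ref <- (ref[b$left[["col"]] + 1] - ref[a$right[["col"]] + 1]) / dc
      cover <- length(unique(b$cols)) / 30
      expect_equal(wij, W$w_d * sqrt(dc^2 + dr^2) +
                          W$w_s * abs(dr / dc - slope_ref) +
                          W$w_a * na[j] * cover)
    }
  })
})

test_that("graphs with no group in the ROI keep a source-sink fallback", {
  gr <- build_boundary_graph(list(), roi = list(min = rep(0, 10), max = rep(9, 10)),
                             reference = NULL, width = 10)
  sp <- shortest_boundary_path(gr)
  expect_length(sp$groups, 0)
  expect_equal(sp$weight, 11)
})

test_that("shortest path equals exhaustive enumeration", {
  # hand-set 5-node graph
  edges <- data.frame(
    from = c(0, 0, 1, 1, 2, 3, 2, 4, 3, 0),
    to   = c(1, 2, 3, 4, 3, 5, 4, 5, 5, 5),
    w    = c(1, 2, 2, 4, 1, 3, 1, 1, 1, 20))
  gr <- structure(list(groups = as.list(1:4), edges = edges, n = 4L,
                       width = 10), class = "boundary_graph")
  gr$groups <- lapply(1:4, function(i) list(left = c(row = 0, col = i),
                                            right = c(row = 0, col = i)))
  sp <- shortest_boundary_path(gr)
  o <- oracle_shortest_path(gr)
  expect_equal(sp$weight, o$weight)
  expect_equal(c(0L, sp$node_ids, 5L), o$path)

  # two parallel chains, lower-weight one wins
  roi <- list(min = rep(0, 20), max = rep(30, 20))
  ch <- function(row) list(rows = rep(row, 20), cols = 0:19,
                           left = c(row = row, col = 0),
                           right = c(row = row, col = 19), size = 20L)
  gr2 <- build_boundary_graph(list(ch(5), ch(15)), roi, NULL, width = 20,
                              nonassoc = c(0.8, 0.1))
  expect_equal(shortest_boundary_path(gr2)$node_ids, 2L)

  # property: 100 random graphs with <= 12 nodes match enumeration
  octretina:::with_seed(7, {
    for (trial in 1:100) {
      gr <- random_boundary_graph(12)
      sp <- shortest_boundary_path(gr)
      o <- oracle_shortest_path(gr)
      expect_equal(sp$weight, o$weight, tolerance = 1e-9)
    }
  })
})

test_that("shrinking the ROI never adds groups", {
  octretina:::with_seed(21, {
    m <- matrix(runif(600) < 0.2, 20, 30)
    groups <- group_edge_pixels(m)
    wide <- list(min = rep(0, 30), max = rep(19, 30))
    narrow <- list(min = rep(4, 30), max = rep(14, 30))
    gw <- build_boundary_graph(groups, wide, NULL, width = 30)
    gn <- build_boundary_graph(groups, narrow, NULL, width = 30)
    expect_lte(gn$n, gw$n)
    key <- function(g) paste(g$left[["row"]], g$left[["col"]], g$size)
    expect_true(all(vapply(gn$groups, key, "") %in% vapply(gw$groups, key, "")))
  })
})

test_that("boundary reconstruction interpolates and fits", {
  ch <- function(rows, cols) list(rows = rows, cols = cols,
                                  left = c(row = rows[1], col = cols[1]),
                                  right = c(row = rows[length(rows)],
                                            col = cols[length(cols)]),
                                  size = length(rows))
  # gap-free straight chain at row 50
  p <- reconstruct_boundary(list(ch(rep(50, 20), 0:19)), 20,
                            fit = list(method = "interp", offset = 0))
  expect_equal(p, rep(50, 20))

  # 4-column interior gap on a flat line is filled at the line's row
  cols <- c(0:7, 12:19)
  p2 <- reconstruct_boundary(list(ch(rep(50, 8), 0:7), ch(rep(50, 8), 12:19)),
                             20, fit = list(method = "interp", offset = 0))
  expect_equal(p2, rep(50, 20))

  # noisy samples of a cubic: spline fit within 1 px of the generative curve
  octretina:::with_seed(3, {
    x <- 0:79
    curve <- 60 + 0.00025 * (x - 40)^3 + 8 * sin(x / 25)
    noisy <- round(curve + rnorm(80, 0, 0.5))
    p3 <- reconstruct_boundary(list(ch(noisy, x)), 80,
                               fit = list(method = "spline", offset = 0))
    expect_lt(max(abs(p3 - curve)), 1)
  })
})
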