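test_that("region graphs are symmetric, irreflexive and validate input", {
  g <- region_graph(rbind(c("A", "B"), c("B", "C"), c("C", "B")))
  expect_equal(g$n_regions, 3L)
  expect_equal(nrow(g$edge_mat), 2L)       # duplicate edge merged
  expect_equal(g$n_neighbors, c(1L, 2L, 1L))
  expect_true(g$connected)
  for (i in seq_len(g$n_regions))
    for (j in g$neighbors[[i]]) {
      expect_true(i %in% g$neighbors[[j]])
      expect_false(i == j)
    }
  expect_error(region_graph(rbind(c("A", "A"))), "self-loop")
  expect_error(region_graph(rbind(c("A", "B")), region_ids = "A"), "unknown")
  expect_error(region_graph(rbind(c("A", "B")), region_ids = c("A", "A", "B")),
               "duplicate")
})

test_that("lattice graphs have the rook edge count and are connected", {
  expect_equal(nrow(lattice_graph(1, 2)$edge_mat), 1L)
  g <- lattice_graph(3, 3)
  # oracle: explicit enumeration of rook edges on 3x3 = 2*3*(3-1)
  expect_equal(nrow(g$edge_mat), 12L)
  expect_true(g$connected)
  expect_equal(sort(unique(g$n_neighbors)), c(2L, 3L, 4L))
  # disconnected graph (extra isolated region) is detected
  gd <- region_graph(rbind(c("A", "B")), region_ids = c("A", "B", "C"))
  expect_false(gd$connected)
})

test_that("graph coloring never puts neighbors in one class", {
  for (g in list(lattice_graph(3, 4), lattice_graph(1, 5),
                 region_graph(rbind(c("A","B"), c("A","C"), c("A","D"),
                                    c("B","C"))))) {
    classes <- arealquant:::graph_coloring(g)
    col <- integer(g$n_regions)
    for (k in seq_along(classes)) col[classes[[k]]] <- k
    for (ei in seq_len(nrow(g$edge_mat)))
      expect_false(col[g$edge_mat[ei, 1]] == col[g$edge_mat[ei, 2]])
  }
})

test_that("edge-list and GAL encodings of the same map read identically", {
  g0 <- lattice_graph(2, 3)
  ef <- withr::local_tempfile(fileext = ".txt")
  write_adjacency(g0, ef)
  g1 <- read_adjacency(ef)
  expect_identical(g1$region_ids, g0$region_ids)
  expect_identical(g1$edge_mat, g0$edge_mat)
  # GAL dialect: header count, then id/degree and neighbor lines
  gal <- withr::local_tempfile(fileext = ".gal")
  lines <- as.character(g0$n_regions)
  for (i in seq_len(g0$n_regions)) {
    ids <- g0$region_ids
    lines <- c(lines,
               paste(ids[i], g0$n_neighbors[i]),
               paste(ids[g0$neighbors[[i]]], collapse = " "))
  }
  writeLines(lines, gal)
  g2 <- read_adjacency(gal)
  expect_identical(g2$region_ids, g0$region_ids)
  expect_identical(g2$neighbors, g0$neighbors)
})

test_that("GAL path graph yields the right cardinalities and warns on asymmetry", {
  gal <- withr::local_tempfile()
  writeLines(c("3", "A 1", "B", "B 2", "A C", "C 1", "B"), gal)
  g <- read_adjacency(gal, format = "gal")
  expect_equal(g$n_neighbors, c(1L, 2L, 1L))
  # one-directional listing: A names B but B does not name A
  gal2 <- withr::local_tempfile()
  writeLines(c("2", "A 1", "B", "B 0"), gal2)
  expect_warning(g2 <- read_adjacency(gal2, format = "gal"), "symmetrized")
  expect_equal(g2$n_neighbors, c(1L, 1L))
})

test_that("panel files round-trip and malformed panels are rejected row-wise", {
  y <- matrix(c(3L, 0L, 7L, 2L), 2, 2)
  e <- matrix(c(2.5, 1.0, 2.5, 1.0), 2, 2)
  X <- array(rnorm(8), c(2, 2, 2), dimnames = list(NULL, NULL, c("x1", "x2")))
  p <- panel_data(y, e, X, region_ids = c("A", "B"), times = c("1", "2"))
  expect_equal(p$n_regions, 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2$y, p$y, tolerance = 1e-12)
  expect_equal(p2$e, p$e)
  expect_equal(as.vector(p2$X), as.vector(p$X))
  expect_identical(p2$region_ids, p$region_ids)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region_id,time,count,expected",
               "A,1,3,2.5", "A,2,1,0", "B,1,0,1", "B,2,2,1"), bad)
  expect_error(read_panel(bad), "row\\(s\\): 3")
  writeLines(c("region_id,time,count,expected",
               "A,1,3,2.5", "A,1,1,2.5", "B,1,0,1", "B,2,2,1"), bad)
  expect_error(read_panel(bad), "duplicate")
  writeLines(c("region_id,time,count,expected",
               "A,1,3,2.5", "B,1,0,1", "B,2,2,1"), bad)
  expect_error(read_panel(bad), "complete")
  writeLines(c("region_id,time,count,expected",
               "A,1,-3,2.5", "A,2,1,1", "B,1,0,1", "B,2,2,1"), bad)
  expect_error(read_panel(bad), "nonnegative")
})

test_that("panel constructor enforces the count and offset domains", {
  expect_error(panel_data(matrix(-1, 1, 1), matrix(1, 1, 1)), "nonnegative")
  expect_error(panel_data(matrix(1.5, 1, 1), matrix(1, 1, 1)), "integer")
  expect_error(panel_data(matrix(1, 1, 1), matrix(0, 1, 1)), "positive")
  expect_error(panel_data(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
  # vector expected counts recycle across periods
  p <- panel_data(matrix(0L, 3, 4), c(1, 2, 3))
  expect_equal(p$e[, 4], c(1, 2, 3), ignore_attr = TRUE)
})

test_that("endemic-window standardization shares counts by population", {
  counts <- rbind(c(10, 2, 3), c(20, 1, 2))
  # window = periods 2:3, total 8 over 2 periods -> 4 cases/period shared
  # 1:3 by population
  expect_equal(expected_rates_endemic(c(100, 300), counts, 2:3), c(1, 3))
  expect_equal(expected_rates_endemic(c(50, 50), counts, 2:3), c(2, 2))
  e <- expected_rates_endemic(c(10, 70), counts, 1:2)
  expect_equal(sum(e), sum(counts[, 1:2]) / 2)   # conservation identity
  expect_error(expected_rates_endemic(c(1, 1), counts, integer(0)), "empty")
  expect_error(expected_rates_endemic(c(1, -1), counts, 1), "positive")
  expect_error(expected_rates_endemic(c(1, 1), counts, 9), "outside")
})
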