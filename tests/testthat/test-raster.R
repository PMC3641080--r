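test_that("a rectangular channel rasterises to the analytic cell block", {
  mask <- straight_mask(1000, 100, cell = 50)
  expect_equal(sum(mask$water), 40)           # 20 x 2 block
  expect_equal(dim(mask$water), c(2, 20))
  expect_equal(sum(mask$water) * (50 / 1000)^2, 0.1)  # 0.1 km2
})

test_that("refining the cell size preserves the rasterised area", {
  coarse <- straight_mask(1000, 100, cell = 50)
  fine <- straight_mask(1000, 100, cell = 25)
  expect_equal(sum(fine$water), 4 * sum(coarse$water))
  expect_equal(sum(fine$water) * (25 / 1000)^2,
               sum(coarse$water) * (50 / 1000)^2)
})

test_that("rasterised area tracks the buffered centreline area on a random river", {
  rv <- generate_river(river_spec(80, n_tributaries = 2, seed = 7))
  mask <- rasterize_river(rv)
  # oracle: channel area as centreline length x local width, summed per segment
  area_m2 <- sum(vapply(rv$branches, function(b) {
    seg <- sqrt(diff(b$x)^2 + diff(b$y)^2)
    sum(seg * (b$width[-1] + b$width[-nrow(b)]) / 2)
  }, 0))
  expect_lt(abs(sum(mask$water) * 2500 - area_m2) / area_m2, 0.10)
})

test_that("ESRI ASCII round-trips a mask exactly", {
  mask <- straight_mask(1000, 100)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(mask, path)
  back <- read_esri_ascii(path)
  expect_identical(back$water, mask$water)
  expect_equal(back$origin_x, mask$origin_x)
  expect_equal(back$cell_size_m, mask$cell_size_m)
})

test_that("graph edges and weights follow 8-connectivity geometry", {
  strip <- crocspace:::new_mask(matrix(TRUE, 1, 3), 0, 0, 50)
  g <- build_graph(strip)
  expect_equal(igraph::ecount(g$g), 2)
  expect_equal(sort(igraph::E(g$g)$weight), c(50, 50))

  block <- crocspace:::new_mask(matrix(TRUE, 2, 2), 0, 0, 50)
  g2 <- build_graph(block)
  expect_equal(igraph::ecount(g2$g), 6)
  expect_equal(sum(abs(igraph::E(g2$g)$weight - 50) < 1e-9), 4)
  expect_equal(sum(abs(igraph::E(g2$g)$weight - 50 * sqrt(2)) < 1e-9), 2)
})

test_that("disjoint water blobs are reduced to the largest with a warning", {
  w <- matrix(FALSE, 5, 9)
  w[1:2, 1:3] <- TRUE     # 6 cells
  w[4:5, 7:9] <- TRUE     # 6 cells -> tie broken by first-found; make larger
  w[4:5, 6] <- TRUE       # now 8 cells
  mask <- crocspace:::new_mask(w, 0, 0, 50)
  expect_warning(g <- build_graph(mask), "components")
  expect_equal(igraph::vcount(g$g), 8)
})

test_that("snapping returns the nearest water cell with deterministic ties", {
  mask <- straight_mask(1000, 100)
  # exactly at a cell centre
  hit <- snap_to_river(125, 75, mask)
  expect_equal(hit$snap_m, 0)
  expect_equal(c(hit$row, hit$col), c(2, 3))
  # equidistant between cells (2,3) and (2,4): lower (row, col) wins
  tie <- snap_to_river(150, 75, mask)
  expect_equal(c(tie$row, tie$col), c(2, 3))
  # a point 80 m inland of the straight bank at y = 100
  inland <- snap_to_river(525, 180, mask)
  expect_true(abs(inland$snap_m - 80) <= 50 / sqrt(2) + 1e-9)
  expect_equal(inland$row, 2)
})

test_that("shortest path distances are exact on small channels", {
  strip <- crocspace:::new_mask(matrix(TRUE, 1, 3), 0, 0, 50)
  g <- build_graph(strip)
  k <- g$cells$key
  expect_equal(river_distance(k[1], k[2], g)[1, 1], 50)
  expect_equal(river_distance(k[2], k[2], g)[1, 1], 0)
})

test_that("every pair on an L-shaped channel matches the Floyd-Warshall oracle", {
  mask <- l_mask(7)     # 13 cells <= 100
  g <- build_graph(mask)
  D_fw <- floyd_warshall_distances(mask)
  D <- river_distance(g$cells$key, g$cells$key, g)
  expect_equal(D[g$cells$key, g$cells$key], D_fw[g$cells$key, g$cells$key],
               tolerance = 1e-12)
})

test_that("halving the cell size changes straight-channel distances by < 10%", {
  m50 <- straight_mask(2000, 100, cell = 50)
  m25 <- straight_mask(2000, 100, cell = 25)
  g50 <- build_graph(m50); g25 <- build_graph(m25)
  a50 <- snap_to_river(25, 25, m50); b50 <- snap_to_river(1975, 25, m50)
  a25 <- snap_to_river(25, 25, m25); b25 <- snap_to_river(1975, 25, m25)
  d50 <- river_distance(a50$key, b50$key, g50)[1, 1]
  d25 <- river_distance(a25$key, b25$key, g25)[1, 1]
  expect_lt(abs(d50 - d25) / d50, 0.10)
})
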