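test_that("adjacency_graph enforces symmetry, no self-loops and id coverage", {
  g <- adjacency_graph(c("a", "b"), list(a = "b", b = "a"))
  expect_equal(nrow(graph_edges(g)), 1L)
  expect_error(adjacency_graph(c("a", "b"), list(a = "b")), "asymmetric")
  expect_error(adjacency_graph(c("a", "b"), list(a = "a", b = character(0))),
               "itself")
  expect_error(adjacency_graph(c("a", "b"), list(a = c("b", "z"), b = "a")),
               "unknown neighbor")
  expect_error(adjacency_graph(c("a", "a")), "duplicate")
})

test_that("GAL files round-trip through write and read", {
  g <- grid_geography(3, 4)$graph
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(g, path)
  g2 <- read_gal(path)
  expect_equal(g2$area_ids, g$area_ids)
  expect_equal(g2$neighbors, g$neighbors)
})

test_that("GAL parser handles the smallest symmetric file and isolated areas", {
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("2", "a 1", "b", "b 1", "a"), path)
  g <- read_gal(path)
  expect_equal(sort(g$area_ids), c("a", "b"))
  expect_equal(g$neighbors$a, "b")

  # isolated area written with a blank neighbor line
  writeLines(c("3", "a 1", "b", "b 1", "a", "c 0", ""), path)
  g3 <- read_gal(path)
  expect_equal(g3$neighbors$c, character(0))

  # libpysal-style header
  writeLines(c("0 2 ids unknown", "a 1", "b", "b 1", "a"), path)
  expect_equal(read_gal(path)$neighbors$a, "b")
})

test_that("one-directional GAL edges are symmetrized with a warning", {
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("2", "a 1", "b", "b 0", ""), path)
  expect_warning(g <- read_gal(path), "symmetrized")
  expect_equal(g$neighbors$b, "a")
  expect_equal(g$neighbors$a, "b")
})

test_that("malformed GAL input produces errors naming the problem line", {
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("2", "a 1", "zzz", "b 0", ""), path)
  expect_error(read_gal(path), "not declared")
  writeLines(c("junk header"), path)
  expect_error(read_gal(path), "line 1")
  writeLines(c("2", "a 3", "b b b"), path)
  expect_error(read_gal(path), "header declares 2")
  writeLines(c("2", "a 2", "b", "b 1", "a"), path)
  expect_error(read_gal(path), "declares 2 neighbors but lists 1")
})

test_that("polygon contiguity follows the queen rule", {
  # shared edge
  g <- adjacency_from_polygons(list(a = square(0, 0), b = square(1, 0)))
  expect_equal(nrow(graph_edges(g)), 1L)
  # corner contact counts under queen ...
  g <- adjacency_from_polygons(list(a = square(0, 0), b = square(1, 1)))
  expect_equal(nrow(graph_edges(g)), 1L)
  # ... but not under rook
  g <- adjacency_from_polygons(list(a = square(0, 0), b = square(1, 1)),
                               queen = FALSE)
  expect_equal(nrow(graph_edges(g)), 0L)
  # disjoint squares
  g <- adjacency_from_polygons(list(a = square(0, 0), b = square(5, 5)))
  expect_equal(nrow(graph_edges(g)), 0L)
  # error contracts
  expect_error(adjacency_from_polygons(list(square(0, 0))), "named")
  expect_error(
    adjacency_from_polygons(stats::setNames(list(square(0, 0), square(1, 0)),
                                            c("a", "a"))),
    "duplicate")
  expect_error(adjacency_from_polygons(list(a = cbind(0, 1))), "invalid polygon")
})

test_that("polygon-derived adjacency of a grid matches its rook graph when queen = FALSE", {
  gg <- grid_geography(4, 5)
  g_poly <- adjacency_from_polygons(gg$polygons, queen = FALSE)
  expect_equal(g_poly$neighbors[gg$graph$area_ids], gg$graph$neighbors)
})

test_that("grid geography has the expected area and edge counts", {
  gg <- grid_geography(2, 2)
  expect_equal(n_areas(gg$graph), 4L)
  expect_equal(nrow(graph_edges(gg$graph)), 4L)
  expect_true(all(lengths(gg$graph$neighbors) == 2L))

  expect_equal(n_areas(grid_geography(1, 1)$graph), 1L)
  expect_equal(nrow(graph_edges(grid_geography(1, 1)$graph)), 0L)

  # Halland-sized lattice
  expect_equal(n_areas(grid_geography(6, 11)$graph), 66L)

  # edge-count identity r(c-1) + c(r-1) over assorted shapes
  for (rc in list(c(1, 7), c(3, 3), c(5, 2), c(6, 11))) {
    g <- grid_geography(rc[1], rc[2])$graph
    expect_equal(nrow(graph_edges(g)),
                 rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1))
  }
  expect_error(grid_geography(0, 3), "positive")
})

test_that("connected components partition the areas", {
  expect_length(graph_components(grid_geography(2, 2)$graph), 1L)
  g2 <- adjacency_from_polygons(list(a = square(0, 0), b = square(5, 5)))
  expect_length(graph_components(g2), 2L)
  g3 <- adjacency_graph(c("x", "y", "z"))
  comps <- graph_components(g3)
  expect_length(comps, 3L)
  expect_true(all(lengths(comps) == 1L))
  expect_setequal(unlist(comps), c("x", "y", "z"))
})

test_that("GeoJSON polygons round-trip and feed contiguity", {
  gg <- grid_geography(2, 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(gg$polygons, path)
  polys <- read_geojson_polygons(path)
  expect_setequal(names(polys), gg$graph$area_ids)
  g <- adjacency_from_polygons(polys, queen = FALSE)
  expect_equal(g$neighbors[gg$graph$area_ids], gg$graph$neighbors)
})
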