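test_that("edge-list construction builds a valid symmetric binary matrix", {
  g <- graph_from_edgelist(c("A", "B", "C"), rbind(c("A", "B")),
                           warn_isolated = FALSE)
  expect_s3_class(g, "region_graph")
  expect_identical(g$region_ids, c("A", "B", "C"))
  expect_equal(g$W["A", "B"], 1)
  expect_equal(g$W["B", "A"], 1)
  expect_equal(sum(g$W), 2)
  expect_equal(unname(g$degrees), c(1, 1, 0))
  # duplicate and reversed edges collapse
  g2 <- graph_from_edgelist(c("A", "B"), rbind(c("A", "B"), c("B", "A"),
                                               c("A", "B")))
  expect_equal(sum(g2$W), 2)
})

test_that("construction invariants are enforced", {
  expect_error(graph_from_edgelist(c("A", "B"), rbind(c("A", "A"))),
               "self-edge")
  expect_error(graph_from_edgelist(c("A", "B"), rbind(c("A", "Z"))), "Z")
  expect_error(region_graph(c("A", "A"), matrix(0, 2, 2)), "duplicate")
  expect_error(region_graph(c("A", "B"), matrix(c(0, 2, 2, 0), 2)), "0 or 1")
  expect_error(region_graph(c("A", "B"), matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(region_graph(c("A", "B"), matrix(c(0, 1, 0, 0), 2)),
               "symmetric")
  expect_warning(graph_from_edgelist(c("A", "B", "C"), rbind(c("A", "B"))),
                 "isolated")
})

test_that("2x2 rook grid gives every region degree 2 (brute-force count)", {
  g <- grid_rook_graph(2, 2)
  # oracle: count neighbors directly from the cell coordinates
  cell <- expand.grid(row = 1:2, col = 1:2)
  manual <- sapply(seq_len(4), function(i) {
    sum(abs(cell$row - cell$row[i]) + abs(cell$col - cell$col[i]) == 1)
  })
  expect_equal(unname(g$degrees[match(sprintf("g%d_%d", cell$row, cell$col),
                                      g$region_ids)]), manual)
  expect_true(all(g$degrees == 2))
})

test_that("degrees always match recomputation from W", {
  for (s in 1:5) {
    g <- random_connected_graph(12, seed = s)
    expect_identical(g$degrees, rowSums(g$W))
    expect_identical(g$W, t(g$W))
    expect_true(all(diag(g$W) == 0))
  }
})

test_that("queen contiguity on a 2x2 polygon grid is the complete graph", {
  f <- grid_geojson(2)
  g <- graph_from_polygons(f, rule = "queen")
  expect_equal(n_edges(g), 6)           # corner touching counts
  gr <- graph_from_polygons(f, rule = "rook")
  expect_equal(n_edges(gr), 4)          # diagonals drop out
})

test_that("rook contiguity on a k x k grid yields 2k(k-1) edges", {
  for (k in 2:4) {
    f <- grid_geojson(k)
    g <- graph_from_polygons(f, rule = "rook")
    expect_equal(n_edges(g), 2 * k * (k - 1))
    # brute-force oracle over all cell pairs
    origins <- as.matrix(expand.grid(x = seq_len(k) - 1, y = seq_len(k) - 1))
    manual <- 0
    for (i in seq_len(k * k - 1)) for (j in seq.int(i + 1, k * k)) {
      if (sum(abs(origins[i, ] - origins[j, ])) == 1) manual <- manual + 1
    }
    expect_equal(n_edges(g), manual)
  }
})

test_that("1x3 polygon strip is a path with degrees 1,2,1", {
  f <- write_squares_geojson(cbind(0:2, 0), c("a", "b", "c"),
                             tempfile(fileext = ".geojson"))
  g <- graph_from_polygons(f, rule = "queen")
  expect_equal(unname(g$degrees), c(1, 2, 1))
})

test_that("disjoint polygons give an empty W with an isolation warning", {
  f <- write_squares_geojson(rbind(c(0, 0), c(5, 5)), c("a", "b"),
                             tempfile(fileext = ".geojson"))
  expect_warning(g <- graph_from_polygons(f), "isolated")
  expect_equal(sum(g$W), 0)
})

test_that("MultiPolygon features contribute all their parts", {
  # region "m" is two disjoint squares flanking square "c"; queen
  # contiguity must pick up contact through either part
  f <- tempfile(fileext = ".geojson")
  feats <- list(
    list(type = "Feature", properties = list(id = "m"),
         geometry = list(type = "MultiPolygon", coordinates = list(
           list(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))),
           list(list(c(2, 0), c(3, 0), c(3, 1), c(2, 1), c(2, 0)))))),
    list(type = "Feature", properties = list(id = "c"),
         geometry = list(type = "Polygon", coordinates = list(
           list(c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 0)))))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       f, auto_unbox = TRUE, digits = NA)
  g <- graph_from_polygons(f, rule = "rook")
  expect_equal(g$W["m", "c"], 1)
  expect_equal(n_edges(g), 1)
})

test_that("duplicate polygon ids are rejected", {
  f <- write_squares_geojson(rbind(c(0, 0), c(1, 0)), c("a", "a"),
                             tempfile(fileext = ".geojson"))
  expect_error(graph_from_polygons(f), "duplicate")
})

test_that("connected components partition the regions", {
  expect_length(connected_components(path_graph(3)), 1)
  empty <- region_graph(LETTERS[1:4], matrix(0, 4, 4), warn_isolated = FALSE)
  comp <- connected_components(empty)
  expect_length(comp, 4)
  expect_true(all(lengths(comp) == 1))
  two <- graph_from_edgelist(c("A", "B", "C", "D"),
                             rbind(c("A", "B"), c("C", "D")))
  comp2 <- connected_components(two)
  expect_length(comp2, 2)
  expect_setequal(unlist(comp2), c("A", "B", "C", "D"))
  # disjoint union property on random graphs
  for (s in 1:3) {
    g <- random_connected_graph(10, extra = 2, seed = s)
    comp <- connected_components(g)
    expect_setequal(unlist(comp), g$region_ids)
    expect_equal(sum(lengths(comp)), length(g$region_ids))
  }
})

test_that("edge CSV round-trips the adjacency", {
  g <- grid_rook_graph(3, 3)
  f <- tempfile(fileext = ".csv")
  write_edges_csv(g, f)
  g2 <- graph_from_edge_csv(f, region_ids = g$region_ids)
  expect_identical(g$W, g2$W)
})
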