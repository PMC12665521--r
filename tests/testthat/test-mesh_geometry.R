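test_that("flat grid subsampling gives even spacing and a Voronoi partition", {
  fx <- fix_sheet_graph()
  g <- fx$graph
  expect_gt(g$n_samples, 70)
  expect_lt(g$n_samples, 140)
  # min pairwise geodesic distance respects spacing tolerance (2 mm, tol 0.2)
  d <- g$gdist[seq_len(g$n_samples), seq_len(g$n_samples)]
  diag(d) <- Inf
  expect_gte(min(d), 1.6)
  expect_gte(g$mu_d, 0.8 * 2)
  expect_lte(g$mu_d, 1.5 * 2)
  # Voronoi cells partition all full-mesh vertices
  expect_equal(length(g$owner), nrow(fx$mesh$vertices))
  expect_true(all(g$owner >= 1 & g$owner <= g$n_samples))
  expect_equal(sum(tabulate(g$owner, g$n_samples)), nrow(fx$mesh$vertices))
})

test_that("adjacency is symmetric and neighborhoods cyclically ordered", {
  g <- fix_sheet_graph()$graph
  for (i in seq_len(g$n_nodes)) {
    for (j in g$neighbors[[i]])
      expect_true(i %in% g$neighbors[[j]])
  }
  # angle monotonicity in the tangent plane (flat sheet: z-normal)
  interior <- which(!g$is_cavity &
                    g$positions[, 1] > 4 & g$positions[, 1] < 16 &
                    g$positions[, 2] > 4 & g$positions[, 2] < 16)
  for (i in head(interior, 10)) {
    nb <- g$neighbors[[i]]
    ang <- atan2(g$positions[nb, 2] - g$positions[i, 2],
                 g$positions[nb, 1] - g$positions[i, 1])
    rot <- which.min(ang)
    ang2 <- ang[c(rot:length(ang), seq_len(rot - 1))]
    expect_true(all(diff(ang2) > 0))
  }
})

test_that("geodesic distances satisfy the triangle inequality on samples", {
  g <- fix_sheet_graph()$graph
  set.seed(1)
  k <- g$n_samples
  for (rep in 1:50) {
    ijk <- sample.int(k, 3)
    expect_lte(g$gdist[ijk[1], ijk[3]],
               g$gdist[ijk[1], ijk[2]] + g$gdist[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("boundary loops become cavity nodes at loop centroids", {
  m <- mesh_sheet(20, 20, dx = 0.5, hole_center = c(10, 10), hole_radius = 3)
  g <- subsample_mesh(m, spacing = 2)       # auto: rim excluded, hole kept
  expect_equal(sum(g$is_cavity), 1L)
  cav <- which(g$is_cavity)
  loop <- g$cavity_loops[[1]]
  expect_equal(as.numeric(g$positions[cav, ]),
               as.numeric(colMeans(m$vertices[loop, ])))
  expect_gte(length(g$neighbors[[cav]]), 3L)
  # closed surface: no cavities
  gs <- fix_sphere_graph()$graph
  expect_equal(sum(gs$is_cavity), 0L)
  expect_equal(length(fix_sphere_graph()$mesh$boundary_loops), 0L)
})

test_that("spacing below mesh resolution and bad meshes are rejected", {
  m <- mesh_sheet(10, 10, dx = 1)
  expect_error(subsample_mesh(m, spacing = 0.5), "spacing")
  # non-manifold: an edge shared by three faces
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0))
  f <- rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 5), c(1, 3, 4))
  expect_error(surface_mesh(v, f))
})

test_that("lowest-cost paths are found with lexicographic tie-breaks", {
  # unit chain a-b-c: only path
  g <- toy_graph(rbind(c(0, 0), c(1, 0), c(2, 0)), rbind(c(1, 2), c(2, 3)))
  expect_equal(geodesic_path(g, 1, 3), c(1, 2, 3))
  expect_error(geodesic_path(g, 2, 2), "differ")
  # diamond with equal costs: path through lower node id
  gd <- toy_graph(rbind(c(0, 0), c(1, 1), c(1, -1), c(2, 0)),
                  rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  expect_equal(geodesic_path(gd, 1, 4), c(1, 2, 4))
})

test_that("Dijkstra with heuristic weights matches exhaustive enumeration", {
  # 4x4 grid; phase-dependent weights
  pos <- as.matrix(expand.grid(x = 0:3, y = 0:3))
  id <- function(i, j) j * 4 + i + 1
  edges <- NULL
  for (j in 0:3) for (i in 0:3) {
    if (i < 3) edges <- rbind(edges, c(id(i, j), id(i + 1, j)))
    if (j < 3) edges <- rbind(edges, c(id(i, j), id(i, j + 1)))
  }
  g <- toy_graph(pos, edges)
  set.seed(42)
  for (rep in 1:5) {
    phi <- runif(16, -pi, pi)
    wfn <- function(i, j) {
      d <- sqrt(sum((g$positions[i, ] - g$positions[j, ])^2))
      heuristic_weight(d, phi[i], phi[j])
    }
    got <- geodesic_path(g, 1, 16, weights = wfn)
    cost_got <- sum(mapply(wfn, got[-length(got)], got[-1]))
    oracle <- all_simple_paths_cost(g, wfn, 1, 16)
    expect_equal(cost_got, oracle$cost, tolerance = 1e-12)
  }
})

test_that("paths project onto the full mesh as connected polylines", {
  fx <- fix_sheet_graph()
  g <- fx$graph
  i <- which(!g$is_cavity)[1]
  j <- g$neighbors[[i]][1]
  pl <- project_to_full_mesh(g, c(i, j))
  expect_equal(pl[1], g$sample_ids[i])
  expect_equal(pl[length(pl)], g$sample_ids[j])
  # consecutive projected vertices share a mesh edge
  ed <- aftopo:::mesh_edges(fx$mesh)$edges
  key <- paste(ed[, 1], ed[, 2])
  for (s in seq_len(length(pl) - 1)) {
    a <- min(pl[s], pl[s + 1]); b <- max(pl[s], pl[s + 1])
    expect_true(paste(a, b) %in% key)
  }
  # polyline length >= geodesic distance between endpoints
  len <- sum(sqrt(rowSums((fx$mesh$vertices[pl[-length(pl)], , drop = FALSE] -
                           fx$mesh$vertices[pl[-1], , drop = FALSE])^2)))
  expect_gte(len + 1e-9, g$gdist[i, j])
})

test_that("mesh files round-trip through PLY and read OFF/VTK", {
  m <- mesh_sheet(4, 4, dx = 1)
  tf <- tempfile(fileext = ".ply")
  write_surface_mesh(m, tf)
  m2 <- read_surface_mesh(tf)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-6)
  expect_equal(m2$faces, m$faces)
  # OFF
  to <- tempfile(fileext = ".off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), to)
  mo <- read_surface_mesh(to)
  expect_equal(nrow(mo$vertices), 3L)
  expect_equal(mo$faces, matrix(c(1L, 2L, 3L), 1))
  # VTK legacy polydata
  tv <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "tri", "ASCII", "DATASET POLYDATA",
               "POINTS 3 float", "0 0 0", "1 0 0", "0 1 0",
               "POLYGONS 1 4", "3 0 1 2"), tv)
  mv <- read_surface_mesh(tv)
  expect_equal(mv$faces, matrix(c(1L, 2L, 3L), 1))
})

test_that("graph JSON export contains nodes and ordered adjacency", {
  g <- fix_sheet_graph()$graph
  tf <- tempfile(fileext = ".json")
  graph_to_json(g, tf)
  j <- jsonlite::read_json(tf)
  expect_equal(length(j$nodes), g$n_nodes)
  expect_equal(unlist(j$nodes[[1]]$neighbors), g$neighbors[[1]])
})
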