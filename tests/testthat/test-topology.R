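test_that("jump classification follows the strict piecewise rule", {
  expect_equal(jump_sign(3.5), 1L)
  expect_equal(jump_sign(0), 0L)
  expect_equal(jump_sign(-4.0), -1L)
  expect_equal(jump_sign(c(pi, -pi)), c(0L, 0L))       # strict inequalities
  expect_equal(jump_sign(pi + 1e-9), 1L)
  expect_error(jump_sign(NaN))
})

test_that("discrete charge matches the analytic winding number", {
  g <- fix_sheet_graph()$graph
  k <- g$n_samples
  pos <- g$positions[seq_len(k), 1:2]
  centers <- rbind(c(6.2, 10.1), c(14.1, 9.8))
  charges <- c(1, -1)
  pf <- as_phase_field(matrix(analytic_phi(pos, centers, charges), 1))
  ch <- topological_charge(pf, g)
  nz <- which(ch$tc[1, ] != 0)
  expect_gt(length(nz), 0)
  # clusters: exactly one +1 and one -1, near the respective centers
  cl <- cluster_timestep(nz, sign(ch$tc[1, nz]), g)
  expect_equal(sort(vapply(cl, function(c_) c_$sign, integer(1))), c(-1L, 1L))
  expect_equal(sum(ch$tc), 0L)
  for (c_ in cl) {
    ctr <- centers[if (c_$sign > 0) 1 else 2, ]
    d <- sqrt(rowSums((g$positions[c_$members, 1:2, drop = FALSE] -
                       matrix(ctr, length(c_$members), 2, byrow = TRUE))^2))
    expect_lt(min(d), 2 * g$mu_d)
  }
  # uniform field: no charge anywhere
  pf0 <- as_phase_field(matrix(0.3, 1, k))
  expect_true(all(topological_charge(pf0, g)$tc == 0L))
})

test_that("charge equals the winding oracle on random multi-singularity fields", {
  g <- fix_sheet_graph()$graph
  k <- g$n_samples
  pos <- g$positions[seq_len(k), 1:2]
  set.seed(7)
  for (rep in 1:20) {
    ns <- sample(2:4, 1)
    centers <- cbind(runif(ns, 3, 17), runif(ns, 3, 17))
    charges <- sample(c(-1, 1), ns, replace = TRUE)
    pf <- as_phase_field(matrix(analytic_phi(pos, centers, charges), 1))
    ch <- topological_charge(pf, g)
    for (i in seq_len(k)) {
      if (g$flagged[i]) next
      nb <- g$neighbors[[i]]
      # away from cores: ring vertices at least one spacing from any center
      dmin <- min(sqrt(outer(g$positions[nb, 1], centers[, 1], "-")^2 +
                       outer(g$positions[nb, 2], centers[, 2], "-")^2))
      if (dmin < 2) next
      expect_equal(ch$tc[1, i],
                   winding_oracle(g, i, centers, charges),
                   info = sprintf("rep %d node %d", rep, i))
    }
  }
})

test_that("total index is conserved on closed surfaces", {
  fx <- fix_sphere_graph()
  g <- fx$graph
  k <- g$n_samples
  pos <- g$positions[seq_len(k), ]
  set.seed(11)
  for (rep in 1:5) {
    # azimuth field about a random axis: singular at the two (antipodal,
    # hence well-separated) axis poles, zero total winding
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    phi <- atan2(pos %*% e2, pos %*% e1)
    pf <- as_phase_field(matrix(atan2(sin(phi), cos(phi)), 1))
    ch <- topological_charge(pf, g)
    nz <- which(ch$tc[1, ] != 0)
    cl <- cluster_timestep(nz, sign(ch$tc[1, nz]), g)
    expect_equal(sum(vapply(cl, function(c_) c_$sign, integer(1))), 0L)
  }
})

test_that("cavity nodes detect anatomical reentry and conserve the total", {
  # annulus: rotating-wave field winds once around the hole
  m <- mesh_sheet(30, 30, dx = 0.5, hole_center = c(15, 15), hole_radius = 5)
  g <- subsample_mesh(m, spacing = 2, cavity_loops = "all")
  expect_equal(sum(g$is_cavity), 2L)
  pos <- g$positions[seq_len(g$n_samples), 1:2]
  pf <- as_phase_field(matrix(analytic_phi(pos, rbind(c(15, 15)), 1), 1))
  ch <- topological_charge(pf, g)
  cav <- which(g$is_cavity)
  hole <- cav[ch$tc[1, cav] != 0 & seq_along(cav) == which(
    vapply(g$cavity_loops, length, integer(1)) ==
      min(vapply(g$cavity_loops, length, integer(1))))]
  tcs <- ch$tc[1, cav]
  expect_equal(sort(tcs), c(-1L, 1L))   # hole hosts the reentry, rim its pair
  expect_equal(sum(ch$tc), 0L)
  expect_true(all(ch$tc[1, -cav] == 0L))
})

test_that("orientation flip inverts every charge", {
  fx <- fix_sheet_graph()
  m <- fx$mesh
  g <- fx$graph
  # rewind every face: same geometry, opposite surface orientation
  flipped <- surface_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  gf <- subsample_mesh(flipped, spacing = 2)
  centers <- rbind(c(6, 10), c(14, 10))
  charges <- c(1, -1)
  phi <- analytic_phi(g$positions[seq_len(g$n_samples), 1:2], centers, charges)
  ch <- topological_charge(as_phase_field(matrix(phi, 1)), g)
  phif <- analytic_phi(gf$positions[seq_len(gf$n_samples), 1:2], centers, charges)
  chf <- topological_charge(as_phase_field(matrix(phif, 1)), gf)
  expect_identical(g$sample_ids, gf$sample_ids)  # same deterministic samples
  expect_equal(chf$tc, -ch$tc)
})

test_that("masked rings are skipped whole and flagged", {
  g <- fix_sheet_graph()$graph
  k <- g$n_samples
  phi <- analytic_phi(g$positions[seq_len(k), 1:2], rbind(c(10, 10)), 1)
  phi[5] <- NA
  pf <- structure(list(phi = matrix(phi, 1), mask = matrix(!is.na(phi), 1),
                       times = 0, point_ids = seq_len(k)),
                  class = "phase_field")
  ch <- topological_charge(pf, g)
  touching <- which(vapply(g$neighbors, function(nb) 5L %in% nb, logical(1)))
  expect_true(all(ch$flagged[1, touching]))
  expect_true(all(ch$tc[1, touching] == 0L))
})

test_that("index metrics summarize the cluster-sum series", {
  m <- index_metrics(c(0, 0, 0, 0))
  expect_equal(m$f0, 1)
  expect_equal(m$m_ind, 0)
  m2 <- index_metrics(c(0, 0, 1, 0))
  expect_equal(m2$f0, 0.75)
  expect_equal(m2$m_ind, 0.25)
  expect_error(index_metrics(integer(0)), "empty")
})
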