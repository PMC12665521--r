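# synthetic charge fields on a toy line graph let every tracking rule be
# exercised with hand-computable answers
line_graph <- function(n = 30, dx = 1) {
  toy_graph(cbind(seq_len(n) * dx, 0),
            cbind(seq_len(n - 1), 2:n))
}

charge_field <- function(tc_matrix, times = seq_len(nrow(tc_matrix)) * 5) {
  structure(list(tc = tc_matrix, flagged = tc_matrix * FALSE,
                 times = as.numeric(times)), class = "charge_field")
}

test_that("spatial clustering separates signs and respects the radius", {
  g <- line_graph()                    # mu_d = 1
  # chain of 3 same-sign points one mu_d apart: a single cluster
  cl <- cluster_timestep(c(5L, 6L, 7L), c(1L, 1L, 1L), g, eps = 2)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c(5L, 6L, 7L))
  # two points 5 mu_d apart: separate clusters
  cl2 <- cluster_timestep(c(5L, 10L), c(1L, 1L), g, eps = 2)
  expect_length(cl2, 2L)
  # co-located opposite signs never merge
  cl3 <- cluster_timestep(c(5L, 5L), c(1L, -1L), g, eps = 2)
  expect_length(cl3, 2L)
  expect_setequal(vapply(cl3, function(c_) c_$sign, integer(1)), c(1L, -1L))
  # empty input: no clusters
  expect_length(cluster_timestep(integer(0), integer(0), g, eps = 2), 0L)
})

test_that("stationary clusters become one track with the right duration", {
  g <- line_graph()
  tc <- matrix(0L, 10, 30)
  tc[, 5] <- 1L
  tc[, 20] <- -1L
  tr <- track_singularities(charge_field(tc), g, eps = 2)
  expect_equal(nrow(tr$tracks), 2L)
  expect_equal(tr$tracks$duration, c(45, 45))   # 10 steps x 5 ms
  expect_equal(tr$cluster_sums, rep(0L, 10))
  expect_equal(tr$alive, rep(2L, 10))
})

test_that("a jump beyond eps kills the old track and births a new one", {
  g <- line_graph()
  tc <- matrix(0L, 6, 30)
  tc[1:3, 5] <- 1L
  tc[4:6, 25] <- 1L                     # 20 mu_d away: a different track
  tr <- track_singularities(charge_field(tc), g, eps = 2)
  expect_equal(nrow(tr$tracks), 2L)
  expect_equal(tr$tracks$birth, c(5, 20))
  expect_equal(tr$tracks$death, c(15, 30))
})

test_that("splits continue the parent and spawn a birth", {
  g <- line_graph()
  tc <- matrix(0L, 4, 30)
  tc[1:2, 10] <- 1L                     # parent
  tc[3:4, 9] <- 1L                      # nearest fragment: continuation
  tc[3:4, 14] <- 1L                     # far fragment (> eps from 10): birth
  tr <- track_singularities(charge_field(tc), g, eps = 2)
  expect_equal(nrow(tr$tracks), 2L)
  expect_equal(tr$tracks$birth, c(5, 15))
  # the parent track lives through the split
  expect_equal(tr$tracks$death[1], 20)
})

test_that("complexity metrics count tracks and simultaneous singularities", {
  g <- line_graph()
  tc <- matrix(0L, 8, 30)
  # three transient pairs overlapping in time
  tc[1:4, c(3, 8)] <- 1L;  tc[1:4, c(13, 18)] <- -1L
  tc[3:6, 23] <- 1L;       tc[3:6, 28] <- -1L
  tr <- track_singularities(charge_field(tc), g, eps = 2)
  cm <- complexity_metrics(tr)
  expect_equal(cm$summary$total_count, 6L)
  expect_equal(cm$summary$max_simultaneous, 6L)
  expect_equal(cm$summary$median_duration, median(tr$tracks$duration))
  # empty run
  tr0 <- track_singularities(charge_field(matrix(0L, 3, 30)), g, eps = 2)
  cm0 <- complexity_metrics(tr0)
  expect_equal(cm0$summary$total_count, 0L)
  expect_equal(cm0$summary$max_simultaneous, 0L)
})

test_that("track conservation ties alive counts to the cluster-sum series", {
  g <- line_graph()
  set.seed(3)
  tc <- matrix(0L, 20, 30)
  for (row in 1:20) {
    pts <- sample.int(30, sample(0:4, 1))
    tc[row, pts] <- sample(c(-1L, 1L), length(pts), replace = TRUE)
  }
  tr <- track_singularities(charge_field(tc), g, eps = 2)
  det <- tr$detections
  for (row in seq_along(tr$times)) {
    d <- det[det$time == tr$times[row], ]
    plus <- length(unique(d$track[d$sign > 0]))
    minus <- length(unique(d$track[d$sign < 0]))
    expect_equal(plus - minus, tr$cluster_sums[row])
    expect_equal(plus + minus, tr$alive[row])
  }
  # partition: every detection belongs to exactly one cluster/track
  expect_equal(nrow(det), sum(tc != 0))
})

test_that("singularity count map sums absolute charges", {
  g <- line_graph()
  tc <- matrix(0L, 100, 30)
  tc[, 5] <- 1L
  tc[, 7] <- rep(c(1L, -1L), 50)
  sc <- singularity_count_map(charge_field(tc))
  expect_equal(sc[5], 100L)
  expect_equal(sc[7], 100L)
  expect_equal(sum(sc[-c(5, 7)]), 0L)
  expect_true(all(singularity_count_map(charge_field(matrix(0L, 4, 30))) == 0L))
})

test_that("Moran's I matches a brute-force double sum and is symmetric", {
  g <- fix_sheet_graph()$graph
  k <- g$n_samples
  set.seed(9)
  x <- rnorm(k); y <- rnorm(k)
  got <- morans_i(x, y, g, R = 2)$value
  # explicit double loop
  d <- g$gdist[seq_len(k), seq_len(k)]
  acc <- 0; wsum <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    w <- exp(-d[i, j]^2 / (2 * 4))
    acc <- acc + w * (x[i] - mean(x)) * (y[j] - mean(y))
    wsum <- wsum + w
  }
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  expect_equal(got, acc / (sx * sy * wsum), tolerance = 1e-10)
  expect_equal(got, morans_i(y, x, g, R = 2)$value, tolerance = 1e-10)
  # centering invariance
  expect_equal(morans_i(x, x + 5, g)$value, morans_i(x, x, g)$value,
               tolerance = 1e-10)
  expect_error(morans_i(x, rep(1, k), g), "variance")
})

test_that("Moran's I is positive for smooth fields, negative for checkerboards", {
  g <- fix_sheet_graph()$graph
  k <- g$n_samples
  smooth <- sin(g$positions[seq_len(k), 1] / 6)
  expect_gt(morans_i(smooth, smooth, g, R = 2)$value, 0.2)
  chk <- (-1)^(round(g$positions[seq_len(k), 1] / 2) +
               round(g$positions[seq_len(k), 2] / 2))
  expect_lt(morans_i(chk, chk, g, R = 2)$value,
            morans_i(smooth, smooth, g, R = 2)$value)
  # independent random fields: near zero on average
  set.seed(21)
  vals <- replicate(30, morans_i(rnorm(k), rnorm(k), g, R = 2)$value)
  expect_lt(abs(mean(vals)), 0.05)
})
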