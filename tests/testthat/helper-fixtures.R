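# Shared fixtures and oracles, all generated in code.

# small meshes reused across files (built once per test run)
fix_env <- new.env()

fix_sheet_graph <- function() {
  if (is.null(fix_env$sheet)) {
    m <- mesh_sheet(20, 20, dx = 0.5)
    fix_env$sheet <- list(mesh = m, graph = subsample_mesh(m, spacing = 2))
  }
  fix_env$sheet
}

fix_sphere_graph <- function() {
  if (is.null(fix_env$sphere)) {
    m <- mesh_sphere(radius = 15, subdiv = 3)
    fix_env$sphere <- list(mesh = m, graph = subsample_mesh(m, spacing = 3))
  }
  fix_env$sphere
}

# analytic multi-singularity angle field: phi(p) = wrap(sum_k q_k * ang_k)
# where ang_k is the azimuth of p around center k in the plane frame
analytic_phi <- function(points, centers, charges) {
  phi <- rep(0, nrow(points))
  for (k in seq_len(nrow(centers)))
    phi <- phi + charges[k] * atan2(points[, 2] - centers[k, 2],
                                    points[, 1] - centers[k, 1])
  atan2(sin(phi), cos(phi))
}

as_phase_field <- function(phi_matrix, times = seq_len(nrow(phi_matrix)) * 5) {
  structure(list(phi = phi_matrix, mask = !is.na(phi_matrix),
                 times = as.numeric(times),
                 point_ids = seq_len(ncol(phi_matrix))),
            class = "phase_field")
}

# continuous winding-number oracle: integrate the wrapped phase increment
# along the (closed) polygon through a node's ordered neighbor positions,
# sampling each edge densely; exact for fields smooth along the polygon
winding_oracle <- function(graph, node, centers, charges, subdiv = 60) {
  nb <- graph$neighbors[[node]]
  nb <- nb[nb <= graph$n_samples]
  pts <- graph$positions[nb, 1:2, drop = FALSE]
  poly <- NULL
  for (i in seq_along(nb)) {
    a <- pts[i, ]; b <- pts[if (i == length(nb)) 1L else i + 1L, ]
    s <- seq(0, 1, length.out = subdiv + 1L)[-(subdiv + 1L)]
    poly <- rbind(poly, cbind(a[1] + s * (b[1] - a[1]),
                              a[2] + s * (b[2] - a[2])))
  }
  phi <- analytic_phi(poly, centers, charges)
  d <- diff(c(phi, phi[1]))
  as.integer(round(sum(atan2(sin(d), cos(d))) / (2 * pi)))
}

# toy sampled_graph built directly from positions + adjacency (planar, z=0)
toy_graph <- function(positions, edges) {
  n <- nrow(positions)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  pos3 <- cbind(positions, 0)
  gd <- matrix(Inf, n, n)
  diag(gd) <- 0
  for (r in seq_len(nrow(edges))) {
    d <- sqrt(sum((positions[edges[r, 1], ] - positions[edges[r, 2], ])^2))
    gd[edges[r, 1], edges[r, 2]] <- gd[edges[r, 2], edges[r, 1]] <- d
  }
  # all-pairs via Floyd-Warshall (tiny graphs only)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (gd[i, k] + gd[k, j] < gd[i, j]) gd[i, j] <- gd[i, k] + gd[k, j]
  structure(list(mesh = NULL, spacing = NA, sample_ids = seq_len(n),
                 n_samples = n, n_nodes = n, positions = pos3,
                 is_cavity = rep(FALSE, n), cavity_loops = list(),
                 neighbors = lapply(adj, function(x) sort(unique(x))),
                 flagged = rep(FALSE, n),
                 mu_d = mean(gd[edges]), gdist = gd,
                 owner = seq_len(n)), class = "sampled_graph")
}

# every simple path between two nodes (exhaustive DFS; tiny graphs only)
all_simple_paths_cost <- function(graph, wfn, src, dst) {
  best <- Inf; best_path <- NULL
  rec <- function(path, cost) {
    u <- path[length(path)]
    if (u == dst) {
      if (cost < best - 1e-12 ||
          (abs(cost - best) <= 1e-12 &&
           paste(path, collapse = ",") < paste(best_path, collapse = ","))) {
        best <<- cost; best_path <<- path
      }
      return()
    }
    for (v in graph$neighbors[[u]]) {
      if (v %in% path) next
      rec(c(path, v), cost + wfn(u, v))
    }
  }
  rec(src, 0)
  list(cost = best, path = best_path)
}

# brute-force assignment oracle over all permutations
brute_match <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) { best <- tot; best_p <- p }
  }
  list(total = best, assignment = best_p)
}

# synthetic vm trace builders
square_pulse_rec <- function(times, t_on, t_off, v_rest = -80, v_on = 20) {
  vm <- ifelse(times >= t_on & times < t_off, v_on, v_rest)
  vm_recording(times, matrix(vm, ncol = 1))
}
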