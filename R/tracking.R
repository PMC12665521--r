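#' Cluster singular points at one timestep
#'
#' Density clustering of same-chirality singular nodes with radius
#' `eps = 2 mu_d` and a minimum cluster size of one: every detection
#' belongs to a cluster, singletons included. With minimum size one this
#' is exactly the connected components of the eps-neighborhood graph
#' under geodesic distance, computed per sign so that co-located positive
#' and negative detections never merge.
#'
#' @param nodes integer node indices with nonzero charge.
#' @param signs chirality (+1/-1) per node.
#' @param graph a `sampled_graph`.
#' @param eps clustering radius in mm (default `2 * graph$mu_d`).
#' @return A list of clusters, each `list(sign, members)`.
#' @export
cluster_timestep <- function(nodes, signs, graph, eps = 2 * graph$mu_d) {
  stopifnot(length(nodes) == length(signs), eps > 0)
  out <- list()
  for (s in c(1L, -1L)) {
    sel <- nodes[signs == s]
    if (length(sel) == 0L) next
    d <- graph$gdist[sel, sel, drop = FALSE]
    a <- d <= eps
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      a, mode = "undirected", diag = FALSE))$membership
    for (cid in sort(unique(comp)))
      out[[length(out) + 1L]] <- list(sign = s, members = sel[comp == cid])
  }
  out
}

#' Track singularity clusters through time
#'
#' Clusters detections at every analyzed timestep (per chirality, radius
#' `eps`), then links clusters of the same chirality across consecutive
#' timesteps when their minimum inter-member geodesic distance is within
#' `eps`. An unlinked new cluster starts a track (birth); an unlinked old
#' track dies at its last occupied timestep. When a track splits, the
#' nearest fragment continues it and the others are births; when tracks
#' merge, the nearest (then lowest-id) track continues and the others die.
#'
#' @param charge a [topological_charge()] field.
#' @param graph the `sampled_graph` it was computed on.
#' @param eps linking/clustering radius in mm (default `2 * graph$mu_d`).
#' @return An object of class `singularity_tracks`: `tracks` (tibble: id,
#'   sign, birth, death, duration in ms), `cluster_sums` (signed cluster
#'   count sum per timestep, each cluster contributing its chirality
#'   once), `alive` (clusters alive per timestep), `detections` (tibble:
#'   time, track, sign, node), `times`.
#' @export
track_singularities <- function(charge, graph, eps = 2 * graph$mu_d) {
  stopifnot(inherits(charge, "charge_field"))
  times <- charge$times
  nt <- length(times)
  track_sign <- integer(0)
  track_birth <- numeric(0)
  track_death <- numeric(0)
  det_time <- numeric(0); det_track <- integer(0)
  det_sign <- integer(0); det_node <- integer(0)
  prev <- list()   # clusters at t-1, each with $track
  cluster_sums <- integer(nt)
  alive <- integer(nt)
  for (row in seq_len(nt)) {
    tc <- charge$tc[row, ]
    nz <- which(tc != 0L)
    cl <- cluster_timestep(nz, sign(tc[nz]), graph, eps)
    cluster_sums[row] <- sum(vapply(cl, function(c_) c_$sign, integer(1)))
    alive[row] <- length(cl)
    # candidate links: (new cluster, old cluster) same sign, min dist <= eps
    links <- NULL
    if (length(cl) && length(prev)) {
      for (i in seq_along(cl)) for (j in seq_along(prev)) {
        if (cl[[i]]$sign != prev[[j]]$sign) next
        d <- min(graph$gdist[cl[[i]]$members, prev[[j]]$members])
        if (d <= eps) links <- rbind(links, c(i, j, d))
      }
    }
    taken_new <- rep(FALSE, length(cl))
    taken_old <- rep(FALSE, length(prev))
    assigned <- integer(length(cl))
    if (!is.null(links)) {
      links <- links[order(links[, 3], links[, 1], links[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(links))) {
        i <- links[r, 1]; j <- links[r, 2]
        if (taken_new[i] || taken_old[j]) next
        assigned[i] <- prev[[j]]$track
        taken_new[i] <- TRUE; taken_old[j] <- TRUE
      }
    }
    for (i in seq_along(cl)) {
      if (assigned[i] == 0L) {
        track_sign <- c(track_sign, cl[[i]]$sign)
        track_birth <- c(track_birth, times[row])
        track_death <- c(track_death, times[row])
        assigned[i] <- length(track_sign)
      } else {
        track_death[assigned[i]] <- times[row]
      }
      cl[[i]]$track <- assigned[i]
      m <- cl[[i]]$members
      det_time <- c(det_time, rep(times[row], length(m)))
      det_track <- c(det_track, rep(assigned[i], length(m)))
      det_sign <- c(det_sign, rep(cl[[i]]$sign, length(m)))
      det_node <- c(det_node, m)
    }
    prev <- cl
  }
  tracks <- tibble::tibble(
    id = seq_along(track_sign), sign = track_sign,
    birth = track_birth, death = track_death,
    duration = track_death - track_birth)
  structure(list(tracks = tracks, cluster_sums = cluster_sums, alive = alive,
                 detections = tibble::tibble(time = det_time, track = det_track,
                                             sign = det_sign, node = det_node),
                 times = times),
            class = "singularity_tracks")
}

#' @export
print.singularity_tracks <- function(x, ...) {
  cat(sprintf("singularity_tracks: %d tracks over %d timesteps, f0 = %.4f\n",
              nrow(x$tracks), length(x$times), mean(x$cluster_sums == 0)))
  invisible(x)
}

#' Arrhythmia complexity metrics
#'
#' Per-track lifespans, the total number of distinct tracked
#' singularities, and the highest number of simultaneously alive
#' singularities (chirality pooled).
#'
#' @param tracks a [track_singularities()] result.
#' @return A list: `durations` (ms, one per track), and a tibble `summary`
#'   with `total_count`, `max_simultaneous`, `median_duration`.
#' @export
complexity_metrics <- function(tracks) {
  stopifnot(inherits(tracks, "singularity_tracks"))
  dur <- tracks$tracks$duration
  list(durations = dur,
       summary = tibble::tibble(
         total_count = nrow(tracks$tracks),
         max_simultaneous = if (length(tracks$alive)) max(tracks$alive) else 0L,
         median_duration = if (length(dur)) median(dur) else NA_real_))
}

#' Singularity count map
#'
#' Per-node total `Sc(p) = sum_t |TC(p, t)|`, ignoring rotation
#' direction: a map of where singular activity accumulated over the run.
#'
#' @param charge a [topological_charge()] field.
#' @return Integer vector, one count per graph node.
#' @export
singularity_count_map <- function(charge) {
  stopifnot(inherits(charge, "charge_field"))
  as.integer(colSums(abs(charge$tc)))
}

#' Global bivariate Moran's I with a Gaussian geodesic kernel
#'
#' Spatially weighted cross-correlation of two scalar fields on the same
#' node set: `I_M = sum_ij w_ij (x_i - xbar)(y_j - ybar) / (sx sy sum w)`
#' with `w_ij = exp(-d_ij^2 / (2 R^2))`, `w_ii = 0`, geodesic `d_ij`.
#' Used to compare singularity-count maps between runs (cross-similarity)
#' or a map with itself (self-similarity); unlike a Pearson correlation
#' it is not confined to `[-1, 1]`.
#'
#' @param x,y numeric fields over the first `length(x)` graph nodes.
#' @param graph a `sampled_graph`.
#' @param R kernel radius in mm (default 2, the sampling radius).
#' @param denom kernel denominator convention: `"2R2"` (default) for
#'   `2 R^2`, `"R2"` for `R^2`.
#' @return A tibble with `value`, `kind` (self/cross), `kernel_R`.
#' @export
morans_i <- function(x, y, graph, R = 2, denom = c("2R2", "R2")) {
  denom <- match.arg(denom)
  n <- length(x)
  stopifnot(length(y) == n, n <= graph$n_nodes)
  d <- graph$gdist[seq_len(n), seq_len(n), drop = FALSE]
  den <- if (denom == "2R2") 2 * R^2 else R^2
  w <- exp(-d^2 / den)
  diag(w) <- 0
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) stop("zero-variance field: Moran's I undefined")
  xc <- x - mean(x); yc <- y - mean(y)
  val <- as.numeric(xc %*% w %*% yc) / (sx * sy * sum(w))
  tibble::tibble(value = val,
                 kind = if (identical(x, y)) "self" else "cross",
                 kernel_R = R)
}

#' Cross-similarity of singularity maps between two runs
#'
#' Convenience wrapper: bivariate Moran's I between the singularity-count
#' maps of two pipeline runs on the same sampled graph. Comparing the
#' value with each run's self-similarity indicates whether singular
#' activity localizes by substrate (high cross-similarity) or by initial
#' condition (low).
#'
#' @param res_x,res_y two [run_pipeline()] results sharing a graph.
#' @param R kernel radius in mm.
#' @return A tibble as from [morans_i()], with `kind = "cross"`.
#' @export
morans_cross <- function(res_x, res_y, R = 2) {
  stopifnot(inherits(res_x, "pipeline_result"),
            inherits(res_y, "pipeline_result"),
            length(res_x$sc_map) == length(res_y$sc_map))
  morans_i(res_x$sc_map, res_y$sc_map, res_x$graph, R = R)
}
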