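#' Phase-aware heuristic edge weight
#'
#' Weight of a graph edge for wavefront-blocking path search: the
#' Euclidean distance between the two nodes scaled by
#' `(phi_x + 1.1 pi)(phi_y + 1.1 pi)`. Since phase lies in `[-pi, pi]`
#' the offset keeps both factors strictly positive; tissue about to be
#' activated (phase near -pi) is nearly free to cross, freshly activated
#' tissue (phase near +pi) is heavily penalized, so minimum-weight paths
#' run just ahead of the wavefront.
#'
#' @param d_euc Euclidean distance between the nodes (mm).
#' @param phi_x,phi_y phases of the two nodes (radians, in `[-pi, pi]`).
#' @return Numeric weight (mm rad^2 scale), strictly positive.
#' @examples
#' heuristic_weight(1, 0, 0)        # 1.21 pi^2
#' heuristic_weight(1, -pi, -pi)    # minimal: 0.01 pi^2
#' @export
heuristic_weight <- function(d_euc, phi_x, phi_y) {
  d_euc * (phi_x + 1.1 * pi) * (phi_y + 1.1 * pi)
}

# strategy edge-weight functions over a sampled graph at a phase snapshot;
# cavity-node edges cost 0 under the heuristic (no phase of their own,
# paths through anatomical obstacles are free)
.strategy_weight_fn <- function(graph, strategy, phi_t = NULL) {
  k <- graph$n_samples
  if (strategy == "heuristic") {
    stopifnot(!is.null(phi_t))
    function(i, j) {
      if (i > k || j > k) return(0)
      pi_i <- phi_t[i]; pi_j <- phi_t[j]
      if (is.na(pi_i) || is.na(pi_j)) return(graph$gdist[i, j] * (2.1 * pi)^2)
      d <- sqrt(sum((graph$positions[i, ] - graph$positions[j, ])^2))
      heuristic_weight(d, pi_i, pi_j)
    }
  } else {
    function(i, j) graph$gdist[i, j]
  }
}

#' Pick a balanced planning snapshot
#'
#' At the requested ablation time the signed cluster-index sum must be
#' zero so that every singularity can be paired with an opposite one. If
#' it is not (a detection hiccup), the snapshot advances by one analysis
#' timestep (5 ms) at a time, up to `max_retries`, until balance is
#' restored.
#'
#' @param charge a [topological_charge()] field.
#' @param graph the `sampled_graph`.
#' @param t requested ablation time (ms).
#' @param eps clustering radius (mm).
#' @param max_retries retry cap (default 100).
#' @return A list: `t` (possibly advanced), `t_index`, `clusters`
#'   (from [cluster_timestep()]), split into `pos` and `neg`.
#' @export
plan_snapshot <- function(charge, graph, t, eps = 2 * graph$mu_d,
                          max_retries = 100L) {
  idx <- which.min(abs(charge$times - t))
  for (try in 0:max_retries) {
    row <- idx + try
    if (row > length(charge$times))
      stop("planning failed: ran out of recording while seeking balance")
    tc <- charge$tc[row, ]
    nz <- which(tc != 0L)
    cl <- cluster_timestep(nz, sign(tc[nz]), graph, eps)
    s <- sum(vapply(cl, function(c_) c_$sign, integer(1)))
    if (s == 0L)
      return(list(t = charge$times[row], t_index = row,
                  clusters = cl,
                  pos = Filter(function(c_) c_$sign > 0, cl),
                  neg = Filter(function(c_) c_$sign < 0, cl)))
  }
  stop("planning failed: index sum never balanced within ", max_retries,
       " retries")
}

#' Minimum-total-cost pairing of opposite singularities
#'
#' Exact minimum-cost perfect matching (Hungarian algorithm) between
#' positive and negative clusters given a cost matrix; every cluster is
#' used exactly once, which is the topological prescription that no
#' singularity may be left unpaired.
#'
#' @param pos_clusters,neg_clusters cluster lists (equal length).
#' @param pairwise_costs numeric matrix, rows = positive clusters,
#'   columns = negative clusters; `Inf` marks unreachable pairs.
#' @return A tibble with `pos`, `neg`, `cost`; attribute `total`.
#' @export
match_pairs <- function(pos_clusters, neg_clusters, pairwise_costs) {
  np <- length(pos_clusters)
  if (np != length(neg_clusters))
    stop("unbalanced clusters: ", np, " positive vs ",
         length(neg_clusters), " negative")
  if (np == 0L) {
    out <- tibble::tibble(pos = integer(0), neg = integer(0), cost = numeric(0))
    attr(out, "total") <- 0
    return(out)
  }
  h <- hungarian_cpp(as.matrix(pairwise_costs))
  if (!is.finite(h$total))
    stop("planning failed: no finite-cost perfect matching")
  out <- tibble::tibble(pos = seq_len(np), neg = h$assignment + 1L,
                        cost = pairwise_costs[cbind(seq_len(np),
                                                    h$assignment + 1L)])
  attr(out, "total") <- h$total
  out
}

#' Closed conduction-block loop through a multi-point cluster
#'
#' Orders the cluster members by a nearest-neighbor tour under the active
#' strategy's weights, connects consecutive members by lowest-cost paths,
#' and closes the cycle back to the first member.
#'
#' @param cluster a cluster (`list(sign, members)`) with >= 2 members.
#' @param graph a `sampled_graph`.
#' @param weight_fn edge-weight function (or `NULL` for geodesic).
#' @param drop_node optional node excluded from path search (outer rim).
#' @return Integer node polyline (closed: first node repeated at end).
#' @export
cluster_loop <- function(cluster, graph, weight_fn = NULL,
                         drop_node = NA_integer_) {
  m <- cluster$members
  if (length(m) < 2L) stop("loop needs >= 2 cluster members")
  csr <- graph_csr(graph, weight_fn, drop_node = drop_node)
  dmat <- matrix(Inf, length(m), length(m))
  for (i in seq_along(m)) {
    d <- dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                           as.integer(m[i] - 1L))
    dmat[i, ] <- d[m]
  }
  tour <- 1L
  left <- setdiff(seq_along(m), tour)
  while (length(left)) {
    last <- tour[length(tour)]
    nxt <- left[which.min(dmat[last, left])]
    tour <- c(tour, nxt)
    left <- setdiff(left, nxt)
  }
  nodes <- m[tour]
  out <- nodes[1]
  for (i in seq_along(nodes)) {
    a <- nodes[i]; b <- nodes[if (i == length(nodes)) 1L else i + 1L]
    if (a == b) next
    seg <- dijkstra_path_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                             as.integer(a - 1L), as.integer(b - 1L)) + 1L
    if (length(seg) == 0L) stop("no path between loop members")
    out <- c(out, seg[-1])
  }
  out
}

#' Plan virtual ablation lines for one snapshot
#'
#' Builds an ablation plan under one of three strategies. `"heuristic"`
#' weighs edges by [heuristic_weight()] at the snapshot's phases (frozen
#' at the adjusted ablation time), `"straight"` uses geodesic distance on
#' the sampled graph, and `"random"` replaces each straight pair by a
#' random sample-pair drawn from the same geodesic-distance decile (so
#' control lines have comparable lengths but arbitrary placement).
#' Multi-member clusters additionally receive a closed block loop through
#' all members. Pairing always uses exact minimum-total-cost matching.
#'
#' @param graph a `sampled_graph`.
#' @param charge a [topological_charge()] field.
#' @param phase the matching [sawtooth_phase()] field.
#' @param t ablation time (ms); advanced in 5 ms steps if unbalanced.
#' @param strategy `"heuristic"`, `"straight"` or `"random"`.
#' @param seed integer seed (random strategy only).
#' @param eps clustering radius (mm).
#' @return An object of class `ablation_plan`: `strategy`, `t_abl`,
#'   `pairs` (tibble: pos, neg, src, dst, cost), `loops`, `lines` (node
#'   polylines), `lines_full` (full-mesh vertex polylines),
#'   `block_vertices` (unique full-mesh vertices to block).
#' @export
plan_ablation <- function(graph, charge, phase, t,
                          strategy = c("heuristic", "straight", "random"),
                          seed = 1L, eps = 2 * graph$mu_d) {
  strategy <- match.arg(strategy)
  snap <- plan_snapshot(charge, graph, t, eps)
  base_strategy <- if (strategy == "heuristic") "heuristic" else "straight"
  # charge may cover a sub-window of the phase series: align by time
  phase_row <- match(snap$t, phase$times)
  if (is.na(phase_row)) stop("phase series does not cover the snapshot time")
  phi_t <- phase$phi[phase_row, ]
  wfn <- .strategy_weight_fn(graph, base_strategy, phi_t)

  pos <- snap$pos; neg <- snap$neg
  n <- length(pos)
  if (n == 0L) {
    plan <- structure(list(strategy = strategy, t_abl = snap$t,
                           pairs = tibble::tibble(pos = integer(0), neg = integer(0),
                                                  src = integer(0), dst = integer(0),
                                                  cost = numeric(0)),
                           loops = list(), lines = list(),
                           lines_full = list(), block_vertices = integer(0)),
                      class = "ablation_plan")
    return(plan)
  }

  # the outer rim (if counted) is endpoint-only: drop its edges from the
  # search graph and reach it through its nearest neighbor instead, so
  # lines may end on the boundary but never pass through the outside
  rim <- graph$rim %||% NA_integer_
  csr <- graph_csr(graph, wfn, drop_node = rim)
  rim_nb <- if (!is.na(rim)) graph$neighbors[[rim]] else integer(0)
  dist_from <- function(m) {
    if (!is.na(rim) && m == rim)
      dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                        as.integer(rim_nb - 1L))
    else
      dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w, as.integer(m - 1L))
  }
  cost_to <- function(d, node) {
    if (!is.na(rim) && node == rim) {
      b <- rim_nb[which.min(d[rim_nb])]
      c(d[b], b)
    } else c(d[node], node)
  }
  cost <- matrix(Inf, n, n)
  src <- matrix(NA_integer_, n, n); dst <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    for (mem in pos[[i]]$members) {
      d <- dist_from(mem)
      for (j in seq_len(n)) {
        for (tgt in neg[[j]]$members) {
          ct <- cost_to(d, tgt)
          if (ct[1] < cost[i, j]) {
            cost[i, j] <- ct[1]
            src[i, j] <- mem
            dst[i, j] <- tgt
          }
        }
      }
    }
  }
  pairing <- match_pairs(pos, neg, cost)
  pairing$src <- src[cbind(pairing$pos, pairing$neg)]
  pairing$dst <- dst[cbind(pairing$pos, pairing$neg)]

  path_rim_aware <- function(csr_, a, b) {
    if (!is.na(rim) && a == rim) {
      d <- dijkstra_dist_cpp(csr_$n, csr_$ptr, csr_$idx, csr_$w,
                             as.integer(b - 1L))
      nb <- rim_nb[which.min(d[rim_nb])]
      p <- dijkstra_path_cpp(csr_$n, csr_$ptr, csr_$idx, csr_$w,
                             as.integer(nb - 1L), as.integer(b - 1L)) + 1L
      return(c(rim, p))
    }
    if (!is.na(rim) && b == rim) {
      d <- dijkstra_dist_cpp(csr_$n, csr_$ptr, csr_$idx, csr_$w,
                             as.integer(a - 1L))
      nb <- rim_nb[which.min(d[rim_nb])]
      p <- dijkstra_path_cpp(csr_$n, csr_$ptr, csr_$idx, csr_$w,
                             as.integer(a - 1L), as.integer(nb - 1L)) + 1L
      return(c(p, rim))
    }
    dijkstra_path_cpp(csr_$n, csr_$ptr, csr_$idx, csr_$w,
                      as.integer(a - 1L), as.integer(b - 1L)) + 1L
  }

  lines <- vector("list", nrow(pairing))
  if (strategy == "random") {
    rp <- .random_pairs(graph, pairing$cost, seed)
    pairing$src <- rp[, 1]
    pairing$dst <- rp[, 2]
    pairing$cost <- graph$gdist[rp]
    csr_geo <- graph_csr(graph, NULL, drop_node = rim)
    for (r in seq_len(nrow(pairing)))
      lines[[r]] <- path_rim_aware(csr_geo, pairing$src[r], pairing$dst[r])
    loops <- list()
  } else {
    for (r in seq_len(nrow(pairing)))
      lines[[r]] <- path_rim_aware(csr, pairing$src[r], pairing$dst[r])
    # block loops around multi-point clusters (the rim needs none: it is
    # already non-conductive)
    drop_rim <- function(m) if (is.na(rim)) m else setdiff(m, rim)
    multi <- Filter(function(c_) length(drop_rim(c_$members)) > 1L,
                    c(pos, neg))
    loops <- lapply(multi, function(c_) {
      c_$members <- drop_rim(c_$members)
      cluster_loop(c_, graph, wfn, drop_node = rim)
    })
  }
  all_paths <- c(lines, loops)
  lines_full <- lapply(all_paths, function(p) project_to_full_mesh(graph, p))
  structure(list(strategy = strategy, t_abl = snap$t, pairs = pairing,
                 loops = loops, lines = lines, lines_full = lines_full,
                 block_vertices = sort(unique(unlist(lines_full)))),
            class = "ablation_plan")
}

#' @export
print.ablation_plan <- function(x, ...) {
  cat(sprintf("ablation_plan (%s) at t = %g ms: %d pair(s), %d loop(s), %d blocked vertices\n",
              x$strategy, x$t_abl, nrow(x$pairs), length(x$loops),
              length(x$block_vertices)))
  invisible(x)
}

# draw a random sample pair from the same geodesic-distance decile as each
# reference pair distance; empty deciles widen to adjacent ones
.random_pairs <- function(graph, ref_dists, seed) {
  k <- graph$n_samples
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  d <- graph$gdist[idx]
  # reference distances measured in geodesic terms for binning
  edges <- quantile(d, probs = seq(0, 1, 0.1), names = FALSE, type = 7)
  bin <- function(x) max(1L, min(10L, findInterval(x, edges,
                                                  rightmost.closed = TRUE)))
  pair_bin <- vapply(d, bin, integer(1))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- matrix(NA_integer_, length(ref_dists), 2)
  for (r in seq_along(ref_dists)) {
    b <- bin(ref_dists[r])
    cand <- which(pair_bin == b)
    widen <- 1L
    while (length(cand) == 0L && widen < 10L) {
      message("empty distance decile ", b, "; widening to adjacent deciles")
      cand <- which(pair_bin >= b - widen & pair_bin <= b + widen)
      widen <- widen + 1L
    }
    pick <- cand[sample.int(length(cand), 1L)]
    out[r, ] <- c(idx[pick, 1], idx[pick, 2])
  }
  out
}

#' Export an ablation plan to JSON (and optionally VTK polylines)
#'
#' @param plan an [plan_ablation()] result.
#' @param path output JSON path.
#' @param vtk_path optional legacy-VTK polyline file for visualization.
#' @param graph the `sampled_graph` (needed for VTK coordinates).
#' @return `path`, invisibly.
#' @export
plan_to_json <- function(plan, path, vtk_path = NULL, graph = NULL) {
  obj <- list(strategy = plan$strategy, t_abl = plan$t_abl,
              pairs = plan$pairs,
              lines = lapply(plan$lines, as.integer),
              loops = lapply(plan$loops, as.integer),
              lines_full = lapply(plan$lines_full, as.integer))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  if (!is.null(vtk_path)) {
    stopifnot(!is.null(graph))
    v <- graph$mesh$vertices
    polys <- plan$lines_full
    con <- file(vtk_path, "w")
    on.exit(close(con))
    used <- sort(unique(unlist(polys)))
    remap <- match(seq_len(nrow(v)), used)
    writeLines(c("# vtk DataFile Version 3.0", "ablation polylines", "ASCII",
                 "DATASET POLYDATA", paste("POINTS", length(used), "float")), con)
    writeLines(apply(v[used, , drop = FALSE], 1, paste, collapse = " "), con)
    sizes <- vapply(polys, length, integer(1))
    writeLines(paste("LINES", length(polys), sum(sizes + 1L)), con)
    for (p in polys)
      writeLines(paste(length(p), paste(remap[p] - 1L, collapse = " ")), con)
  }
  invisible(path)
}

#' Classify a virtual-ablation outcome
#'
#' Implements the three outcome branches for ablation at `t_abl` with an
#' evaluation window ending at `t_end = t_abl + window`, given a possible
#' spontaneous termination time `t_sp` of the unablated run and the
#' ablation-induced termination time `t_ai` observed in the ablated run:
#' if the arrhythmia had already stopped (`t_sp < t_abl`) no ablation is
#' performed; if the spontaneous termination lies beyond the window,
#' success means `t_abl < t_ai < t_end`; if it falls inside the window,
#' the ablation must beat it by at least one recording step
#' (`t_ai <= t_sp - step`).
#'
#' @param t_abl ablation time (ms).
#' @param t_ai ablation-induced termination time (ms) or `NA`.
#' @param t_sp spontaneous termination time (ms) or `NA`.
#' @param window evaluation window (ms, default 400).
#' @param step outcome recording step (ms, default 10).
#' @return A tibble: `t_abl`, `t_end`, `t_sp`, `t_ai`, `performed`,
#'   `success`.
#' @export
evaluate_outcome <- function(t_abl, t_ai = NA_real_, t_sp = NA_real_,
                             window = 400, step = 10) {
  t_end <- t_abl + window
  if (!is.na(t_sp) && t_sp < t_abl) {
    return(tibble::tibble(t_abl = t_abl, t_end = t_end, t_sp = t_sp,
                          t_ai = NA_real_, performed = FALSE, success = NA))
  }
  success <-
    if (is.na(t_sp) || t_end < t_sp) {
      !is.na(t_ai) && t_ai > t_abl && t_ai < t_end
    } else {
      !is.na(t_ai) && t_ai > t_abl && t_ai <= t_sp - step
    }
  tibble::tibble(t_abl = t_abl, t_end = t_end, t_sp = t_sp, t_ai = t_ai,
                 performed = TRUE, success = success)
}
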