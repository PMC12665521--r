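#' Subsample a surface mesh into a geodesic Voronoi neighbor graph
#'
#' Reduces a full-resolution mesh to approximately even-spaced sample
#' points (farthest-point sampling on geodesic distance), assigns every
#' full-mesh vertex to its nearest sample (geodesic Voronoi cells), and
#' connects samples whose Voronoi cells share at least one full-mesh edge.
#' One synthetic node is added at the centroid of each anatomical cavity
#' (interior boundary loop); its neighbors are the samples whose Voronoi
#' cells touch the cavity rim. Neighbor lists are cyclically ordered
#' counterclockwise as seen from outside the surface, which is what the
#' phase-jump counting in [topological_charge()] requires.
#'
#' @param mesh a [surface_mesh()].
#' @param spacing target sample spacing in mm (default 2).
#' @param start index of the seed vertex for farthest-point sampling
#'   (deterministic given `start`).
#' @param cavity_loops which boundary loops are anatomical cavities:
#'   `"auto"` (all loops except the longest one when the surface is open
#'   -- the longest is taken to be an outer rim), `"all"`, `"none"`, or an
#'   integer vector of loop indices.
#' @return An object of class `sampled_graph`: sample vertex ids,
#'   positions, cyclically ordered neighbor lists, cavity flags, the mean
#'   neighbor distance `mu_d`, the pairwise geodesic distance matrix
#'   `gdist` (mm) over all nodes, and the Voronoi assignment of full-mesh
#'   vertices.
#' @examples
#' g <- subsample_mesh(mesh_sheet(20, 20, dx = 1), spacing = 3)
#' g$mu_d
#' @export
subsample_mesh <- function(mesh, spacing = 2, start = 1L,
                           cavity_loops = "auto") {
  stopifnot(inherits(mesh, "surface_mesh"))
  csr <- mesh_csr(mesh)
  mean_edge <- mean(mesh_edges(mesh)$lengths)
  if (spacing <= mean_edge)
    stop("spacing (", spacing, " mm) must exceed the mean mesh edge length (",
         signif(mean_edge, 3), " mm)")
  fps <- fps_cpp(csr$n, csr$ptr, csr$idx, csr$w, as.integer(start - 1L), spacing)
  sample_ids <- fps$samples + 1L
  owner <- fps$owner + 1L          # full-mesh vertex -> sample index (1..k)
  k <- length(sample_ids)

  loops <- mesh$boundary_loops
  cav_idx <- .select_cavity_loops(loops, cavity_loops)
  ncav <- length(cav_idx)
  nn <- k + ncav

  pos <- matrix(NA_real_, nn, 3)
  pos[seq_len(k), ] <- mesh$vertices[sample_ids, , drop = FALSE]
  for (c_ in seq_along(cav_idx))
    pos[k + c_, ] <- colMeans(mesh$vertices[loops[[cav_idx[c_]]], , drop = FALSE])

  # adjacency: Voronoi cells sharing >= 1 full-mesh edge
  ed <- mesh_edges(mesh)$edges
  ou <- owner[ed[, 1]]; ov <- owner[ed[, 2]]
  pairs <- unique(cbind(pmin(ou, ov), pmax(ou, ov))[ou != ov, , drop = FALSE])
  adj <- vector("list", nn)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cavity_loop_list <- vector("list", ncav)
  for (c_ in seq_along(cav_idx)) {
    lv <- loops[[cav_idx[c_]]]
    cavity_loop_list[[c_]] <- lv
    nbrs <- sort(unique(owner[lv]))
    adj[[k + c_]] <- nbrs
    for (s in nbrs) adj[[s]] <- c(adj[[s]], k + c_)
  }

  # geodesic distances: samples via per-sample Dijkstra on the full mesh;
  # cavity nodes via multi-source Dijkstra from their rim vertices
  gd <- matrix(NA_real_, nn, nn)
  for (i in seq_len(k)) {
    d <- dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                           as.integer(sample_ids[i] - 1L))
    gd[i, seq_len(k)] <- d[sample_ids]
  }
  gd[seq_len(k), seq_len(k)] <- (gd[seq_len(k), seq_len(k)] +
                                 t(gd[seq_len(k), seq_len(k)])) / 2
  for (c_ in seq_along(cav_idx)) {
    lv <- loops[[cav_idx[c_]]]
    d <- dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                           as.integer(lv - 1L))
    gd[k + c_, seq_len(k)] <- d[sample_ids]
    gd[seq_len(k), k + c_] <- d[sample_ids]
  }
  if (ncav > 1) {
    for (a in seq_len(ncav - 1)) for (b in (a + 1):ncav) {
      lv <- cavity_loop_list[[b]]
      d <- dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                             as.integer(cavity_loop_list[[a]] - 1L))
      gd[k + a, k + b] <- gd[k + b, k + a] <- min(d[lv])
    }
  }
  diag(gd) <- 0

  sample_pairs <- pairs
  mu_d <- mean(gd[sample_pairs])

  # the outer rim of an open surface, when counted as a boundary node, is
  # flagged: it may host charge and terminate ablation lines, but unlike a
  # small anatomical hole it cannot be crossed by one
  rim <- NA_integer_
  if (ncav > 0) {
    longest <- which.max(lengths(loops))
    hit <- match(longest, cav_idx)
    # a loop carrying most of the boundary is an outer rim, not a hole
    if (!is.na(hit) && lengths(loops)[longest] > sum(lengths(loops)) / 2)
      rim <- k + hit
  }
  g <- structure(list(
    mesh = mesh, spacing = spacing, sample_ids = sample_ids,
    n_samples = k, n_nodes = nn, positions = pos,
    is_cavity = c(rep(FALSE, k), rep(TRUE, ncav)),
    cavity_loops = cavity_loop_list,
    neighbors = lapply(adj, function(x) sort(unique(x))),
    flagged = rep(FALSE, nn),
    rim = rim,
    mu_d = mu_d, gdist = gd, owner = owner), class = "sampled_graph")
  order_neighbors(g, mesh)
}

.select_cavity_loops <- function(loops, cavity_loops) {
  if (is.numeric(cavity_loops)) return(as.integer(cavity_loops))
  switch(cavity_loops,
    all = seq_along(loops),
    none = integer(0),
    auto = if (length(loops) == 0L) integer(0) else
      seq_along(loops)[-which.max(lengths(loops))],
    stop("unknown cavity_loops specification"))
}

#' @export
print.sampled_graph <- function(x, ...) {
  cat(sprintf(paste0("sampled_graph: %d samples + %d cavity node(s), ",
                     "mu_d = %.2f mm (target spacing %.1f mm)\n"),
              x$n_samples, x$n_nodes - x$n_samples, x$mu_d, x$spacing))
  invisible(x)
}

#' Cyclically order every node's neighbors counterclockwise
#'
#' Neighbors are projected onto the tangent plane of the node's outward
#' normal (from the face winding) and sorted by angle; the resulting cyclic
#' order is counterclockwise as seen from outside the surface. Nodes whose
#' normal is degenerate are flagged and excluded from singularity
#' detection. Called by [subsample_mesh()]; exposed for re-ordering after
#' manual graph edits.
#'
#' @param graph a `sampled_graph`.
#' @param mesh the full-resolution [surface_mesh()].
#' @return The graph with ordered neighbor lists (deterministic: starting
#'   neighbor is the one with the smallest signed angle).
#' @export
order_neighbors <- function(graph, mesh = graph$mesh) {
  vn <- vertex_normals(mesh)
  k <- graph$n_samples
  normals <- matrix(NA_real_, graph$n_nodes, 3)
  normals[seq_len(k), ] <- vn[graph$sample_ids, , drop = FALSE]
  for (c_ in seq_len(graph$n_nodes - k)) {
    nv <- vn[graph$cavity_loops[[c_]], , drop = FALSE]
    m <- colMeans(nv, na.rm = TRUE)
    normals[k + c_, ] <- m / sqrt(sum(m^2))
  }
  for (i in seq_len(graph$n_nodes)) {
    nb <- graph$neighbors[[i]]
    if (length(nb) < 2L) next
    n <- normals[i, ]
    if (anyNA(n)) { graph$flagged[i] <- TRUE; next }
    # deterministic tangent frame
    ref <- c(1, 0, 0)
    if (abs(sum(ref * n)) > 0.9) ref <- c(0, 1, 0)
    e1 <- ref - sum(ref * n) * n
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    d <- graph$positions[nb, , drop = FALSE] -
      matrix(graph$positions[i, ], length(nb), 3, byrow = TRUE)
    ang <- atan2(d %*% e2, d %*% e1)
    ord <- nb[order(ang, nb)]
    if (i > k) {
      # A cavity node stands for the cap that would close this boundary;
      # its ring must run opposite to the boundary-loop orientation (an
      # interior hole, whose loop runs clockwise around it, keeps the
      # counterclockwise ring; an outer rim gets the reversed ring).
      lv <- graph$cavity_loops[[i - k]]
      lp <- mesh$vertices[lv, , drop = FALSE] -
        matrix(graph$positions[i, ], length(lv), 3, byrow = TRUE)
      la <- atan2(lp %*% e2, lp %*% e1)
      winding <- sum(wrap_angle(diff(c(la, la[1]))))
      if (winding > 0) ord <- rev(ord)
    }
    graph$neighbors[[i]] <- ord
  }
  graph
}

# CSR over sampled-graph nodes; edge weights from a function(i, j) or the
# geodesic distance by default; drop_node removes all edges touching one
# node (used to make the outer rim endpoint-only in path searches)
graph_csr <- function(graph, weight_fn = NULL, drop_node = NA_integer_) {
  nn <- graph$n_nodes
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nn)) {
    nb <- graph$neighbors[[i]]
    from <- c(from, rep.int(i, length(nb)))
    to <- c(to, nb)
  }
  if (!is.na(drop_node)) {
    keep <- from != drop_node & to != drop_node
    from <- from[keep]; to <- to[keep]
  }
  w <- if (is.null(weight_fn)) graph$gdist[cbind(from, to)] else
    mapply(weight_fn, from, to)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = nn)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), w = as.numeric(w),
       n = nn)
}

#' Lowest-cost path between two nodes of a sampled graph
#'
#' Dijkstra over the neighbor graph with user-supplied edge weights. Ties
#' between equal-cost paths are broken lexicographically by node id, so
#' results are deterministic.
#'
#' @param graph a `sampled_graph`.
#' @param src,dst node indices (cavity nodes allowed).
#' @param weights `NULL` for geodesic edge lengths, or a function
#'   `f(i, j)` returning the weight of edge i--j.
#' @return Integer vector of node indices from `src` to `dst`.
#' @export
geodesic_path <- function(graph, src, dst, weights = NULL) {
  if (src == dst) stop("src and dst must differ")
  csr <- graph_csr(graph, weights)
  p <- dijkstra_path_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                         as.integer(src - 1L), as.integer(dst - 1L))
  if (length(p) == 0L) stop("no path between nodes ", src, " and ", dst)
  p + 1L
}

#' Project a sampled-graph path back onto the full mesh
#'
#' Consecutive samples are joined by geodesic (Dijkstra) shortest paths on
#' the full-resolution edge graph. A cavity node on the path is realised on
#' the cavity rim: the segment enters at the rim vertex nearest the
#' preceding sample, follows the shorter rim arc, and leaves at the rim
#' vertex nearest the following sample.
#'
#' @param graph a `sampled_graph`.
#' @param path integer vector of node indices (consecutive nodes adjacent).
#' @return Integer vector of full-mesh vertex ids forming a connected
#'   polyline.
#' @export
project_to_full_mesh <- function(graph, path) {
  mesh <- graph$mesh
  csr <- mesh_csr(mesh)
  k <- graph$n_samples
  # realise each path node as one or more full-mesh vertices
  anchor <- function(node, ref_vertex) {
    if (node <= k) return(graph$sample_ids[node])
    lv <- graph$cavity_loops[[node - k]]
    d <- dijkstra_dist_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                           as.integer(ref_vertex - 1L))
    lv[which.min(d[lv])]
  }
  out <- integer(0)
  prev_v <- NULL
  for (s in seq_along(path)) {
    node <- path[s]
    if (node <= k) {
      v <- graph$sample_ids[node]
      if (is.null(prev_v)) out <- v
      else {
        seg <- dijkstra_path_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                                 as.integer(prev_v - 1L), as.integer(v - 1L)) + 1L
        out <- c(out, seg[-1])
      }
      prev_v <- v
    } else {
      lv <- graph$cavity_loops[[node - k]]
      vin <- anchor(node, if (is.null(prev_v)) graph$sample_ids[path[s + 1L]] else prev_v)
      if (!is.null(prev_v)) {
        seg <- dijkstra_path_cpp(csr$n, csr$ptr, csr$idx, csr$w,
                                 as.integer(prev_v - 1L), as.integer(vin - 1L)) + 1L
        out <- c(out, seg[-1])
      } else out <- vin
      prev_v <- vin
      if (s < length(path)) {
        # exit vertex nearest the next sample, reached along the rim
        nxt <- path[s + 1L]
        ref <- if (nxt <= k) graph$sample_ids[nxt] else vin
        vout <- anchor(node, ref)
        if (vout != vin) {
          i1 <- match(vin, lv); i2 <- match(vout, lv)
          nlv <- length(lv)
          fwd <- if (i2 >= i1) lv[i1:i2] else lv[c(i1:nlv, 1:i2)]
          bwd <- if (i1 >= i2) lv[i1:i2] else lv[c(i1:1, nlv:i2)]
          arc <- if (length(fwd) <= length(bwd)) fwd else bwd
          out <- c(out, arc[-1])
          prev_v <- vout
        }
      }
    }
  }
  out
}

#' Export a sampled graph to JSON
#'
#' Nodes (positions, cavity flags, ordered adjacency, 1-based ids) plus
#' `mu_d` and the target spacing, written with jsonlite.
#'
#' @param graph a `sampled_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
graph_to_json <- function(graph, path) {
  obj <- list(
    spacing = graph$spacing, mu_d = graph$mu_d,
    nodes = lapply(seq_len(graph$n_nodes), function(i) list(
      id = i,
      position = as.numeric(graph$positions[i, ]),
      cavity = graph$is_cavity[i],
      neighbors = as.integer(graph$neighbors[[i]]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
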