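#' Sign of a phase jump
#'
#' The discrete contribution of one phase difference to the winding count:
#' -1 for differences below -pi, +1 above +pi, 0 otherwise (strict
#' inequalities; a difference of exactly pi does not count).
#'
#' @param delta_phi phase difference(s) in radians.
#' @return Integer vector in \{-1, 0, +1\}.
#' @examples
#' jump_sign(c(3.5, 0, -4))
#' @export
jump_sign <- function(delta_phi) {
  stopifnot(all(is.finite(delta_phi)))
  as.integer(sign(delta_phi) * (abs(delta_phi) > pi))
}

#' Topological charge at every node for one timestep
#'
#' The discrete winding number: for each node, phase differences between
#' consecutive members of its cyclically ordered neighbor ring (closed,
#' last back to first) are classified by [jump_sign()] and summed. A
#' counterclockwise jump adds +1, a clockwise jump -1; charges of
#' magnitude above one are possible and preserved. Cavity nodes carry no
#' phase themselves but are evaluated identically through their ring of
#' phase-bearing neighbors, which is what lets anatomical reentries be
#' detected like functional ones. Neighbors without phase (cavity nodes)
#' are dropped from the ring; if any remaining ring member is masked the
#' whole ring is skipped (charge 0, flagged), because partial rings break
#' the integer quantization of the winding count.
#'
#' @param phase a [sawtooth_phase()] field over the graph's samples.
#' @param graph a `sampled_graph` with ordered neighbors.
#' @param t_index timestep index into `phase$times`, or `NULL` for all.
#' @return An object of class `charge_field`: integer matrix `tc`
#'   (timesteps x nodes), logical `flagged` of the same shape, `times`.
#' @export
topological_charge <- function(phase, graph, t_index = NULL) {
  stopifnot(inherits(phase, "phase_field"), inherits(graph, "sampled_graph"))
  k <- graph$n_samples
  if (ncol(phase$phi) != k)
    stop("phase field must cover the graph's ", k, " samples")
  ti <- t_index %||% seq_along(phase$times)
  nt <- length(ti)
  tc <- matrix(0L, nt, graph$n_nodes)
  fl <- matrix(FALSE, nt, graph$n_nodes)
  rings <- lapply(seq_len(graph$n_nodes), function(i) {
    r <- graph$neighbors[[i]]
    r[r <= k]                       # cavity neighbors carry no phase
  })
  for (row in seq_len(nt)) {
    ph <- phase$phi[ti[row], ]
    for (i in seq_len(graph$n_nodes)) {
      ring <- rings[[i]]
      if (graph$flagged[i] || length(ring) < 3L) { fl[row, i] <- TRUE; next }
      pr <- ph[ring]
      if (anyNA(pr)) { fl[row, i] <- TRUE; next }
      # difference taken against the counterclockwise traversal so that the
      # jump count equals the continuous winding number (a CCW-increasing
      # field wraps by -2 pi along the ring; counting it with reversed sign
      # yields +1)
      d <- c(pr, pr[1])
      tc[row, i] <- sum(jump_sign(d[-length(d)] - d[-1]))
    }
  }
  structure(list(tc = tc, flagged = fl, times = phase$times[ti]),
            class = "charge_field")
}

#' Index-theorem adherence metrics
#'
#' From the per-timestep signed sum of cluster indices: `f0` is the
#' fraction of analyzed timesteps on which the sum is zero, and `m_ind`
#' the time-mean of the signed sum. On a closed surface the index theorem
#' demands a zero sum at all times, so `f0` near 1 and `m_ind` near 0
#' measure how well detection and clustering adhere to it.
#'
#' @param cluster_sums integer vector, signed cluster-index sum per
#'   analyzed timestep.
#' @return A tibble with `f0`, `m_ind`, `n_timesteps`.
#' @examples
#' index_metrics(c(0, 0, 1, 0))
#' @export
index_metrics <- function(cluster_sums) {
  if (length(cluster_sums) == 0L) stop("empty analysis span")
  tibble::tibble(f0 = mean(cluster_sums == 0),
                 m_ind = mean(cluster_sums),
                 n_timesteps = length(cluster_sums))
}
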