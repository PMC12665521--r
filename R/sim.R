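#' Remodeling variants of the Courtemanche atrial cell
#'
#' Conductance scale factors applied to the baseline human atrial model:
#' the AF-remodeled variant halves the ultra-rapid delayed rectifier
#' (G_Kur) and transient outward (G_to) conductances and reduces the
#' L-type calcium conductance (G_CaL) by 70%; the fibrotic variant
#' instead reduces G_CaL by 50% and additionally the fast sodium
#' conductance (G_Na) by 30%, which slows conduction.
#'
#' @param variant `"af"`, `"fibrotic"` or `"baseline"`.
#' @return Named numeric vector of multipliers `(g_kur, g_to, g_cal, g_na)`.
#' @examples
#' remodeling_params("af")
#' @export
remodeling_params <- function(variant = c("af", "fibrotic", "baseline")) {
  variant <- match.arg(variant)
  switch(variant,
    af = c(g_kur = 0.5, g_to = 0.5, g_cal = 0.3, g_na = 1.0),
    fibrotic = c(g_kur = 0.5, g_to = 0.5, g_cal = 0.5, g_na = 0.7),
    baseline = c(g_kur = 1.0, g_to = 1.0, g_cal = 1.0, g_na = 1.0))
}

.as_scales <- function(params) {
  if (is.character(params)) params <- remodeling_params(params)
  stopifnot(length(params) == 4, all(is.finite(params)), all(params > 0))
  as.numeric(params)
}

#' Pace a single cell and measure APD90
#'
#' Integrates the ionic model from rest under regular stimulation and
#' measures the action potential duration at 90% repolarization on the
#' final beat: the interval between the upward and downward crossings of
#' `V90 = Vpeak - 0.9 (Vpeak - Vrest)`, with `Vrest` taken just before
#' the last stimulus. Twenty beats reach a quasi-steady state.
#'
#' @param params a variant name or 4-vector of conductance scales.
#' @param bcl basic cycle length in ms (500 ms = 2 Hz pacing).
#' @param beats number of paced beats (>= 10 recommended).
#' @param dt integration step (ms).
#' @param record_dt trace recording step (ms).
#' @return An object of class `paced_cell`: `trace` (tibble time/vm),
#'   `apd90` (ms), `params`, `bcl`.
#' @examples
#' \donttest{
#' pc <- pace_cell("af", beats = 20)
#' pc$apd90
#' }
#' @export
pace_cell <- function(params = "af", bcl = 500, beats = 20, dt = 0.02,
                      record_dt = 0.5) {
  stopifnot(bcl >= 300, beats >= 1)
  sc <- .as_scales(params)
  r <- crn_pace_cpp(sc, bcl, as.integer(beats), dt, record_dt, -20, 2, 16L)
  t <- r$time; v <- r$vm
  t0 <- bcl * (beats - 1)
  rest <- v[max(which(t <= t0))]
  sel <- t >= t0
  tb <- t[sel]; vb <- v[sel]
  pk <- max(vb)
  v90 <- pk - 0.9 * (pk - rest)
  up <- which(vb[-length(vb)] < v90 & vb[-1] >= v90)[1]
  apd <- NA_real_
  if (!is.na(up)) {
    tup <- tb[up] + (v90 - vb[up]) / (vb[up + 1] - vb[up]) * (tb[up + 1] - tb[up])
    dn <- which(vb[-length(vb)] >= v90 & vb[-1] < v90)
    dn <- dn[dn > up][1]
    if (!is.na(dn)) {
      tdn <- tb[dn] + (v90 - vb[dn]) / (vb[dn + 1] - vb[dn]) * (tb[dn + 1] - tb[dn])
      apd <- tdn - tup
    }
  }
  structure(list(trace = tibble::tibble(time = t, vm = v), apd90 = apd,
                 params = sc, bcl = bcl), class = "paced_cell")
}

#' @export
print.paced_cell <- function(x, ...) {
  cat(sprintf("paced_cell: bcl %g ms, APD90 = %.1f ms\n", x$bcl, x$apd90))
  invisible(x)
}

# paced limit-cycle trajectory over one final cycle, cached per variant
.lc_cache <- new.env(parent = emptyenv())
limit_cycle <- function(params, bcl = 500, beats = 12, n = 256, dt = 0.02) {
  sc <- .as_scales(params)
  key <- paste(c(sc, bcl, beats, n, dt), collapse = "|")
  if (!is.null(.lc_cache[[key]])) return(.lc_cache[[key]])
  r <- crn_pace_cpp(sc, bcl, as.integer(beats), dt, bcl, -20, 2, as.integer(n))
  .lc_cache[[key]] <- r$cycle
  r$cycle
}

#' Conduction velocity on a 1D cable
#'
#' Simulates a cable of coupled cells stimulated at one end and fits
#' activation time against distance over the central half (excluding
#' boundary effects); the slope gives CV in m/s.
#'
#' @param params variant name or conductance scales.
#' @param diffusion coupling coefficient D (mm^2/ms).
#' @param n_cells cable length in cells (>= 100).
#' @param dx inter-cell spacing (mm).
#' @param dt integration step (ms).
#' @param duration simulated time (ms).
#' @return CV in m/s.
#' @export
cable_cv <- function(params, diffusion, n_cells = 160, dx = 0.25,
                     dt = 0.02, duration = 150) {
  stopifnot(n_cells >= 100)
  sc <- .as_scales(params)
  n <- as.integer(n_cells)
  rest <- crn_rest_state_cpp()
  states0 <- matrix(rest, n, 21, byrow = TRUE)
  nbr <- lapply(seq_len(n), function(i) {
    x <- c(i - 1L, i + 1L); x[x >= 1L & x <= n]
  })
  ptr <- as.integer(cumsum(c(0L, lengths(nbr))))
  idx <- as.integer(unlist(nbr) - 1L)
  w <- rep(diffusion / dx^2, length(idx))
  r <- monodomain_cpp(states0, ptr, idx, w, matrix(sc, n, 4, byrow = TRUE),
                      dt, duration, 0.25, 0:2, 5.0, 2.0, -30.0, integer(0))
  vm <- r$vm; tt <- r$time
  lat <- vapply(seq_len(n), function(i) {
    v <- vm[, i]
    kk <- which(v[-length(v)] < -40 & v[-1] >= -40)[1]
    if (is.na(kk)) return(NA_real_)
    tt[kk] + (-40 - v[kk]) / (v[kk + 1] - v[kk]) * (tt[kk + 1] - tt[kk])
  }, numeric(1))
  ctr <- seq.int(n %/% 4, 3L * n %/% 4)
  if (anyNA(lat[ctr])) stop("propagation failed: no CV measurable")
  unname(coef(lm(dist ~ lat, data = data.frame(dist = ctr * dx,
                                               lat = lat[ctr])))[2])
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Root-finds D on a 1D cable so the chosen variant conducts at
#' `target_cv` (monodomain CV scales as sqrt(D), so the root is unique).
#'
#' @param params variant name or conductance scales.
#' @param target_cv desired CV in m/s.
#' @param dx cable spacing in mm (use the tissue's dx so lattice effects
#'   are calibrated away).
#' @param interval search interval for D (mm^2/ms).
#' @param tol root tolerance on CV (m/s).
#' @return Calibrated D (mm^2/ms).
#' @export
calibrate_diffusion <- function(params, target_cv, dx = 0.25,
                                interval = c(0.01, 0.6), tol = 5e-3) {
  f <- function(D) {
    cv <- tryCatch(cable_cv(params, D, dx = dx), error = function(e) 0)
    cv - target_cv   # propagation failure counts as zero velocity
  }
  uniroot(f, interval, tol = tol)$root
}

#' Build a monodomain tissue simulation on a surface mesh
#'
#' Couples one ionic cell per mesh vertex through the cotangent-Laplacian
#' diffusion operator of the triangulated surface (which reduces to the
#' standard 5-point stencil on a regular right-triangle sheet). Blocked
#' vertices are fully decoupled (no-flux) but keep their local dynamics.
#'
#' @param mesh a [surface_mesh()]; see [mesh_sheet()] for fixtures.
#' @param diffusion D in mm^2/ms.
#' @param params variant name or conductance scales (uniform), or an
#'   n x 4 matrix for heterogeneous tissue.
#' @param fiber optional 3-vector fiber direction; edges orthogonal to it
#'   are weakened so transverse CV drops to `cv_frac` of longitudinal.
#' @param cv_frac transverse/longitudinal CV ratio (default 0.5).
#' @return An object of class `tissue_sim` with fields `mesh`, `csr`,
#'   `scales`, `states` (n x 21, at rest), `time` (0), `block` (empty).
#' @export
tissue_sim <- function(mesh, diffusion, params = "af", fiber = NULL,
                       cv_frac = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  csr <- cotan_csr(mesh, diffusion, fiber = fiber, cv_frac = cv_frac)
  scales <- if (is.matrix(params)) {
    stopifnot(nrow(params) == n, ncol(params) == 4)
    params
  } else matrix(.as_scales(params), n, 4, byrow = TRUE)
  rest <- crn_rest_state_cpp()
  structure(list(mesh = mesh, csr = csr, diffusion = diffusion,
                 scales = scales,
                 states = matrix(rest, n, 21, byrow = TRUE),
                 time = 0, block = integer(0)),
            class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  cat(sprintf("tissue_sim: %d nodes, t = %g ms, %d blocked\n",
              nrow(x$states), x$time, length(x$block)))
  invisible(x)
}

#' Seed reentry by phase distribution
#'
#' Initializes every node's full ionic state from a precomputed paced
#' limit cycle, at the cycle fraction prescribed by a spatial phase
#' pattern: phase +pi maps to the instant of activation and -pi to the
#' end of diastole. A pattern that winds by 2 pi around a point seeds a
#' rotor there; the shipped patterns are a counter-rotating spiral pair
#' (`type = "pair"`, windings +1 and -1 at two in-plane centers, the
#' planar analogue of distributing phase around a Cartesian axis of a
#' closed surface) and a single axial winding (`type = "axis"`, phase =
#' angle about a Cartesian axis through the mesh centroid, which on a
#' closed surface creates an antipodal pair). `direction = -1` mirrors
#' the pattern and flips every chirality.
#'
#' @param sim a [tissue_sim()].
#' @param type `"pair"` or `"axis"`.
#' @param centers 2 x 2 matrix of (x, y) winding centers in mm (pair
#'   type); defaults to one third and two thirds across the sheet.
#' @param axis `"x"`, `"y"` or `"z"` (axis type).
#' @param direction +1 or -1 (chirality of the first/positive winding).
#' @param bcl,beats limit-cycle pacing protocol.
#' @return The sim with initialized states.
#' @export
induce_phase_distribution <- function(sim, type = c("pair", "axis"),
                                      centers = NULL, axis = "z",
                                      direction = 1, bcl = 500, beats = 12) {
  type <- match.arg(type)
  stopifnot(inherits(sim, "tissue_sim"), direction %in% c(-1, 1))
  v <- sim$mesh$vertices
  if (type == "pair") {
    if (is.null(centers)) {
      rx <- range(v[, 1]); ry <- range(v[, 2])
      centers <- rbind(c(rx[1] + diff(rx) / 3, mean(ry)),
                       c(rx[1] + 2 * diff(rx) / 3, mean(ry)))
    }
    a1 <- atan2(v[, 2] - centers[1, 2], v[, 1] - centers[1, 1])
    a2 <- atan2(v[, 2] - centers[2, 2], v[, 1] - centers[2, 1])
    phi <- wrap_angle(direction * (a1 - a2))
  } else {
    ctr <- colMeans(v)
    rel <- sweep(v, 2, ctr)
    phi <- switch(axis,
      x = atan2(rel[, 3], rel[, 2]),
      y = atan2(rel[, 1], rel[, 3]),
      z = atan2(rel[, 2], rel[, 1]),
      stop("axis must be x, y or z"))
    phi <- wrap_angle(direction * phi)
  }
  lc <- limit_cycle(sim$scales[1, ], bcl = bcl, beats = beats)
  frac <- (pi - phi) / (2 * pi)           # 0 at activation, 1 end of cycle
  row <- pmin(nrow(lc), pmax(1L, 1L + floor(frac * nrow(lc))))
  sim$states <- lc[row, , drop = FALSE]
  # each node sits frac of a cycle past its (virtual) activation, so the
  # induced activation time is known exactly; analysis can seed the
  # activation series with it instead of extrapolating backwards
  sim$induced_activation <- -frac * bcl
  sim
}

# prepend known induced activation times to a detected series
seed_activations <- function(acts, t0, min_interval = 50) {
  stopifnot(inherits(acts, "activation_series"),
            length(t0) == length(acts$acts))
  acts$acts <- lapply(seq_along(acts$acts), function(i) {
    a <- acts$acts[[i]]
    if (length(a) && a[1] - t0[i] < min_interval) return(a)
    c(t0[i], a)
  })
  acts
}

#' Mark vertices as conduction block
#'
#' The listed full-mesh vertices become non-conductive from the current
#' simulation time onward: all diffusive coupling to and from them is
#' removed while their local membrane dynamics continue (they simply
#' repolarize to rest).
#'
#' @param sim a [tissue_sim()].
#' @param vertices integer vertex ids (e.g. an ablation plan's
#'   `block_vertices`).
#' @return The sim with the block applied.
#' @export
apply_block <- function(sim, vertices) {
  stopifnot(inherits(sim, "tissue_sim"))
  if (length(vertices) == 0L) {
    warning("empty block polyline: no-op")
    return(sim)
  }
  stopifnot(all(vertices >= 1L), all(vertices <= nrow(sim$states)))
  sim$block <- sort(unique(c(sim$block, as.integer(vertices))))
  sim
}

#' Advance a tissue simulation
#'
#' Runs the monodomain model for `duration` ms from the sim's current
#' state, recording Vm every `record_dt` ms (5 ms for analysis, 10 ms
#' for post-ablation outcome windows).
#'
#' @param sim a [tissue_sim()].
#' @param duration ms to simulate.
#' @param record_dt recording step (ms).
#' @param dt integration step (ms).
#' @param stim optional stimulus: `list(nodes, times, dur, amp)` with
#'   times relative to the current sim time.
#' @return A list: `rec` (a [vm_recording()] with absolute times) and
#'   `sim` (advanced).
#' @export
simulate_tissue <- function(sim, duration, record_dt = 5, dt = 0.05,
                            stim = NULL) {
  stopifnot(inherits(sim, "tissue_sim"))
  stim_nodes <- if (is.null(stim)) integer(0) else as.integer(stim$nodes - 1L)
  stim_times <- if (is.null(stim)) numeric(0) else as.numeric(stim$times)
  stim_dur <- if (is.null(stim)) 0 else stim$dur
  stim_amp <- if (is.null(stim)) 0 else stim$amp
  r <- monodomain_cpp(sim$states, sim$csr$ptr, sim$csr$idx, sim$csr$w,
                      sim$scales, dt, duration, record_dt,
                      stim_nodes, stim_times, stim_dur, stim_amp,
                      as.integer(sim$block - 1L))
  rec <- vm_recording(sim$time + r$time, r$vm)
  sim$states <- r$states
  sim$time <- sim$time + duration
  list(rec = rec, sim = sim)
}

#' Detect termination of electrical activity
#'
#' The termination time is the earliest recorded instant after which all
#' transmembrane voltages stay below the threshold for the remainder of
#' the recording (default -40 mV). Returns `NA` when activity persists
#' through the final sample.
#'
#' @param rec a [vm_recording()].
#' @param threshold mV.
#' @return Termination time in ms, or `NA`.
#' @export
detect_termination <- function(rec, threshold = -40) {
  stopifnot(inherits(rec, "vm_recording"))
  active <- apply(rec$vm, 1, max) >= threshold
  if (!any(active)) return(rec$times[1])
  last <- max(which(active))
  if (last == length(rec$times)) return(NA_real_)
  rec$times[last + 1L]
}

# concatenate recordings that share a boundary sample
.bind_recordings <- function(a, b) {
  keep <- b$times > a$times[length(a$times)] + 1e-9
  vm_recording(c(a$times, b$times[keep]),
               rbind(a$vm, b$vm[keep, , drop = FALSE]), a$point_ids)
}
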