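#' Transmembrane-voltage recordings
#'
#' A light container for per-point Vm time series on a uniform time grid.
#'
#' @param times numeric vector of sample times (ms), uniform step.
#' @param vm numeric matrix, length(times) x n_points, in mV.
#' @param point_ids integer ids of the recorded points (sample or vertex
#'   indices); defaults to column numbers.
#' @return An object of class `vm_recording`.
#' @export
vm_recording <- function(times, vm, point_ids = seq_len(ncol(vm))) {
  vm <- as.matrix(vm)
  if (length(times) != nrow(vm)) stop("times must match rows of vm")
  if (length(times) >= 3) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("time grid must be uniform")
  }
  if (!all(is.finite(vm))) stop("vm contains non-finite values")
  structure(list(times = as.numeric(times), vm = vm,
                 point_ids = as.integer(point_ids)),
            class = "vm_recording")
}

#' @export
print.vm_recording <- function(x, ...) {
  cat(sprintf("vm_recording: %d points x %d timesteps (%g..%g ms, step %g ms)\n",
              ncol(x$vm), length(x$times), min(x$times), max(x$times),
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  invisible(x)
}

#' Local activation times from Vm traces
#'
#' An activation is an upward crossing of `threshold` (default -40 mV, the
#' same voltage convention used to declare termination of activity), with
#' linear sub-step interpolation. Crossings closer than `min_interval` to
#' the previous accepted activation are discarded as re-crossing noise.
#'
#' @param rec a [vm_recording()].
#' @param threshold crossing threshold in mV.
#' @param min_interval refractory floor in ms (default 50, well below the
#'   ~90 ms lower end of clinical fibrillation cycle lengths).
#' @return An object of class `activation_series`: a list with `acts`
#'   (per-point numeric vectors of activation times, ms) and `point_ids`.
#' @export
detect_activations <- function(rec, threshold = -40, min_interval = 50) {
  stopifnot(inherits(rec, "vm_recording"))
  t <- rec$times
  acts <- lapply(seq_len(ncol(rec$vm)), function(i) {
    v <- rec$vm[, i]
    up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
    if (length(up) == 0L) return(numeric(0))
    tx <- t[up] + (threshold - v[up]) / (v[up + 1L] - v[up]) * (t[up + 1L] - t[up])
    out <- tx[1]
    for (a in tx[-1]) if (a - out[length(out)] >= min_interval) out <- c(out, a)
    out
  })
  structure(list(acts = acts, point_ids = rec$point_ids),
            class = "activation_series")
}

#' Sawtooth phase field from activation times
#'
#' Between consecutive activations t_k and t_{k+1} the phase falls
#' linearly from +pi (just activated, excited) to -pi (about to activate,
#' resting): phi(t) = pi - 2 pi (t - t_k) / (t_{k+1} - t_k). Times outside
#' the first/last activation follow the `extend` convention below.
#'
#' @param acts an [detect_activations()] result.
#' @param times analysis time grid (ms).
#' @param extend how to treat times outside a point's first/last
#'   activation: `"clamp"` (default) continues the sawtooth decay past the
#'   last activation at that point's final cycle length until the phase
#'   reaches -pi (rest) and holds it there, and symmetrically
#'   extrapolates one cycle before the first activation (earlier times are
#'   resting, -pi); `"mask"` leaves those times undefined, which excludes
#'   every neighbor ring touching them from jump counting.
#' @return An object of class `phase_field`: `phi` (times x points matrix
#'   in `[-pi, pi]`, NA where undefined), `mask` (TRUE where defined),
#'   `times`, `point_ids`.
#' @export
sawtooth_phase <- function(acts, times, extend = c("clamp", "mask")) {
  stopifnot(inherits(acts, "activation_series"))
  extend <- match.arg(extend)
  np <- length(acts$acts)
  phi <- matrix(NA_real_, length(times), np)
  for (i in seq_len(np)) {
    a <- acts$acts[[i]]
    if (length(a) < 2L) {
      if (extend == "clamp") {
        if (length(a) == 1L) {
          # single activation: one nominal cycle of decay, rest elsewhere
          cl0 <- 200
          p <- pi - 2 * pi * (times - a) / cl0
          phi[, i] <- pmax(-pi, pmin(pi, ifelse(times < a, -pi, p)))
        } else phi[, i] <- -pi      # never activates: resting throughout
      }
      next
    }
    k <- findInterval(times, a)
    ok <- k >= 1L & k < length(a)
    kk <- k[ok]
    phi[ok, i] <- pi - 2 * pi * (times[ok] - a[kk]) / (a[kk + 1L] - a[kk])
    at <- match(round(a, 9), round(times, 9))  # exact activation instants
    phi[at[!is.na(at)], i] <- pi
    if (extend == "clamp") {
      ncl <- length(a)
      cl_last <- a[ncl] - a[ncl - 1L]
      post <- times > a[ncl]
      phi[post, i] <- pmax(-pi, pi - 2 * pi * (times[post] - a[ncl]) / cl_last)
      cl_first <- a[2L] - a[1L]
      pre <- times < a[1L]
      # one extrapolated cycle ending at the first activation, rest before
      p <- pi - 2 * pi * (times[pre] - (a[1L] - cl_first)) / cl_first
      phi[pre, i] <- pmax(-pi, pmin(pi, p))
    }
  }
  structure(list(phi = phi, mask = !is.na(phi), times = as.numeric(times),
                 point_ids = acts$point_ids), class = "phase_field")
}

#' Cycle-length statistics pooled over all points
#'
#' Pools all per-point consecutive activation-time differences and
#' returns their median and interquartile range (75th - 25th percentile).
#' Clinical fibrillation cycle lengths run roughly 90--250 ms.
#'
#' @param acts an [detect_activations()] result.
#' @return A tibble with columns `median_cl`, `iqr_cl`, `n_intervals` (ms).
#' @export
cycle_length_stats <- function(acts) {
  stopifnot(inherits(acts, "activation_series"))
  d <- unlist(lapply(acts$acts, diff))
  if (length(d) == 0L) stop("no activation intervals: cycle length undefined")
  q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median_cl = q[2], iqr_cl = q[3] - q[1],
                 n_intervals = length(d))
}

#' Write / read a Vm recording as CSV
#'
#' Columnar plain-text layout: first column `time` (ms), one column per
#' recorded point named `p<id>` (mV).
#'
#' @param rec a [vm_recording()].
#' @param path file path.
#' @return `path` (write) or a [vm_recording()] (read).
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "vm_recording"))
  df <- data.frame(time = rec$times, rec$vm)
  names(df) <- c("time", paste0("p", rec$point_ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  ids <- as.integer(sub("^p", "", names(df)[-1]))
  vm_recording(df$time, as.matrix(df[, -1, drop = FALSE]), ids)
}
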