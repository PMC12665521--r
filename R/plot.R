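#' Plot a voltage snapshot of a sheet simulation
#'
#' Raster of Vm over the sheet at the recorded time nearest `t`, with
#' optional ablation-plan overlay (blocked vertices in black). Requires
#' ggplot2.
#'
#' @param rec a [vm_recording()] covering all mesh vertices.
#' @param mesh the [surface_mesh()] the recording lives on.
#' @param t time in ms.
#' @param plan optional [plan_ablation()] result to overlay.
#' @return A ggplot object.
#' @export
plot_vm_snapshot <- function(rec, mesh, t, plan = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_vm_snapshot requires ggplot2")
  row <- which.min(abs(rec$times - t))
  d <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                  vm = rec$vm[row, ])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$vm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "red", midpoint = -40,
                                  name = "Vm (mV)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("t = %g ms", rec$times[row]),
                  x = "x (mm)", y = "y (mm)")
  if (!is.null(plan) && length(plan$block_vertices)) {
    b <- data.frame(x = mesh$vertices[plan$block_vertices, 1],
                    y = mesh$vertices[plan$block_vertices, 2])
    p <- p + ggplot2::geom_point(data = b, ggplot2::aes(x = .data$x,
                                                        y = .data$y),
                                 inherit.aes = FALSE, size = 0.4)
  }
  p
}

#' Plot singularity tracks over time
#'
#' Lifespan segments per track, colored by chirality, with the signed
#' cluster-index sum underneath — the visual counterpart of the `f0`
#' metric. Requires ggplot2.
#'
#' @param tracks a [track_singularities()] result.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tracks requires ggplot2")
  stopifnot(inherits(tracks, "singularity_tracks"))
  tt <- tracks$tracks
  sums <- data.frame(time = tracks$times, sum = tracks$cluster_sums)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = tt,
      ggplot2::aes(x = .data$birth, xend = .data$death,
                   y = .data$id, yend = .data$id,
                   color = factor(.data$sign))) +
    ggplot2::geom_step(data = sums,
      ggplot2::aes(x = .data$time, y = .data$sum * 0.5 - 2),
      linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`-1` = "#2166ac", `1` = "#b2182b"),
                                name = "chirality") +
    ggplot2::labs(x = "time (ms)", y = "track id  (index sum below 0)")
}
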