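#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.singularity_tracks <- function(x, ...) x$tracks

#' @export
glance.singularity_tracks <- function(x, ...) {
  tibble::tibble(n_tracks = nrow(x$tracks),
                 f0 = mean(x$cluster_sums == 0),
                 m_ind = mean(x$cluster_sums),
                 max_simultaneous = if (length(x$alive)) max(x$alive) else 0L)
}

#' @export
tidy.paced_cell <- function(x, ...) x$trace

#' @export
glance.paced_cell <- function(x, ...) {
  tibble::tibble(apd90 = x$apd90, bcl = x$bcl,
                 g_kur = x$params[1], g_to = x$params[2],
                 g_cal = x$params[3], g_na = x$params[4])
}

#' @export
tidy.pipeline_result <- function(x, ...) x$outcomes

#' @export
glance.pipeline_result <- function(x, ...) x$metrics
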