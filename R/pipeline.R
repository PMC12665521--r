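#' Configuration for an end-to-end run
#'
#' Collects geometry, remodeling, induction, analysis and ablation
#' settings with the defaults used throughout: a flat sheet fixture,
#' AF-remodeled membrane kinetics, spiral-pair induction, 5 ms analysis
#' sampling from 50 ms onward, ablation snapshots at 1000/2000/3000 ms
#' with a 400 ms / 10 ms outcome window, and all three strategies.
#'
#' @param width,height,dx sheet geometry (mm).
#' @param hole_center,hole_radius optional circular anatomical hole (mm).
#' @param variant remodeling variant (see [remodeling_params()]).
#' @param diffusion coupling D (mm^2/ms); the desk-scale default 0.025 is
#'   the smallest coupling at which the canonical counter-rotating pair
#'   stays coherent while its wavelength still fits the sheet.
#' @param duration simulated time (ms).
#' @param induction `"pair"`, `"axis"`, or `"none"` (leave the tissue at
#'   rest; useful as a negative control).
#' @param direction +1 or -1 (mirrors every chirality).
#' @param jitter_centers if TRUE, winding centers are drawn around the
#'   default positions using `seed`, giving distinct seeded fixtures.
#' @param spacing analysis subsampling distance (mm).
#' @param analysis_start start of the analysis window (ms).
#' @param ablation_times snapshot times (ms), strictly increasing.
#' @param strategies subset of heuristic/straight/random.
#' @param window,outcome_dt outcome window length and recording step (ms).
#' @param dt integration step (ms); 0.05 default, 0.1 remains stable and
#'   halves run time for batch studies.
#' @param seed integer seed for every stochastic choice in the run.
#' @param keep_recording keep the full-resolution Vm recording in the
#'   result (large); sample-level traces are always kept.
#' @param graph optional precomputed [subsample_mesh()] result for the
#'   fixture mesh (reused across runs on the same geometry).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(width = 40, height = 40, dx = 0.5,
                            hole_center = NULL, hole_radius = 5,
                            variant = "af", diffusion = 0.025,
                            duration = 3400,
                            induction = "pair", direction = 1,
                            jitter_centers = FALSE,
                            spacing = 2, analysis_start = 50,
                            ablation_times = c(1000, 2000, 3000),
                            strategies = c("heuristic", "straight", "random"),
                            window = 400, outcome_dt = 10,
                            dt = 0.05,
                            seed = 1L, keep_recording = FALSE,
                            graph = NULL) {
  stopifnot(all(diff(ablation_times) > 0), duration > analysis_start)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on one synthetic fixture
#'
#' simulate -> activation/phase -> topological charge -> tracking ->
#' metrics -> (per ablation time and strategy) plan -> block -> outcome.
#' Ablation times falling after a spontaneous termination are skipped,
#' since there is no activity left to terminate.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `graph`, `tracks`,
#'   `metrics` (one-row tibble), `outcomes` (tibble: strategy, t_abl,
#'   t_ai, success, ...), `plans`, `sc_map`, `t_sp`, `cl`, `sample_rec`,
#'   and optionally `recording`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mesh <- mesh_sheet(config$width, config$height, config$dx,
                     hole_center = config$hole_center,
                     hole_radius = config$hole_radius)
  sim <- tissue_sim(mesh, config$diffusion, config$variant)

  centers <- NULL
  if (config$induction == "pair") {
    v <- mesh$vertices
    rx <- range(v[, 1]); ry <- range(v[, 2])
    centers <- rbind(c(rx[1] + diff(rx) / 3, mean(ry)),
                     c(rx[1] + 2 * diff(rx) / 3, mean(ry)))
    if (config$jitter_centers) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(config$seed)
      centers <- centers + matrix(stats::runif(4, -0.12, 0.12) *
                                  c(diff(rx), diff(rx), diff(ry), diff(ry)),
                                  2, 2)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }
  }
  if (config$induction != "none")
    sim <- induce_phase_distribution(sim, type = config$induction,
                                     centers = centers,
                                     direction = config$direction)

  # base run, segmented at ablation times so their states are checkpointed
  t_break <- sort(unique(c(config$ablation_times[
    config$ablation_times < config$duration], config$duration)))
  rec <- NULL
  checkpoints <- list()
  t_prev <- 0
  for (tb in t_break) {
    out <- simulate_tissue(sim, tb - t_prev, record_dt = 5, dt = config$dt)
    rec <- if (is.null(rec)) out$rec else .bind_recordings(rec, out$rec)
    sim <- out$sim
    checkpoints[[as.character(tb)]] <- sim
    t_prev <- tb
  }
  t_sp <- detect_termination(rec)

  # analysis on the subsampled graph; on an open fixture the outer rim is
  # itself a boundary that can host (or absorb) reentry, so every boundary
  # loop gets a cavity node -- otherwise charge escaping through the rim
  # would break the index-sum accounting
  graph <- config$graph %||% subsample_mesh(mesh, spacing = config$spacing,
                                            cavity_loops = "all")
  sample_rec <- vm_recording(rec$times,
                             rec$vm[, graph$sample_ids, drop = FALSE],
                             graph$sample_ids)
  acts <- detect_activations(sample_rec)
  if (!is.null(sim$induced_activation))
    acts <- seed_activations(acts, sim$induced_activation[graph$sample_ids])
  phase <- sawtooth_phase(acts, sample_rec$times)
  t_hi <- min(config$duration, if (is.na(t_sp)) Inf else t_sp)
  win <- which(phase$times >= config$analysis_start & phase$times <= t_hi)
  if (length(win) == 0L)   # terminated before the window opened
    win <- which.min(abs(phase$times - config$analysis_start))
  charge <- topological_charge(phase, graph, t_index = win)
  tracks <- track_singularities(charge, graph)
  im <- index_metrics(tracks$cluster_sums)
  cx <- complexity_metrics(tracks)
  cl <- tryCatch(cycle_length_stats(acts),
                 error = function(e) tibble::tibble(median_cl = NA_real_,
                                                    iqr_cl = NA_real_,
                                                    n_intervals = 0L))
  sc <- singularity_count_map(charge)
  moran_self <- tryCatch(morans_i(sc, sc, graph)$value,
                         error = function(e) NA_real_)
  metrics <- tibble::tibble(
    f0 = im$f0, m_ind = im$m_ind,
    total_count = cx$summary$total_count,
    max_simultaneous = cx$summary$max_simultaneous,
    median_duration = cx$summary$median_duration,
    median_cl = cl$median_cl, iqr_cl = cl$iqr_cl,
    moran_self = moran_self, t_sp = t_sp)

  # virtual ablations
  outcomes <- NULL
  plans <- list()
  for (t_abl in config$ablation_times) {
    if (!is.na(t_sp) && t_sp < t_abl) {
      for (strat in config$strategies)
        outcomes <- rbind(outcomes,
                          cbind(tibble::tibble(strategy = strat),
                                evaluate_outcome(t_abl, NA, t_sp,
                                                 config$window,
                                                 config$outcome_dt)))
      next
    }
    if (t_abl >= config$duration) next
    base_sim <- checkpoints[[as.character(t_abl)]]
    for (strat in config$strategies) {
      plan <- tryCatch(
        plan_ablation(graph, charge, phase, t_abl, strategy = strat,
                      seed = config$seed),
        error = function(e) e)
      key <- paste(strat, t_abl, sep = "@")
      plans[[key]] <- plan
      if (inherits(plan, "error") || length(plan$block_vertices) == 0L) {
        outcomes <- rbind(outcomes,
                          cbind(tibble::tibble(strategy = strat),
                                evaluate_outcome(t_abl, NA, t_sp,
                                                 config$window,
                                                 config$outcome_dt)))
        next
      }
      s2 <- base_sim
      if (plan$t_abl > t_abl) {
        adv <- simulate_tissue(s2, plan$t_abl - t_abl, record_dt = 5, dt = config$dt)
        s2 <- adv$sim
      }
      s2 <- apply_block(s2, plan$block_vertices)
      post <- simulate_tissue(s2, config$window, record_dt = config$outcome_dt, dt = config$dt)
      t_ai <- detect_termination(post$rec)
      outcomes <- rbind(outcomes,
                        cbind(tibble::tibble(strategy = strat),
                              evaluate_outcome(plan$t_abl, t_ai, t_sp,
                                               config$window,
                                               config$outcome_dt)))
    }
  }
  res <- list(config = config, graph = graph, tracks = tracks,
              metrics = metrics, outcomes = outcomes, plans = plans,
              sc_map = sc, t_sp = t_sp, cl = cl, sample_rec = sample_rec)
  if (config$keep_recording) res$recording <- rec
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$metrics)
  if (!is.null(x$outcomes)) {
    cat("outcomes:\n")
    print(x$outcomes[, c("strategy", "t_abl", "t_ai", "performed", "success")])
  }
  invisible(x)
}

#' Write the per-run CSV report
#'
#' Two files: `<prefix>_tracks.csv` (track table: id, sign, birth, death,
#' duration) and `<prefix>_metrics.csv` (one summary row).
#'
#' @param result a [run_pipeline()] result.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
report_csv <- function(result, prefix) {
  p1 <- paste0(prefix, "_tracks.csv")
  p2 <- paste0(prefix, "_metrics.csv")
  utils::write.csv(result$tracks$tracks, p1, row.names = FALSE)
  utils::write.csv(result$metrics, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
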