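#' Specify a synthetic BOLD simulation
#'
#' Describes one synthetic dataset: a generating event model, per-ROI event
#' amplitudes, the time-to-peak of the double-gamma HRF used to build the
#' responses, an additive white-Gaussian noise level, and the acquisition
#' grid. [simulate_bold()] turns the specification into a long BOLD table.
#'
#' @param model Generating event model (columns `event`, `start_time`,
#'   `duration`).
#' @param amplitudes Per-ROI event amplitudes: a data frame with a `roi`
#'   column plus one numeric column per event, or a numeric matrix with ROI
#'   rownames and event colnames.
#' @param hrf_ttp Time-to-peak (s) of the double-gamma HRF used to generate
#'   the data; the default 5 s matches the default evaluation HRF.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (independent across ROIs and frames); 0 gives noiseless data.
#' @param tr Repetition time in seconds.
#' @param n_frames Number of BOLD frames.
#' @param seed Optional integer seed for the noise stream.
#' @param f Up-sampling factor used when building the responses.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(model, amplitudes, hrf_ttp = 5, noise_sd = 0,
                            tr = 1, n_frames = 30, seed = NULL, f = 100) {
  model <- .as_event_model(model)
  amp <- .as_amplitude_matrix(amplitudes, model$event)
  .assert_scalar_num(hrf_ttp, "hrf_ttp", positive = TRUE)
  .assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  .assert_scalar_num(tr, "tr", positive = TRUE)
  n_frames <- .assert_count(n_frames, "n_frames", min = 2L)
  f <- .assert_count(f, "f", min = 1L)
  if (!is.null(seed)) seed <- .assert_count(seed, "seed", min = 0L)
  structure(
    list(model = model, amplitudes = amp, hrf_ttp = hrf_ttp,
         noise_sd = noise_sd, tr = tr, n_frames = n_frames,
         seed = seed, f = f),
    class = "simulation_spec"
  )
}

.as_amplitude_matrix <- function(amplitudes, events) {
  if (is.data.frame(amplitudes)) {
    .require_columns(amplitudes, "roi", "`amplitudes`")
    rois <- as.character(amplitudes$roi)
    cols <- setdiff(names(amplitudes), "roi")
    amp <- as.matrix(amplitudes[, cols, drop = FALSE])
    rownames(amp) <- rois
  } else if (is.matrix(amplitudes)) {
    amp <- amplitudes
    if (is.null(rownames(amp))) {
      rownames(amp) <- paste0("ROI_", seq_len(nrow(amp)))
    }
  } else {
    abort("`amplitudes` must be a data frame with a roi column or a matrix with event colnames.")
  }
  if (is.null(colnames(amp))) abort("`amplitudes` must name its event columns.")
  missing <- setdiff(events, colnames(amp))
  extra <- setdiff(colnames(amp), events)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(sprintf("`amplitudes` columns must match the model events (missing: %s; unexpected: %s).",
                  paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(rownames(amp))) abort("`amplitudes` has duplicated ROI names.")
  storage.mode(amp) <- "double"
  if (any(!is.finite(amp))) abort("`amplitudes` must be finite.")
  amp[, events, drop = FALSE]
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %d events, %d ROIs, ttp %g s, noise SD %g, %d frames @ tr %g s\n",
              nrow(x$model), nrow(x$amplitudes), x$hrf_ttp, x$noise_sd,
              x$n_frames, x$tr))
  invisible(x)
}

#' Generate synthetic BOLD time series
#'
#' For each ROI `r` the signal is the amplitude-weighted sum of the event
#' regressors, `y_r(t) = sum_e A[r, e] x_e(t) + eps`, where `x_e` is the
#' boxcar of event `e` convolved with a double-gamma HRF whose time-to-peak
#' is `spec$hrf_ttp`, and `eps ~ N(0, noise_sd^2)` independently per ROI and
#' frame. With a `seed` in the specification the output is reproducible.
#'
#' @param spec A [simulation_spec()].
#' @return A long-format tibble with columns `roi`, `t`, `y`, ready for
#'   [evaluate_model()] / [optimize_events()].
#' @export
simulate_bold <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    abort("`spec` must be created with simulation_spec().")
  }
  hrf <- shift_time_to_peak(hrf_spec("spm", tr = spec$tr, f = spec$f),
                            spec$hrf_ttp)
  frame_times <- (seq_len(spec$n_frames) - 1) * spec$tr
  ## context without data: reuse the regressor machinery on a dummy grid
  bm <- list(rois = rownames(spec$amplitudes), frame_times = frame_times,
             values = matrix(0, nrow(spec$amplitudes), spec$n_frames),
             tr = spec$tr, n_frames = spec$n_frames)
  ctx <- .eval_ctx(bm, hrf, rep(1, nrow(spec$amplitudes)))
  R <- .ctx_regressors(ctx, spec$model$start_time, spec$model$duration,
                       spec$model$event)
  signal <- R %*% t(spec$amplitudes)   # n_frames x n_roi

  draw_noise <- function() {
    if (spec$noise_sd == 0) 0 else
      matrix(rnorm(length(signal), 0, spec$noise_sd),
             nrow = nrow(signal), ncol = ncol(signal))
  }
  noise <- if (is.null(spec$seed)) draw_noise() else
    withr::with_seed(spec$seed, draw_noise())
  y <- signal + noise

  rois <- rownames(spec$amplitudes)
  tibble(
    roi = rep(rois, each = spec$n_frames),
    t = rep(frame_times, times = length(rois)),
    y = as.vector(y)
  )
}

#' Enumerate a factorial simulation design
#'
#' Builds one [simulation_spec()] per combination of generating event model,
#' HRF time-to-peak and noise SD (Cartesian product, models varying
#' slowest). The defaults reproduce a 4 x 3 x 5 = 60-dataset design: four
#' event models, times-to-peak of 4, 5 and 6 s, and noise SDs of 0, 0.067,
#' 0.1, 0.15 and 0.225.
#'
#' @param models Named list of event-model data frames.
#' @param ttps Distinct HRF times-to-peak in seconds.
#' @param noise_sds Distinct noise standard deviations.
#' @param amplitudes Per-ROI event amplitudes shared by all specs (see
#'   [simulation_spec()]).
#' @param tr,n_frames,f Acquisition grid passed to every spec.
#' @param seed Base seed; row `i` of the grid receives seed `seed + i - 1`
#'   so every dataset has its own reproducible noise stream.
#' @return A tibble with columns `model` (name), `hrf_ttp`, `noise_sd` and a
#'   `spec` list-column of [simulation_spec()] objects.
#' @examples
#' grid <- factorial_grid(wm_example_models(),
#'                        amplitudes = default_amplitudes())
#' nrow(grid) # 60
#' @export
factorial_grid <- function(models, ttps = c(4, 5, 6),
                           noise_sds = c(0, 0.067, 0.1, 0.15, 0.225),
                           amplitudes = default_amplitudes(),
                           tr = 1, n_frames = 30, seed = 1, f = 100) {
  if (!is.list(models) || length(models) == 0 ||
      !all(vapply(models, is.data.frame, logical(1)))) {
    abort("`models` must be a nonempty list of event-model data frames.")
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model_", LETTERS[seq_along(models)])
  }
  if (length(ttps) == 0 || length(noise_sds) == 0) {
    abort("`ttps` and `noise_sds` must be nonempty.")
  }
  if (anyDuplicated(ttps)) abort("`ttps` contains duplicate entries.")
  if (anyDuplicated(noise_sds)) abort("`noise_sds` contains duplicate entries.")

  grid <- tidyr::expand_grid(model = names(models), hrf_ttp = ttps,
                             noise_sd = noise_sds)
  grid$spec <- purrr::pmap(
    list(grid$model, grid$hrf_ttp, grid$noise_sd, seq_len(nrow(grid))),
    function(m, ttp, sd, i) {
      simulation_spec(models[[m]], amplitudes, hrf_ttp = ttp, noise_sd = sd,
                      tr = tr, n_frames = n_frames, seed = seed + i - 1, f = f)
    }
  )
  grid
}
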