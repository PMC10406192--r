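#' Example working-memory trial event models
#'
#' Four three-event models of a slow event-related working-memory trial
#' (encoding of a briefly presented target, a maintenance delay, and a
#' response phase), differing in the exact onsets and durations. They serve
#' as generating truths for the simulation framework: models A and B follow
#' the theoretical timeline of such a trial (a very short or a somewhat
#' extended encoding), while C and D represent data-informed variants with
#' later onsets and shorter durations. They are illustrative inputs, not
#' claims about any particular experiment.
#'
#' @return A named list (`A`-`D`) of event-model tibbles with columns
#'   `event`, `start_time`, `duration` (seconds).
#' @examples
#' wm_example_models()$A
#' @export
wm_example_models <- function() {
  list(
    A = tibble(
      event = c("encoding", "delay", "response"),
      start_time = c(0, 0.15, 10),
      duration = c(0.15, 9.85, 3)
    ),
    B = tibble(
      event = c("encoding", "delay", "response"),
      start_time = c(0, 2, 10),
      duration = c(2, 8, 3)
    ),
    C = tibble(
      event = c("encoding", "delay", "response"),
      start_time = c(0.5, 2.5, 10.5),
      duration = c(1, 7, 2)
    ),
    D = tibble(
      event = c("encoding", "delay", "response"),
      start_time = c(0.25, 1, 10.25),
      duration = c(0.5, 9, 2.5)
    )
  )
}

#' Default per-ROI event amplitudes for simulation
#'
#' Draws a reproducible amplitude table for `n_roi` hypothetical ROIs that
#' differ in how strongly they respond to each event. Amplitudes are drawn
#' uniformly from `[0.5, 1.5]` under a fixed seed, giving clearly active
#' regions with about a three-fold spread in responsiveness.
#'
#' @param n_roi Number of ROIs (default 10).
#' @param events Event names (columns of the table).
#' @param seed Seed for the draw; the default yields the same table in
#'   every session.
#' @return A tibble with a `roi` column and one amplitude column per event.
#' @export
default_amplitudes <- function(n_roi = 10,
                               events = c("encoding", "delay", "response"),
                               seed = 20221205) {
  n_roi <- .assert_count(n_roi, "n_roi", min = 1L)
  amps <- withr::with_seed(seed, matrix(runif(n_roi * length(events), 0.5, 1.5),
                                        nrow = n_roi))
  colnames(amps) <- events
  dplyr::bind_cols(tibble(roi = sprintf("ROI_%02d", seq_len(n_roi))),
                   as_tibble(amps))
}

#' Full-factorial amplitude grid
#'
#' Builds a simulated-ROI set in which every combination of per-event
#' amplitude levels occurs exactly once, so that for any target event and
#' level there is a group of ROIs sharing that amplitude while the other
#' events' amplitudes vary — the design needed to quantify how much a beta
#' estimate for one event is contaminated by activity of the others (see
#' [beta_recovery()]). With the defaults (6 levels, 3 events) this yields
#' `6^3 = 216` ROIs. Levels are kept strictly positive so every simulated
#' ROI carries signal (an all-zero ROI has undefined R-squared under zero
#' noise).
#'
#' @param levels Amplitude levels shared by all events.
#' @param events Event names.
#' @return A tibble with a `roi` column and one amplitude column per event.
#' @export
amplitude_grid <- function(levels = seq(0.25, 1.5, by = 0.25),
                           events = c("encoding", "delay", "response")) {
  if (length(levels) < 2) abort("`levels` must contain at least two amplitude levels.")
  if (anyDuplicated(levels)) abort("`levels` contains duplicate entries.")
  grid <- expand.grid(rep(list(levels), length(events)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- events
  dplyr::bind_cols(tibble(roi = sprintf("ROI_%03d", seq_len(nrow(grid)))),
                   as_tibble(grid))
}
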