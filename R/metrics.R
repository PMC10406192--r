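#' Coverage overlap between a true and an estimated event interval
#'
#' Percentage of the true (simulated) interval covered by the estimated
#' interval: `100 * |true AND estimated| / |true|`. Disjoint intervals score
#' 0; an estimate containing the whole true interval scores 100.
#'
#' @param simulated,estimated Intervals as numeric `c(start, end)` vectors
#'   in seconds, `start <= end`. The simulated interval must have positive
#'   length.
#' @return Coverage as a percentage in `[0, 100]`.
#' @examples
#' overlap_coverage(c(2, 10), c(6, 12)) # 50
#' @export
overlap_coverage <- function(simulated, estimated) {
  s <- .as_interval(simulated, "simulated")
  e <- .as_interval(estimated, "estimated")
  if (s[2] <= s[1]) abort("`simulated` interval must have positive length.")
  inter <- max(0, min(s[2], e[2]) - max(s[1], e[1]))
  100 * inter / (s[2] - s[1])
}

#' Robustness overlap of a set of intervals
#'
#' Percentage of the common time covered by all intervals relative to the
#' time covered by any of them: `100 * |intersection| / |union|` (0 when any
#' two intervals are disjoint). Used both for robustness of recovered event
#' timing across noise levels and for consistency of recovered timing across
#' recording sessions.
#'
#' @param intervals A list of numeric `c(start, end)` intervals, or a data
#'   frame / matrix with two columns (start, end), one row per interval.
#' @return Overlap as a percentage in `[0, 100]`.
#' @examples
#' overlap_robustness(list(c(0, 4), c(2, 6))) # 33.33
#' @export
overlap_robustness <- function(intervals) {
  ints <- .as_interval_list(intervals)
  starts <- vapply(ints, `[`, numeric(1), 1L)
  ends <- vapply(ints, `[`, numeric(1), 2L)
  inter <- max(0, min(ends) - max(starts))
  ## union of possibly disjoint intervals by sweeping merged segments
  ord <- order(starts)
  un <- 0
  cur_s <- starts[ord[1]]
  cur_e <- ends[ord[1]]
  for (i in ord[-1]) {
    if (starts[i] > cur_e) {
      un <- un + (cur_e - cur_s)
      cur_s <- starts[i]
      cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  un <- un + (cur_e - cur_s)
  if (un <= 0) abort("all intervals have zero length; overlap is undefined.")
  100 * inter / un
}

.as_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric c(start, end) pair.", name))
  }
  if (x[2] < x[1]) abort(sprintf("`%s`: start must be <= end.", name))
  as.numeric(x)
}

.as_interval_list <- function(intervals) {
  if (is.data.frame(intervals) || is.matrix(intervals)) {
    m <- as.matrix(intervals)
    if (ncol(m) != 2) abort("`intervals` must have two columns (start, end).")
    intervals <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  if (!is.list(intervals) || length(intervals) == 0) {
    abort("`intervals` must be a nonempty list of c(start, end) pairs.")
  }
  lapply(seq_along(intervals),
         function(i) .as_interval(intervals[[i]], sprintf("intervals[[%d]]", i)))
}

#' Per-event coverage of a true model by an estimated model
#'
#' Applies [overlap_coverage()] event by event, matching events by name.
#'
#' @param true_model,estimated_model Event-model data frames sharing the
#'   same event names.
#' @return A tibble with columns `event`, `coverage` (percent).
#' @export
event_coverage <- function(true_model, estimated_model) {
  tm <- .as_event_model(true_model, "true_model")
  em <- .as_event_model(estimated_model, "estimated_model")
  if (!setequal(tm$event, em$event)) {
    abort("`true_model` and `estimated_model` must share the same event names.")
  }
  em <- em[match(tm$event, em$event), ]
  tibble(
    event = tm$event,
    coverage = purrr::map2_dbl(
      seq_len(nrow(tm)), seq_len(nrow(em)),
      function(i, j) overlap_coverage(
        c(tm$start_time[i], tm$start_time[i] + tm$duration[i]),
        c(em$start_time[j], em$start_time[j] + em$duration[j])
      )
    )
  )
}

#' Amplitude recovery of a fitted model against its generating simulation
#'
#' Compares the per-ROI beta estimates of an [evaluate_model()] fit with the
#' amplitudes used to simulate the data. For each event it reports (i) the
#' Pearson correlation between simulated amplitudes and estimated betas
#' across ROIs, and (ii) for every amplitude level at which several ROIs
#' share the same simulated amplitude of that event (while other events
#' vary), the spread of the beta estimates: their range and a bootstrap
#' percentile 95% confidence interval of their mean. An unbiased model
#' yields correlations of 1 and zero-width ranges on noiseless data.
#'
#' @param sim A [simulation_spec()] describing how the data were generated.
#' @param fit An `event_fit` produced on data simulated from `sim` (same
#'   ROIs).
#' @param n_boot Number of bootstrap resamples for the confidence
#'   intervals. Uses the current RNG state.
#' @return An object of class `recovery_report`: a list with
#'   * `correlations`: tibble `(event, pearson_r, n_roi)` — `pearson_r` is
#'     `NA` when the amplitude column is constant (correlation undefined);
#'   * `ranges`: tibble `(event, amplitude, n_roi, beta_mean, beta_min,
#'     beta_max, width, ci_lower, ci_upper)`.
#' @export
beta_recovery <- function(sim, fit, n_boot = 1000) {
  if (!inherits(sim, "simulation_spec")) {
    abort("`sim` must be created with simulation_spec().")
  }
  if (!inherits(fit, "event_fit")) {
    abort("`fit` must be produced by evaluate_model().")
  }
  n_boot <- .assert_count(n_boot, "n_boot", min = 1L)
  amp <- sim$amplitudes
  betas <- fit$betas
  if (nrow(amp) < 3) abort("at least 3 ROIs are required for correlation.")
  if (!setequal(rownames(amp), rownames(betas))) {
    abort("`sim` and `fit` must cover the same ROIs.")
  }
  events <- intersect(colnames(amp), colnames(betas))
  if (length(events) == 0) {
    abort("`sim` and `fit` share no event names; betas cannot be matched.")
  }
  betas <- betas[rownames(amp), , drop = FALSE]

  correlations <- purrr::map_dfr(events, function(e) {
    a <- amp[, e]
    b <- betas[, e]
    r <- if (stats::sd(a) == 0) NA_real_ else cor(a, b)
    tibble(event = e, pearson_r = r, n_roi = length(a))
  })

  ranges <- purrr::map_dfr(events, function(e) {
    levels <- split(betas[, e], amp[, e])
    purrr::map_dfr(names(levels), function(lv) {
      b <- levels[[lv]]
      bm <- mean(b)
      ci <- if (length(b) > 1) {
        boots <- vapply(seq_len(n_boot),
                        function(i) mean(sample(b, length(b), replace = TRUE)),
                        numeric(1))
        quantile(boots, c(0.025, 0.975), names = FALSE)
      } else c(bm, bm)
      tibble(event = e, amplitude = as.numeric(lv), n_roi = length(b),
             beta_mean = bm, beta_min = min(b), beta_max = max(b),
             width = max(b) - min(b), ci_lower = ci[1], ci_upper = ci[2])
    })
  })

  structure(list(correlations = correlations, ranges = ranges),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n  amplitude-beta correlations:\n")
  print(x$correlations)
  cat(sprintf("  beta spread summarised over %d event x amplitude cells\n",
              nrow(x$ranges)))
  invisible(x)
}
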