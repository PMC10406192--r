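#' Build high-resolution boxcar neural time series for an event model
#'
#' Each event is represented as a 0/1 boxcar on the up-sampled grid with step
#' `tr / f`: sample `i` (at time `i * tr / f`) is 1 when
#' `start_time <= t < start_time + duration`. Events running past the end of
#' the scan are truncated at the last high-resolution sample.
#'
#' @param model Event-model data frame with columns `event`, `start_time`,
#'   `duration` (seconds).
#' @param n_frames Number of BOLD frames in the scan.
#' @param tr Repetition time in seconds.
#' @param f Integer up-sampling factor.
#' @return A numeric matrix with one row per event (rownames are event
#'   names) and `n_frames * f` columns, with attribute `step = tr / f`.
#' @examples
#' m <- data.frame(event = "cue", start_time = 0, duration = 2.5)
#' n <- build_neural_matrix(m, n_frames = 4, tr = 2.5, f = 100)
#' sum(n) # 100 high-resolution samples are active
#' @export
build_neural_matrix <- function(model, n_frames, tr, f) {
  model <- .as_event_model(model)
  n_frames <- .assert_count(n_frames, "n_frames", min = 1L)
  .assert_scalar_num(tr, "tr", positive = TRUE)
  f <- .assert_count(f, "f", min = 1L)
  step <- tr / f
  n_hi <- n_frames * f

  idx <- .boxcar_indices(model, step, n_hi)
  out <- matrix(0, nrow = nrow(model), ncol = n_hi,
                dimnames = list(model$event, NULL))
  for (e in seq_len(nrow(model))) {
    out[e, (idx$i0[e] + 1L):idx$i1[e]] <- 1
  }
  attr(out, "step") <- step
  out
}

## Half-open boxcar support [i0, i1) in 0-based high-resolution samples,
## truncated at the scan end. A positive duration shorter than the sample
## step still occupies one sample. Errors on events with no support in the
## scan.
.boxcar_indices <- function(model, step, n_hi) {
  tol <- 1e-9
  i0 <- ceiling(model$start_time / step - tol)
  bad <- i0 >= n_hi
  if (any(bad)) {
    abort(sprintf("event(s) %s start at or after the end of the scan (%g s) and would produce all-zero regressors.",
                  paste(model$event[bad], collapse = ", "), n_hi * step))
  }
  i1 <- ceiling((model$start_time + model$duration) / step - tol)
  i1 <- pmin(pmax(i1, i0 + 1L), n_hi)
  list(i0 = as.integer(i0), i1 = as.integer(i1))
}

#' Convolve neural time series with an HRF kernel and down-sample
#'
#' Performs the full linear convolution of each high-resolution neural time
#' series with the sampled HRF kernel, scales by the sample step `tr / f`
#' (so the result approximates the continuous convolution and is invariant
#' to the choice of `f`), truncates to the scan length, and decimates by
#' keeping every `f`-th sample starting at index 0. The retained samples sit
#' exactly on the BOLD frame times `0, tr, 2 tr, ...`.
#'
#' @param neural Matrix of high-resolution neural time series (one row per
#'   event), as produced by [build_neural_matrix()].
#' @param kernel An `hrf_kernel` from [generate_hrf()]; its `step` must
#'   match the step of `neural`.
#' @param f Integer down-sampling factor (the up-sampling factor used to
#'   build `neural`).
#' @return Matrix of frame-resolution regressors, events x `n_frames`.
#' @export
convolve_downsample <- function(neural, kernel, f) {
  if (!is.matrix(neural)) abort("`neural` must be a matrix (events x samples).")
  if (!inherits(kernel, "hrf_kernel")) abort("`kernel` must come from generate_hrf().")
  f <- .assert_count(f, "f", min = 1L)
  n_hi <- ncol(neural)
  if (n_hi %% f != 0) {
    abort("`neural` length is not a multiple of `f`; steps are mismatched.")
  }
  step_attr <- attr(neural, "step")
  if (!is.null(step_attr) &&
      abs(step_attr - kernel$step) > 1e-9 * max(1, kernel$step)) {
    abort(sprintf("step mismatch: neural sampled at %g s, kernel at %g s.",
                  step_attr, kernel$step))
  }
  keep <- seq(1L, n_hi, by = f)
  out <- matrix(0, nrow = nrow(neural), ncol = length(keep),
                dimnames = list(rownames(neural), NULL))
  for (e in seq_len(nrow(neural))) {
    z <- convolve(neural[e, ], rev(kernel$values), type = "open")
    out[e, ] <- z[keep] * kernel$step
  }
  out
}

#' Ordinary least-squares fit of event regressors to one ROI time series
#'
#' Fits `y ~ intercept + regressors` by OLS and reports the coefficient of
#' determination and a Gaussian-likelihood BIC,
#' `BIC = n log(RSS / n) + k log(n)` with `k` = number of event regressors
#' plus one for the intercept. Only relative BIC comparisons between models
#' fitted to the same series are meaningful.
#'
#' @param regressors Matrix of frame-resolution regressors, events x frames
#'   (as returned by [convolve_downsample()]).
#' @param y Numeric BOLD time series, one value per frame.
#' @return A list with `betas` (named per event), `intercept`, `r2`, `bic`,
#'   `predicted` and `rss`.
#' @export
fit_roi <- function(regressors, y) {
  if (!is.matrix(regressors)) abort("`regressors` must be a matrix (events x frames).")
  y <- as.numeric(y)
  n <- length(y)
  p <- nrow(regressors)
  if (ncol(regressors) != n) {
    abort(sprintf("`y` has %d frames but `regressors` has %d columns.",
                  n, ncol(regressors)))
  }
  if (n <= p + 1L) {
    abort(sprintf("need more frames (%d) than parameters (%d regressors + intercept).",
                  n, p))
  }
  if (any(!is.finite(y))) abort("`y` contains missing or non-finite values.")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("`y` is constant; R-squared is undefined.")

  X <- cbind("(Intercept)" = 1, t(regressors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(sprintf("rank-deficient design: regressor(s) %s are collinear with the others.",
                  paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qx, y)
  predicted <- drop(X %*% coefs)
  rss <- sum((y - predicted)^2)
  k <- p + 1L
  list(
    betas = coefs[-1L],
    intercept = unname(coefs[1L]),
    r2 = 1 - rss / tss,
    bic = n * log(rss / n) + k * log(n),
    predicted = predicted,
    rss = rss
  )
}
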