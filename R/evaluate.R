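## Shared fast evaluation context -------------------------------------------
##
## Regressors for boxcar events can be read off a cumulative sum of the
## kernel: the full convolution of an indicator on samples [i0, i1) with a
## kernel K satisfies z[n] = C[n - i0] - C[n - i1], C = cumsum(K). Only the
## decimated frame samples are ever materialised. This is algebraically
## identical to build_neural_matrix() + convolve_downsample() and is what
## evaluate_model() and the genetic-algorithm inner loop use.

.eval_ctx <- function(bm, hrf, weights) {
  if (abs(hrf$tr - bm$tr) > 1e-9 * max(1, bm$tr)) {
    abort(sprintf("`hrf` was specified for tr = %g s but the data has tr = %g s.",
                  hrf$tr, bm$tr))
  }
  kernel <- generate_hrf(hrf)
  f <- hrf$f
  n_frames <- bm$n_frames
  n_hi <- n_frames * f
  C <- cumsum(kernel$values)
  n_need <- n_hi
  Cfull <- if (length(C) >= n_need) C[seq_len(n_need)] else
    c(C, rep(C[length(C)], n_need - length(C)))
  list(
    bm = bm, hrf = hrf, kernel = kernel, f = f, step = kernel$step,
    n_frames = n_frames, n_hi = n_hi, Cfull = Cfull,
    frame_hi = (seq_len(n_frames) - 1L) * f,
    Yt = t(bm$values),
    tss = apply(bm$values, 1L, function(y) sum((y - mean(y))^2)),
    weights = weights
  )
}

## lookup of the padded kernel cumulative sum at 0-based lags (0 for j < 0)
.cs_lookup <- function(j, Cfull) {
  v <- numeric(length(j))
  ok <- j >= 0L
  v[ok] <- Cfull[pmin(j[ok], length(Cfull) - 1L) + 1L]
  v
}

## frame-resolution regressor matrix (n_frames x n_events) for given timings
.ctx_regressors <- function(ctx, start_time, duration, events) {
  model <- tibble(event = events, start_time = start_time, duration = duration)
  idx <- .boxcar_indices(model, ctx$step, ctx$n_hi)
  R <- matrix(0, nrow = ctx$n_frames, ncol = length(events),
              dimnames = list(NULL, events))
  for (e in seq_along(events)) {
    R[, e] <- ctx$step * (.cs_lookup(ctx$frame_hi - idx$i0[e], ctx$Cfull) -
                            .cs_lookup(ctx$frame_hi - idx$i1[e], ctx$Cfull))
  }
  R
}

## weighted R2 across ROIs for a regressor matrix; rank-deficient designs are
## scored through the rank-reduced projection (used only inside the GA, where
## an occasional degenerate candidate must not abort the search)
.ctx_weighted_r2 <- function(ctx, R) {
  fit <- stats::.lm.fit(cbind(1, R), ctx$Yt)
  rss <- colSums(fit$residuals^2)
  r2 <- 1 - rss / ctx$tss
  sum(ctx$weights * r2) / sum(ctx$weights)
}

## Aggregation ----------------------------------------------------------------

#' Aggregate per-ROI fit scores
#'
#' Computes the mean, median, minimum and weighted mean of a vector of
#' per-ROI scores (R-squared or BIC). The weighted mean is
#' `sum(w * score) / sum(w)`; every ROI defaults to weight 1.
#'
#' @param scores Numeric vector of per-ROI scores, optionally named by ROI.
#' @param weights Optional weights: a data frame with columns `roi`,
#'   `weight`, or a named numeric vector. Requires named `scores`.
#'   Unlisted ROIs keep weight 1.
#' @return A one-row tibble with columns `mean`, `median`, `min`, `weighted`.
#' @examples
#' aggregate_scores(c(0.2, 0.4, 0.9))
#' @export
aggregate_scores <- function(scores, weights = NULL) {
  if (!is.numeric(scores) || length(scores) == 0) {
    abort("`scores` must be a nonempty numeric vector.")
  }
  if (is.null(weights)) {
    w <- rep(1, length(scores))
  } else {
    if (is.null(names(scores))) {
      abort("`scores` must be named by ROI when `weights` are supplied.")
    }
    w <- .resolve_weights(names(scores), weights)
  }
  tibble(
    mean = mean(scores),
    median = median(scores),
    min = min(scores),
    weighted = sum(w * scores) / sum(w)
  )
}

## evaluate_model -------------------------------------------------------------

#' Evaluate an event model against BOLD time series
#'
#' Builds one regressor per event (boxcar neural time series convolved with
#' the HRF at resolution `tr / f`, then down-sampled to the frame grid), fits
#' an ordinary least-squares model with intercept to every ROI independently,
#' and summarises the fit with per-ROI and aggregate R-squared and BIC.
#'
#' @param bold Long-format BOLD data frame with columns `roi`, `t`
#'   (seconds, frames at `0, tr, 2 tr, ...`) and `y`.
#' @param model Event-model data frame with columns `event`, `start_time`,
#'   `duration` (seconds).
#' @param tr Repetition time in seconds.
#' @param hrf An [hrf_spec()]; defaults to the double-gamma HRF at the given
#'   `tr` with up-sampling factor 100. Its `tr` must match `tr`.
#' @param roi_weights Optional per-ROI weights (data frame with columns
#'   `roi`, `weight`, or a named numeric vector); unlisted ROIs have
#'   weight 1. Used for the `weighted` aggregates.
#' @return An object of class `event_fit` with elements
#'   * `by_roi`: tibble of per-ROI `r2`, `bic`, `intercept` and one
#'     `beta_<event>` column per event;
#'   * `aggregates`: tibble with the mean/median/min/weighted `r2` and `bic`;
#'   * `timecourses`: tibble `(roi, t, observed, predicted)`;
#'   * `contributions`: tibble `(roi, t, event, value)` with each event's
#'     fitted contribution `beta * regressor`;
#'   plus the `model`, `hrf`, `tr` and resolved `weights` used.
#'   [glance()] returns the aggregates as one row, [tidy()] the per-ROI
#'   coefficients, and [autoplot()] plots observed against fitted series.
#' @examples
#' model <- data.frame(event = c("cue", "response"),
#'                     start_time = c(0, 6), duration = c(2, 3))
#' amps <- data.frame(roi = c("r1", "r2"), cue = c(1, 0.5), response = c(0.2, 1))
#' bold <- simulate_bold(simulation_spec(model, amps, tr = 1, n_frames = 20))
#' fit <- evaluate_model(bold, model, tr = 1)
#' glance(fit)
#' @export
evaluate_model <- function(bold, model, tr, hrf = hrf_spec(tr = tr),
                           roi_weights = NULL) {
  model <- .as_event_model(model)
  bm <- .as_bold_matrix(bold, tr)
  weights <- .resolve_weights(bm$rois, roi_weights)
  ctx <- .eval_ctx(bm, hrf, weights)

  R <- .ctx_regressors(ctx, model$start_time, model$duration, model$event)
  n <- ctx$n_frames
  p <- ncol(R)
  if (n <= p + 1L) {
    abort(sprintf("need more frames (%d) than parameters (%d regressors + intercept).",
                  n, p))
  }
  zero_tss <- ctx$tss == 0
  if (any(zero_tss)) {
    abort(sprintf("ROI(s) %s have constant BOLD series; R-squared is undefined.",
                  paste(bm$rois[zero_tss], collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1, R)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(sprintf("rank-deficient design: regressor(s) %s are collinear with the others.",
                  paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qx, ctx$Yt)              # (p + 1) x n_roi
  predicted <- X %*% coefs                  # n_frames x n_roi
  rss <- colSums((ctx$Yt - predicted)^2)
  r2 <- 1 - rss / ctx$tss
  k <- p + 1L
  bic <- n * log(rss / n) + k * log(n)

  betas <- t(coefs[-1L, , drop = FALSE])    # n_roi x n_events
  colnames(betas) <- model$event
  rownames(betas) <- bm$rois

  by_roi <- tibble(
    roi = bm$rois, r2 = unname(r2), bic = unname(bic),
    intercept = unname(coefs[1L, ])
  )
  beta_cols <- as_tibble(betas)
  names(beta_cols) <- paste0("beta_", model$event)
  by_roi <- dplyr::bind_cols(by_roi, beta_cols)

  aggregates <- dplyr::bind_rows(
    dplyr::mutate(aggregate_scores(setNames(unname(r2), bm$rois), roi_weights),
                  metric = "r2", .before = 1),
    dplyr::mutate(aggregate_scores(setNames(unname(bic), bm$rois), roi_weights),
                  metric = "bic", .before = 1)
  )

  timecourses <- tibble(
    roi = rep(bm$rois, each = n),
    t = rep(bm$frame_times, times = length(bm$rois)),
    observed = as.vector(t(bm$values)),
    predicted = as.vector(predicted[, match(bm$rois, colnames(predicted)),
                                    drop = FALSE])
  )
  contributions <- purrr::map_dfr(seq_len(p), function(e) {
    contrib <- outer(R[, e], betas[, e])    # n_frames x n_roi
    tibble(
      roi = rep(bm$rois, each = n),
      t = rep(bm$frame_times, times = length(bm$rois)),
      event = model$event[e],
      value = as.vector(contrib)
    )
  })

  structure(
    list(by_roi = by_roi, aggregates = aggregates, betas = betas,
         timecourses = timecourses, contributions = contributions,
         model = model, hrf = hrf, tr = tr, weights = weights),
    class = "event_fit"
  )
}

#' @export
print.event_fit <- function(x, ...) {
  agg <- x$aggregates
  cat(sprintf("<event_fit> %d events, %d ROIs\n", nrow(x$model), nrow(x$by_roi)))
  cat(sprintf("  R2  : mean %.4f, median %.4f, min %.4f, weighted %.4f\n",
              agg$mean[1], agg$median[1], agg$min[1], agg$weighted[1]))
  cat(sprintf("  BIC : mean %.2f, median %.2f, min %.2f, weighted %.2f\n",
              agg$mean[2], agg$median[2], agg$min[2], agg$weighted[2]))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x,object An `event_fit`.
#' @param ... Unused.
#' @method glance event_fit
#' @export
glance.event_fit <- function(x, ...) {
  agg <- x$aggregates
  tibble(
    r2_mean = agg$mean[1], r2_median = agg$median[1],
    r2_min = agg$min[1], r2_weighted = agg$weighted[1],
    bic_mean = agg$mean[2], bic_median = agg$median[2],
    bic_min = agg$min[2], bic_weighted = agg$weighted[2],
    n_roi = nrow(x$by_roi), n_events = nrow(x$model)
  )
}

#' @rdname evaluate_model
#' @method tidy event_fit
#' @export
tidy.event_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(x$by_roi, "roi", "intercept",
                  dplyr::starts_with("beta_")),
    cols = -"roi", names_to = "term", values_to = "estimate"
  )
  dplyr::mutate(long, term = sub("^beta_", "", .data$term))
}

#' Weighted-R2 fitness of an event model
#'
#' Thin wrapper around [evaluate_model()] returning only the weighted
#' R-squared aggregate, the objective maximised by [optimize_events()].
#'
#' @inheritParams evaluate_model
#' @return A single number, the ROI-weight-averaged R-squared.
#' @export
fitness <- function(model, bold, tr, hrf = hrf_spec(tr = tr),
                    roi_weights = NULL) {
  fit <- evaluate_model(bold, model, tr, hrf = hrf, roi_weights = roi_weights)
  fit$aggregates$weighted[fit$aggregates$metric == "r2"]
}
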