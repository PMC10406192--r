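## internal validators shared across modules

.assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

## Validate an event-model table (columns event, start_time, duration) and
## return it as a tibble with those three columns in canonical order.
.as_event_model <- function(model, arg = "model") {
  if (!is.data.frame(model)) abort(sprintf("`%s` must be a data frame.", arg))
  .require_columns(model, c("event", "start_time", "duration"),
                   sprintf("`%s`", arg))
  out <- tibble(
    event = as.character(model$event),
    start_time = as.numeric(model$start_time),
    duration = as.numeric(model$duration)
  )
  if (nrow(out) == 0) abort(sprintf("`%s` must contain at least one event.", arg))
  if (anyDuplicated(out$event)) {
    abort(sprintf("`%s` has duplicated event names: %s.", arg,
                  paste(unique(out$event[duplicated(out$event)]), collapse = ", ")))
  }
  if (any(!is.finite(out$start_time)) || any(out$start_time < 0)) {
    abort(sprintf("`%s`: start_time must be finite and >= 0.", arg))
  }
  if (any(!is.finite(out$duration)) || any(out$duration <= 0)) {
    abort(sprintf("`%s`: duration must be finite and > 0.", arg))
  }
  out
}

## Pivot a long BOLD table (roi, t, y) into an ROI x frame matrix, checking
## the frame grid is complete, uniform with spacing tr, and anchored at t = 0.
.as_bold_matrix <- function(bold, tr, tol = 1e-6) {
  if (!is.data.frame(bold)) abort("`bold` must be a data frame.")
  .require_columns(bold, c("roi", "t", "y"), "`bold`")
  .assert_scalar_num(tr, "tr", positive = TRUE)
  roi <- as.character(bold$roi)
  t <- as.numeric(bold$t)
  y <- as.numeric(bold$y)
  if (any(!is.finite(y))) abort("`bold`: column y contains missing or non-finite values.")
  if (any(!is.finite(t))) abort("`bold`: column t contains missing or non-finite values.")

  rois <- unique(roi)
  frame_times <- sort(unique(t))
  n_frames <- length(frame_times)
  if (n_frames < 2) abort("`bold` must contain at least two frames per ROI.")
  spacing <- diff(frame_times)
  if (any(abs(spacing - tr) > tol * max(1, tr))) {
    abort(sprintf("non-uniform frame times: spacing deviates from tr = %g (observed range %g-%g).",
                  tr, min(spacing), max(spacing)))
  }
  if (abs(frame_times[1]) > tol) {
    abort(sprintf("frame times must start at t = 0 (observed first frame t = %g).",
                  frame_times[1]))
  }

  key <- paste(roi, format(t, digits = 15), sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort(sprintf("duplicate (roi, t) row in `bold`: roi = %s, t = %g.", roi[d], t[d]))
  }
  if (nrow(bold) != length(rois) * n_frames) {
    full <- expand.grid(roi = rois, t = frame_times, stringsAsFactors = FALSE)
    full_key <- paste(full$roi, format(full$t, digits = 15), sep = "\r")
    miss <- which(!(full_key %in% key))[1]
    abort(sprintf("`bold` is missing a value for roi = %s at t = %g.",
                  full$roi[miss], full$t[miss]))
  }

  values <- matrix(NA_real_, nrow = length(rois), ncol = n_frames,
                   dimnames = list(rois, NULL))
  values[cbind(match(roi, rois), match(t, frame_times))] <- y
  list(rois = rois, frame_times = frame_times, values = values,
       tr = tr, n_frames = n_frames)
}

## Resolve per-ROI weights from a (roi, weight) data frame or a named numeric
## vector; unlisted ROIs default to weight 1.
.resolve_weights <- function(rois, roi_weights) {
  w <- rep(1, length(rois))
  names(w) <- rois
  if (is.null(roi_weights)) return(w)
  if (is.data.frame(roi_weights)) {
    .require_columns(roi_weights, c("roi", "weight"), "`roi_weights`")
    nm <- as.character(roi_weights$roi)
    val <- as.numeric(roi_weights$weight)
  } else if (is.numeric(roi_weights) && !is.null(names(roi_weights))) {
    nm <- names(roi_weights)
    val <- as.numeric(roi_weights)
  } else {
    abort("`roi_weights` must be a data frame with columns roi, weight or a named numeric vector.")
  }
  if (any(!is.finite(val)) || any(val < 0)) {
    abort("`roi_weights`: weights must be finite and >= 0.")
  }
  unknown <- setdiff(nm, rois)
  if (length(unknown) > 0) {
    abort(sprintf("`roi_weights` refers to ROI(s) absent from the data: %s.",
                  paste(unknown, collapse = ", ")))
  }
  w[nm] <- val
  if (all(w == 0)) abort("`roi_weights`: at least one ROI must have a strictly positive weight.")
  w
}
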