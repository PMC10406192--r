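#' Plot observed and fitted BOLD time series for an evaluated model
#'
#' One panel per ROI showing the observed BOLD series, the fitted series,
#' and each event's fitted contribution (`beta * regressor`).
#'
#' @param object An `event_fit` from [evaluate_model()].
#' @param rois Optional character vector restricting the panels to a subset
#'   of ROIs.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_fit
#' @export
autoplot.event_fit <- function(object, rois = NULL, ...) {
  tc <- object$timecourses
  contrib <- object$contributions
  if (!is.null(rois)) {
    tc <- dplyr::filter(tc, .data$roi %in% rois)
    contrib <- dplyr::filter(contrib, .data$roi %in% rois)
    if (nrow(tc) == 0) abort("none of the requested ROIs are in the fit.")
  }
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(data = contrib,
                       ggplot2::aes(y = .data$value, colour = .data$event),
                       linewidth = 0.4, alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "#d66a84",
                       linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$roi), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "BOLD signal", colour = "event",
                  title = "Observed (black), fitted (pink) and per-event contributions") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fitness
#' @method autoplot event_search
#' @export
autoplot.event_search <- function(object, ...) {
  plot_fitness(object)
}

#' Plot the convergence of an event-timing search
#'
#' Shows the best weighted R-squared in the population at each iteration,
#' one line per constraint set. A trace that is still rising at the final
#' iteration indicates the search has not converged and should be resumed
#' or re-run with more iterations or a larger population.
#'
#' @param res An `event_search` from [optimize_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fitness <- function(res, ...) {
  tr <- fitness_trace(res)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                   colour = .data$constraint_set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = expression("best weighted" ~ R^2),
                  colour = "constraints") +
    ggplot2::theme_minimal()
}

#' Plot the best model found for each constraint set
#'
#' For every constraint set, shows each event's HRF-convolved regressor
#' (coloured lines), their sum (black), and the event's onset/duration as a
#' rectangle along the time axis.
#'
#' @param res An `event_search` from [optimize_events()].
#' @param n_frames Number of frames over which to draw the responses;
#'   defaults to covering the latest event offset plus the HRF length.
#' @return A ggplot object.
#' @export
plot_best_models <- function(res, n_frames = NULL) {
  if (!inherits(res, "event_search")) abort("`res` must be an event_search object.")
  hrf <- res$config$hrf
  tr <- res$config$tr
  dat <- purrr::map_dfr(res$results, function(r) {
    m <- r$best_model
    if (is.null(n_frames)) {
      horizon <- max(m$start_time + m$duration) +
        (if (hrf$method == "spm") hrf$p_spm$length else hrf$p_boynton$length)
      nf <- ceiling(horizon / tr) + 1L
    } else nf <- n_frames
    bm <- list(rois = "x", frame_times = (seq_len(nf) - 1) * tr,
               values = matrix(0, 1, nf), tr = tr, n_frames = nf)
    ctx <- .eval_ctx(bm, hrf, 1)
    R <- .ctx_regressors(ctx, m$start_time, m$duration, m$event)
    times <- (seq_len(nrow(R)) - 1) * tr
    dplyr::bind_rows(
      tibble(set = r$set, t = rep(times, ncol(R)),
             event = rep(m$event, each = nrow(R)), value = as.vector(R)),
      tibble(set = r$set, t = times, event = "total", value = rowSums(R))
    )
  })
  boxes <- purrr::map_dfr(res$results, function(r) {
    dplyr::mutate(r$best_model, set = r$set)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(data = dplyr::filter(dat, .data$event != "total"),
                       ggplot2::aes(colour = .data$event)) +
    ggplot2::geom_line(data = dplyr::filter(dat, .data$event == "total"),
                       colour = "black") +
    ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_time,
                   xmax = .data$start_time + .data$duration,
                   fill = .data$event),
      ymin = -0.08, ymax = -0.02, alpha = 0.8
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$set)) +
    ggplot2::labs(x = "time (s)", y = "modelled response", colour = "event",
                  fill = "event") +
    ggplot2::theme_minimal()
}

#' Plot an HRF kernel
#'
#' @param object An `hrf_kernel` from [generate_hrf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hrf_kernel
#' @export
autoplot.hrf_kernel <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$t, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "response (peak-normalised)") +
    ggplot2::theme_minimal()
}
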