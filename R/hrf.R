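#' Specify a haemodynamic response function
#'
#' Describes how the HRF kernel used to build event regressors is sampled.
#' Two canonical shapes are supported: the Boynton single-gamma response and
#' the SPM-style double-gamma response (a positive gamma lobe followed by an
#' undershoot). The kernel is sampled on a high-resolution grid with step
#' `tr / f` and is peak-normalised, so the maximum of the sampled kernel is
#' exactly 1.
#'
#' @param method HRF shape, `"spm"` (double gamma, the default) or
#'   `"boynton"` (single gamma).
#' @param tr Repetition time of the BOLD acquisition in seconds.
#' @param f Integer up-sampling factor; the kernel (and the neural time
#'   series it is convolved with) are sampled at step `tr / f`.
#' @param p_boynton Named list of single-gamma parameters: `shape` (integer
#'   gamma shape `n`), `tau` (time scale, s), `delay` (pure onset delay, s)
#'   and `length` (kernel length, s). Defaults follow the canonical
#'   parameterisation (`n = 3`, `tau = 1.2`, no onset delay). The mode of the
#'   response sits at `delay + (shape - 1) * tau`.
#' @param p_spm Named list of double-gamma parameters: `peak_delay` and
#'   `peak_disp` for the positive lobe, `undershoot_delay` and
#'   `undershoot_disp` for the undershoot, `ratio` (peak:undershoot amplitude
#'   ratio) and `length` (kernel length, s). With the defaults
#'   (`peak_delay = 6`, `peak_disp = 1`) the kernel attains its maximum at
#'   `peak_delay - peak_disp = 5` s, the default time-to-peak.
#'
#' @return An object of class `hrf_spec`.
#' @seealso [generate_hrf()], [shift_time_to_peak()]
#' @examples
#' spec <- hrf_spec("spm", tr = 1, f = 100)
#' k <- generate_hrf(spec)
#' k$time[which.max(k$values)] # 5 s
#' @export
hrf_spec <- function(method = c("spm", "boynton"), tr = 1, f = 100,
                     p_boynton = list(), p_spm = list()) {
  method <- match.arg(method)
  .assert_scalar_num(tr, "tr", positive = TRUE)
  f <- .assert_count(f, "f", min = 1L)

  pb_default <- list(shape = 3, tau = 1.2, delay = 0, length = 32)
  ps_default <- list(peak_delay = 6, peak_disp = 1,
                     undershoot_delay = 16, undershoot_disp = 1,
                     ratio = 6, length = 32)
  pb <- utils::modifyList(pb_default, p_boynton)
  ps <- utils::modifyList(ps_default, p_spm)
  unknown <- c(setdiff(names(p_boynton), names(pb_default)),
               setdiff(names(p_spm), names(ps_default)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown HRF parameter(s): %s.", paste(unknown, collapse = ", ")))
  }
  for (nm in c("shape", "tau", "length")) {
    .assert_scalar_num(pb[[nm]], paste0("p_boynton$", nm), positive = TRUE)
  }
  .assert_scalar_num(pb$delay, "p_boynton$delay", nonneg = TRUE)
  for (nm in c("peak_delay", "peak_disp", "undershoot_delay",
               "undershoot_disp", "ratio", "length")) {
    .assert_scalar_num(ps[[nm]], paste0("p_spm$", nm), positive = TRUE)
  }

  structure(
    list(method = method, tr = tr, f = f, p_boynton = pb, p_spm = ps),
    class = "hrf_spec"
  )
}

#' @export
print.hrf_spec <- function(x, ...) {
  cat(sprintf("<hrf_spec> method = %s, tr = %g s, f = %d (step %g s)\n",
              x$method, x$tr, x$f, x$tr / x$f))
  p <- if (x$method == "spm") x$p_spm else x$p_boynton
  cat("  parameters:", paste(sprintf("%s = %g", names(p), unlist(p)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Sample an HRF kernel
#'
#' Evaluates the HRF described by an [hrf_spec()] on the grid
#' `0, tr/f, 2 tr/f, ...` up to the configured kernel length, and
#' peak-normalises it so `max(values) == 1`.
#'
#' The double-gamma kernel is the difference of two gamma densities,
#' `dgamma(t, peak_delay / peak_disp, scale = peak_disp) -
#'  dgamma(t, undershoot_delay / undershoot_disp, scale = undershoot_disp) / ratio`;
#' the single-gamma kernel is the gamma density with integer shape `n` and
#' scale `tau`, evaluated at `t - delay`.
#'
#' @param spec An [hrf_spec()].
#' @return An object of class `hrf_kernel`: a list with `values` (sampled,
#'   peak-normalised kernel), `time` (sampling grid in seconds) and `step`
#'   (`tr / f`, seconds).
#' @examples
#' k <- generate_hrf(hrf_spec("boynton", tr = 2))
#' all(k$values >= 0)
#' @export
generate_hrf <- function(spec) {
  if (!inherits(spec, "hrf_spec")) abort("`spec` must be created with hrf_spec().")
  step <- spec$tr / spec$f
  len <- if (spec$method == "spm") spec$p_spm$length else spec$p_boynton$length
  t <- seq(0, len, by = step)
  h <- if (spec$method == "spm") {
    p <- spec$p_spm
    dgamma(t, shape = p$peak_delay / p$peak_disp, scale = p$peak_disp) -
      dgamma(t, shape = p$undershoot_delay / p$undershoot_disp,
             scale = p$undershoot_disp) / p$ratio
  } else {
    p <- spec$p_boynton
    dgamma(t - p$delay, shape = p$shape, scale = p$tau)
  }
  m <- max(h)
  if (!is.finite(m) || m <= 0) {
    abort("HRF parameters yield a kernel with no positive lobe inside its length.")
  }
  structure(list(values = h / m, time = t, step = step), class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %d samples, step %g s, peak at %g s\n",
              length(x$values), x$step, x$time[which.max(x$values)]))
  invisible(x)
}

#' @method as_tibble hrf_kernel
#' @export
as_tibble.hrf_kernel <- function(x, ...) {
  tibble(t = x$time, h = x$values)
}

#' Retarget an HRF specification at a given time-to-peak
#'
#' Returns a copy of `spec` whose generated kernel attains its maximum at
#' `ttp` seconds (within one sample step). For the double-gamma this sets
#' `peak_delay = ttp + peak_disp` (the analytic mode of the positive lobe is
#' `peak_delay - peak_disp`); for the single gamma it adjusts the onset
#' delay so that `delay + (shape - 1) * tau = ttp`.
#'
#' @param spec An [hrf_spec()].
#' @param ttp Target time-to-peak in seconds; must be positive and
#'   representable within the kernel length (for the single gamma, also
#'   reachable with a non-negative onset delay).
#' @return A modified `hrf_spec`.
#' @examples
#' k <- generate_hrf(shift_time_to_peak(hrf_spec("spm"), 4))
#' k$time[which.max(k$values)] # 4 s
#' @export
shift_time_to_peak <- function(spec, ttp) {
  if (!inherits(spec, "hrf_spec")) abort("`spec` must be created with hrf_spec().")
  .assert_scalar_num(ttp, "ttp", positive = TRUE)
  if (spec$method == "spm") {
    if (ttp >= spec$p_spm$length) {
      abort(sprintf("ttp = %g s is not representable within the kernel length (%g s).",
                    ttp, spec$p_spm$length))
    }
    spec$p_spm$peak_delay <- ttp + spec$p_spm$peak_disp
  } else {
    if (ttp >= spec$p_boynton$length) {
      abort(sprintf("ttp = %g s is not representable within the kernel length (%g s).",
                    ttp, spec$p_boynton$length))
    }
    p <- spec$p_boynton
    delay <- ttp - (p$shape - 1) * p$tau
    if (delay < 0) {
      abort(sprintf("ttp = %g s is below the gamma mode (%g s); reduce shape or tau instead.",
                    ttp, (p$shape - 1) * p$tau))
    }
    spec$p_boynton$delay <- delay
  }
  spec
}
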