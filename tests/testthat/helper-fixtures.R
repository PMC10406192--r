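# Shared fixtures: a small three-event trial model, a matching amplitude
# table, and noiseless/noisy BOLD generated from them.

fix_model <- function() {
  data.frame(
    event = c("encoding", "delay", "response"),
    start_time = c(0, 2, 10),
    duration = c(1.5, 8, 3)
  )
}

fix_amplitudes <- function(n_roi = 10, seed = 7) {
  withr::with_seed(seed, {
    data.frame(
      roi = sprintf("R%02d", seq_len(n_roi)),
      encoding = runif(n_roi, 0.5, 1.5),
      delay = runif(n_roi, 0.5, 1.5),
      response = runif(n_roi, 0.5, 1.5)
    )
  })
}

fix_bold <- function(noise_sd = 0, n_roi = 10, n_frames = 28, seed = 11,
                     ttp = 5) {
  simulate_bold(simulation_spec(
    fix_model(), fix_amplitudes(n_roi), hrf_ttp = ttp, noise_sd = noise_sd,
    tr = 1, n_frames = n_frames, seed = seed
  ))
}

fix_constraints <- function() {
  # windows equal to the generating timeline (a "strict" search)
  data.frame(
    event = c("encoding", "delay", "response"),
    start_time = c(0, 2, 10),
    end_time = c(1.5, 10, 13)
  )
}

# brute-force OLS via the normal equations, independent of fit_roi
ne_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# direct O(n * m) convolution sum, independent of stats::convolve and of the
# cumulative-sum fast path
direct_conv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  out <- numeric(n)
  for (i in seq_along(x)) {
    out[i:(i + length(k) - 1L)] <- out[i:(i + length(k) - 1L)] + x[i] * k
  }
  out
}
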