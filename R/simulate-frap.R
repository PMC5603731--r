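#' Parameter set for a simulated FRAP trace
#'
#' Bundles and validates the generator settings for [simulate_frap_trace()].
#' The defaults mirror a typical spinning-disk acquisition of a mobile
#' nuclear protein: 8 frames per second, 50 pre-bleach and 1000 post-bleach
#' frames, a bleach that removes 70% of the spot intensity, mild
#' acquisition photobleaching, and shot-noise-like Gaussian fluctuation.
#'
#' The recovery is biexponential: a fraction `amplitude_fast` recovers at
#' rate `rate_fast` (1/s), `amplitude_slow` at `rate_slow`, and
#' `1 - amplitude_fast - amplitude_slow` is immobile on the timescale of
#' the experiment. All three components must lie in \[0, 1\].
#'
#' @param amplitude_fast,amplitude_slow Mobile amplitudes (unitless
#'   fractions of the bleached signal).
#' @param rate_fast,rate_slow Recovery rate constants (1/s); `rate_fast`
#'   need not exceed `rate_slow`, components are interpreted by position.
#' @param bleach_depth Fraction of pre-bleach spot intensity remaining
#'   immediately after the bleach, in (0, 1].
#' @param acquisition_bleach_rate Whole-cell photobleaching rate during
#'   imaging (1/s); applied multiplicatively as `exp(-rate * t)` to both
#'   channels from the first acquired frame.
#' @param noise_sd Standard deviation of additive Gaussian noise, on the
#'   scale of a pre-bleach spot intensity of 1.
#' @param frame_rate Acquisition rate (frames/s).
#' @param n_prebleach,n_postbleach Number of pre- and post-bleach frames.
#' @param seed Integer seed making the trace reproducible.
#'
#' @return A list of class `frap_sim_params`.
#' @seealso [simulate_frap_trace()]
#' @export
frap_sim_params <- function(amplitude_fast = 0.5,
                            rate_fast = 2,
                            amplitude_slow = 0.3,
                            rate_slow = 0.3,
                            bleach_depth = 0.3,
                            acquisition_bleach_rate = 0.002,
                            noise_sd = 0.02,
                            frame_rate = 8,
                            n_prebleach = 50,
                            n_postbleach = 1000,
                            seed = 1L) {
  check_scalar(amplitude_fast, "amplitude_fast", 0, 1)
  check_scalar(amplitude_slow, "amplitude_slow", 0, 1)
  if (amplitude_fast + amplitude_slow > 1 + 1e-12) {
    abort("`amplitude_fast` + `amplitude_slow` must not exceed 1.")
  }
  check_scalar(rate_fast, "rate_fast", 0, open_lower = TRUE)
  check_scalar(rate_slow, "rate_slow", 0, open_lower = TRUE)
  check_scalar(bleach_depth, "bleach_depth", 0, 1, open_lower = TRUE)
  check_scalar(acquisition_bleach_rate, "acquisition_bleach_rate", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(frame_rate, "frame_rate", 0, open_lower = TRUE)
  check_count(n_prebleach, "n_prebleach", min = 2L)
  check_count(n_postbleach, "n_postbleach", min = 1L)
  structure(
    list(
      amplitude_fast = amplitude_fast, rate_fast = rate_fast,
      amplitude_slow = amplitude_slow, rate_slow = rate_slow,
      bleach_depth = bleach_depth,
      acquisition_bleach_rate = acquisition_bleach_rate,
      noise_sd = noise_sd, frame_rate = frame_rate,
      n_prebleach = as.integer(n_prebleach),
      n_postbleach = as.integer(n_postbleach),
      seed = as.integer(seed)
    ),
    class = "frap_sim_params"
  )
}

#' Simulate one FRAP trace
#'
#' Generates a single-cell bleach-spot / whole-cell intensity time series
#' with the structure the FRAP analysis chain assumes: a stationary
#' pre-bleach segment, an instantaneous bleach to
#' `bleach_depth * prebleach mean`, biexponential recovery of the mobile
#' fraction, a shared whole-cell acquisition-photobleaching decay on both
#' channels, and homoscedastic Gaussian noise.
#'
#' The noiseless spot intensity at time `t` after the bleach is
#' `(d + (1 - d) * (A1 * (1 - exp(-k1 t)) + A2 * (1 - exp(-k2 t)))) *
#' exp(-lambda * t_total)` where `d` is the bleach depth and `t_total` is
#' the time since the first acquired frame; the whole-cell channel carries
#' only the `exp(-lambda * t_total)` decay.
#'
#' @param params A [frap_sim_params()] object.
#' @return A tibble of class `frap_trace` with columns `time` (s),
#'   `roi_intensity`, `cell_intensity`, `background`, and attributes
#'   `bleach_index` (first post-bleach frame, 1-based) and `params`.
#' @examples
#' tr <- simulate_frap_trace(frap_sim_params(seed = 7))
#' head(tr)
#' @export
simulate_frap_trace <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_prebleach + p$n_postbleach
  time <- (seq_len(n) - 1) / p$frame_rate
  bleach_index <- p$n_prebleach + 1L
  t_post <- time - time[bleach_index]

  recovery <- rep(1, n)
  post <- seq(bleach_index, n)
  recovery[post] <- p$bleach_depth + (1 - p$bleach_depth) * (
    p$amplitude_fast * (1 - exp(-p$rate_fast * t_post[post])) +
      p$amplitude_slow * (1 - exp(-p$rate_slow * t_post[post]))
  )
  decay <- exp(-p$acquisition_bleach_rate * time)
  roi <- recovery * decay + rnorm(n, 0, p$noise_sd)
  cell <- decay + rnorm(n, 0, p$noise_sd)

  out <- tibble(
    time = time,
    roi_intensity = roi,
    cell_intensity = cell,
    background = 0
  )
  structure(out,
    bleach_index = bleach_index,
    params = p,
    class = c("frap_trace", class(out))
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf(
    "<frap_trace> %d frames, bleach at frame %d\n",
    nrow(x), attr(x, "bleach_index")
  ))
  NextMethod()
}
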