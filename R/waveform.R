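#' Synthetic arterial pressure waveform
#'
#' A periodic pressure trace whose time average over whole cardiac cycles is
#' exactly `mean`: the pulsatile component is a sum of zero-mean harmonics.
#' `shape = "sine"` is a pure sinusoid; `shape = "pulse"` adds second and
#' third harmonics for a steeper systolic upstroke, still zero-mean per
#' cycle.
#'
#' @param mean Mean pressure (mmHg by convention; any unit is carried
#'   through unchanged).
#' @param amplitude Peak amplitude of the fundamental harmonic.
#' @param period Cycle length in seconds (> 0).
#' @param n_cycles Number of whole cycles to generate (>= 1).
#' @param dt Sampling interval in seconds (> 0).
#' @param shape `"sine"` or `"pulse"`.
#' @return A tibble with columns `time` (s) and `pressure`.
#' @examples
#' wf <- pressure_waveform(mean = 100, amplitude = 20, period = 0.8)
#' mean_pressure(wf) # 100 up to quadrature error
#' @export
pressure_waveform <- function(mean = 100, amplitude = 20, period = 0.8,
                              n_cycles = 5, dt = period / 200,
                              shape = c("sine", "pulse")) {
  shape <- match.arg(shape)
  check_scalar(mean, "mean")
  check_scalar(amplitude, "amplitude", nonneg = TRUE)
  check_scalar(period, "period", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) abort("`n_cycles` must be >= 1.")
  t <- seq(0, n_cycles * period, by = dt)
  ph <- 2 * pi * t / period
  pulse <- sin(ph)
  if (shape == "pulse") pulse <- pulse + 0.35 * sin(2 * ph + 0.4) + 0.15 * sin(3 * ph + 0.8)
  tibble(time = t, pressure = mean + amplitude * pulse)
}
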