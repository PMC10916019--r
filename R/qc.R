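#' Detect cells that stop beating during recording
#'
#' Cells that cease to move while trapped are in distress and must be
#' excluded before group statistics. With no simultaneous video available,
#' cessation is detected from the force trace itself: the trace is
#' band-limited to the beating band (default 0-30 Hz, DC excluded), split
#' into contiguous windows of `window_s`, and each window's RMS force is
#' compared against `threshold_nN`. A cell passes when the fraction of
#' active windows is at least `min_active_fraction` *and* the trace does
#' not end with an inactive run longer than `cessation_grace_s` (a cell
#' that goes quiet and stays quiet to the end has ceased, whatever its
#' earlier activity).
#'
#' All thresholds are instrument- and preparation-dependent operational
#' choices, validated on the synthetic generator; they are not derived
#' from any reference measurement.
#'
#' @param force A [force_trace()] with the baseline removed.
#' @param band Length-2 numeric, beating band in Hz (within Nyquist).
#' @param window_s RMS window length in seconds (< duration).
#' @param threshold_nN A window is "active" when its RMS force is at least
#'   this value.
#' @param min_active_fraction Minimum fraction of active windows to pass.
#' @param cessation_grace_s Longest tolerated inactive run at the end of
#'   the trace before the cell is declared to have ceased beating.
#'
#' @return A one-row tibble: `cell_id`, `passed`, `active_fraction`,
#'   `cessation_time_s` (start of the terminal inactive run, `NA` if the
#'   trace ends active), `window_s`, `threshold_nN`.
#' @export
assess_motility <- function(force, band = c(0, 30), window_s = 5,
                            threshold_nN = 0.05, min_active_fraction = 0.5,
                            cessation_grace_s = 10) {
  if (!inherits(force, "force_trace")) abort("`force` must be a force_trace.")
  meta <- trace_meta(force)
  fs <- meta$sampling_rate_hz
  if (length(band) != 2L || band[2] <= band[1] || band[1] < 0) {
    abort("`band` must be (lo, hi) with 0 <= lo < hi.")
  }
  if (band[2] > fs / 2) abort("`band` exceeds the Nyquist frequency.")
  if (window_s <= 0 || window_s >= meta$duration_s) {
    abort("Require 0 < window_s < duration.")
  }
  if (threshold_nN < 0) abort("`threshold_nN` must be non-negative.")

  one_band <- make_band_scheme(band[1], band[2], band[2] - band[1])
  sig <- band_decompose(force, one_band)[[one_band$label]]

  wlen <- as.integer(round(window_s * fs))
  n_win <- length(sig) %/% wlen
  if (n_win < 1L) abort("Trace shorter than one window.")
  idx <- rep(seq_len(n_win), each = wlen)
  rms <- sqrt(tapply(sig[seq_along(idx)]^2, idx, mean))
  active <- rms >= threshold_nN

  active_fraction <- mean(active)
  cessation_time_s <- NA_real_
  ceased <- FALSE
  if (!active[n_win]) {
    run_start <- n_win
    while (run_start > 1L && !active[run_start - 1L]) run_start <- run_start - 1L
    cessation_time_s <- (run_start - 1L) * window_s
    ceased <- (meta$duration_s - cessation_time_s) > cessation_grace_s
  }
  tibble(
    cell_id = meta$cell_id,
    passed = active_fraction >= min_active_fraction && !ceased,
    active_fraction = active_fraction,
    cessation_time_s = cessation_time_s,
    window_s = window_s,
    threshold_nN = threshold_nN
  )
}
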