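# Per-bin absolute frequency for an n-point DFT sampled at fs:
# bin j (0-based) sits at j*fs/n for j <= n/2 and mirrors above.
dft_abs_freq <- function(n, fs) {
  j <- 0:(n - 1)
  j[j > n / 2] <- n - j[j > n / 2]
  j * fs / n
}

# Logical mask over DFT bins for a half-open band [lo, hi), DC always
# excluded. Matching on |f| keeps conjugate-symmetric partners together so
# the inverse transform is real.
band_bin_mask <- function(n, fs, lo, hi) {
  f <- dft_abs_freq(n, fs)
  f >= lo & f < hi & seq_len(n) != 1L
}

#' Decompose a force trace into frequency-band signals
#'
#' Isolates the contribution of each frequency band to the beating-force
#' signal by spectral masking: the trace is Fourier transformed once (full
#' complex spectrum, real and imaginary parts), every coefficient outside a
#' band's half-open range `[lo, hi)` is zeroed — keeping the
#' conjugate-symmetric negative-frequency partners so the inverse transform
#' is real — and the masked spectrum is inverse transformed back to the
#' time domain. The DC (0 Hz) coefficient is excluded from every band,
#' including the first: the static suction bending is a baseline, not a
#' beating force. Everything the scheme does not cover (DC plus
#' out-of-scheme frequencies) goes into a `residual_nN` column, so the band
#' columns and the residual always sum back to the input signal.
#'
#' No taper is applied before the transform (rectangular window); see
#' [band_max_force()] for the edge guard that compensates the resulting
#' edge ringing.
#'
#' @param force A [force_trace()] with `baseline_removed = TRUE`.
#' @param scheme A [make_band_scheme()]; `f_max` must not exceed the
#'   Nyquist frequency.
#'
#' @return A tibble of class `"band_signals"` with columns `time_s`,
#'   `force_nN` (the input), one column per band label, and `residual_nN`.
#'   The scheme and cell metadata travel as attributes.
#' @export
band_decompose <- function(force, scheme = make_band_scheme()) {
  if (!inherits(force, "force_trace")) abort("`force` must be a force_trace.")
  if (!isTRUE(attr(force, "baseline_removed", exact = TRUE))) {
    abort("Baseline not removed: run deflection_to_force() first.")
  }
  if (!inherits(scheme, "band_scheme")) abort("`scheme` must be a band_scheme.")
  fs <- sampling_rate(force)
  if (max(scheme$hi_hz) > fs / 2 + 1e-12) {
    abort(sprintf("Scheme reaches %g Hz but Nyquist is %g Hz.",
                  max(scheme$hi_hz), fs / 2))
  }
  x <- force$force_nN
  n <- length(x)
  spec <- stats::fft(x)
  scale <- max(abs(x), 1e-300)

  in_any <- rep(FALSE, n)
  bands <- lapply(seq_len(nrow(scheme)), function(i) {
    m <- band_bin_mask(n, fs, scheme$lo_hz[i], scheme$hi_hz[i])
    in_any <<- in_any | m
    masked <- complex(n)
    masked[m] <- spec[m]
    y <- stats::fft(masked, inverse = TRUE) / n
    if (max(abs(Im(y))) > 1e-9 * scale) {
      abort("Internal error: imaginary residue after inverse FFT exceeds tolerance.")
    }
    Re(y)
  })
  names(bands) <- scheme$label

  masked <- complex(n)
  masked[!in_any] <- spec[!in_any]
  resid <- Re(stats::fft(masked, inverse = TRUE) / n)

  out <- tibble(time_s = force$time_s, force_nN = x)
  for (lab in scheme$label) out[[lab]] <- bands[[lab]]
  out$residual_nN <- resid
  structure(
    out,
    meta = trace_meta(force), scheme = scheme,
    class = c("band_signals", class(tibble()))
  )
}

#' Per-band maximum beating force
#'
#' The core per-cell statistic: for each band-limited signal, the maximum
#' absolute force over the recording interval. The swimming direction of
#' the trapped cell cannot be controlled, the signal sign only reflects the
#' instantaneous thrust direction, and the amplitude of every band waxes
#' and wanes as the cell reorients — so the magnitude maximum over the
#' whole recording is the physically meaningful thrust estimate. A guard
#' interval at each end of the trace is excluded from the search because
#' rectangular spectral masking rings at the edges.
#'
#' @param signals A [band_decompose()] result.
#' @param guard_s Guard interval trimmed from each end, seconds
#'   (default 1; `2 * guard_s` must be smaller than the trace duration).
#' @param statistic `"max_abs"` (default) or `"peak_to_peak"`
#'   (max minus min, reported as is).
#'
#' @return A tibble of class `"band_force_profile"`: one row per band with
#'   `cell_id`, `band`, `lo_hz`, `hi_hz`, `max_force_nN`, `argmax_time_s`.
#' @export
band_max_force <- function(signals, guard_s = 1,
                           statistic = c("max_abs", "peak_to_peak")) {
  if (!inherits(signals, "band_signals")) {
    abort("`signals` must come from band_decompose().")
  }
  statistic <- match.arg(statistic)
  meta <- trace_meta(signals)
  scheme <- attr(signals, "scheme", exact = TRUE)
  duration <- meta$duration_s
  if (guard_s < 0 || 2 * guard_s >= duration) {
    abort("Require 0 <= guard_s and 2 * guard_s < trace duration.")
  }
  keep <- signals$time_s >= guard_s & signals$time_s <= duration - guard_s
  t_win <- signals$time_s[keep]
  res <- purrr::map_dfr(seq_len(nrow(scheme)), function(i) {
    v <- signals[[scheme$label[i]]][keep]
    i_max <- which.max(abs(v))
    value <- if (statistic == "max_abs") abs(v[i_max]) else max(v) - min(v)
    tibble(
      cell_id = meta$cell_id,
      band = scheme$label[i],
      lo_hz = scheme$lo_hz[i],
      hi_hz = scheme$hi_hz[i],
      max_force_nN = value,
      argmax_time_s = t_win[i_max]
    )
  })
  structure(res, class = c("band_force_profile", class(tibble())))
}
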