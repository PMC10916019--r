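#' Spring constant from thermal fluctuations (equipartition)
#'
#' Estimates the cantilever spring constant from the thermal motion of the
#' free lever. By equipartition the mean-square thermal displacement of the
#' tip satisfies `k <z^2> = kB T`, so
#' `k = beta * kB * T / Var(z)` with `Var` the unbiased sample variance
#' after mean removal and `kB = 1.380649e-5 nN nm / K`. `beta` is a
#' dimensionless mode-shape correction: the default 1 treats the lever as
#' an ideal point mass; the standard first-flexural-mode value for a
#' rectangular cantilever (~0.817) can be supplied when calibrating real
#' probes.
#'
#' @param deflection_nm Numeric vector of tip deflection in nm, or a data
#'   frame with a `deflection_nm` column (as returned by
#'   [generate_thermal_trace()]). At least 1000 samples.
#' @param temperature_K Bath temperature in kelvin (> 0).
#' @param beta Dimensionless correction factor (> 0), default 1.
#'
#' @return A one-row tibble of class `"thermal_calibration"` with columns
#'   `spring_constant_N_per_m` (numerically equal to nN/nm),
#'   `positional_variance_nm2`, `n_samples`, `temperature_K`, `beta`.
#' @examples
#' z <- generate_thermal_trace(0.3, 298, 10000, 2, seed = 1)
#' thermal_noise_spring_constant(z, 298)
#' @export
thermal_noise_spring_constant <- function(deflection_nm, temperature_K = 298,
                                          beta = 1) {
  if (is.data.frame(deflection_nm)) {
    if (!"deflection_nm" %in% names(deflection_nm)) {
      abort("Data frame input must have a `deflection_nm` column.")
    }
    deflection_nm <- deflection_nm$deflection_nm
  }
  if (!is.numeric(deflection_nm)) abort("`deflection_nm` must be numeric.")
  if (length(deflection_nm) < 1000L) {
    abort("Thermal calibration needs at least 1000 samples.")
  }
  if (!is.numeric(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be positive.")
  }
  if (!is.numeric(beta) || beta <= 0) abort("`beta` must be positive.")
  v <- stats::var(deflection_nm) # unbiased, mean removed
  if (v <= 0 || !is.finite(v)) {
    abort("Degenerate input: deflection series has zero variance.")
  }
  k <- beta * KB_NN_NM_PER_K * temperature_K / v
  structure(
    tibble(
      spring_constant_N_per_m = k,
      positional_variance_nm2 = v,
      n_samples = length(deflection_nm),
      temperature_K = temperature_K,
      beta = beta
    ),
    class = c("thermal_calibration", class(tibble()))
  )
}

#' Convert a deflection trace to a force trace
#'
#' Applies the standard optical-beam-deflection conversion
#' `F[nN] = V[volt] * S[nm/volt] * K[nN/nm]` sample by sample, then removes
#' the static bending baseline caused by the residual suction holding the
#' cell: that bending is constant over the recording and carries no beating
#' information, so it is subtracted before any spectral analysis.
#'
#' @param trace A [deflection_trace()].
#' @param baseline Baseline model: `"mean"` (default) subtracts the
#'   full-trace mean; `"linear"` removes a least-squares linear drift;
#'   `"none"` keeps the raw converted force (e.g. to inspect the suction
#'   offset) and leaves `baseline_removed = FALSE`.
#'
#' @return A [force_trace()] with `baseline_removed = TRUE` unless
#'   `baseline = "none"`.
#' @examples
#' tr <- generate_cell_trace(linear_profile(), cell_meta("c1", duration_s = 2),
#'                           calibration_constants(), seed = 1)
#' deflection_to_force(tr)
#' @export
deflection_to_force <- function(trace, baseline = c("mean", "linear", "none")) {
  if (!inherits(trace, "deflection_trace")) {
    abort("`trace` must be a deflection_trace.")
  }
  baseline <- match.arg(baseline)
  calib <- trace_calib(trace)
  s <- calib$sensitivity_nm_per_V
  k <- calib$spring_constant_nN_per_nm
  if (!is.finite(s) || s <= 0 || !is.finite(k) || k <= 0) {
    abort("Calibration error: S and K must be positive.")
  }
  f <- trace$deflection_V * s * k
  removed <- baseline != "none"
  if (baseline == "mean") {
    f <- f - mean(f)
  } else if (baseline == "linear") {
    f <- stats::lm.fit(cbind(1, trace$time_s), f)$residuals
  }
  force_trace(
    tibble(time_s = trace$time_s, force_nN = f),
    meta = trace_meta(trace),
    baseline_removed = removed
  )
}
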