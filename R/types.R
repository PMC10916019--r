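#' Per-cell acquisition metadata
#'
#' Describes one trapped cell: its identity, motility phenotype, the region
#' of the cell held by the microfluidic probe, the semen-sample motility
#' group it came from, the residual trapping pressure during recording, and
#' the acquisition grid.
#'
#' @param cell_id Character scalar, unique within a dataset.
#' @param phenotype `"linear"` or `"circular"` swimming behaviour.
#' @param trap_region `"tail"`, `"midpiece"` or `"head"`.
#' @param sample_group `"prog100"` (100% progressive sample) or
#'   `"prog80_20"` (80-20% progressive sample).
#' @param trap_pressure_mbar Residual pressure holding the cell, in mbar
#'   (negative = suction). Metadata only; not used in any computation.
#' @param sampling_rate_hz Sampling rate in Hz, must be positive.
#' @param duration_s Recording duration in seconds, must be positive.
#'
#' @return A list of class `"cell_meta"`.
#' @examples
#' cell_meta("cell_01", "linear", "tail", "prog100")
#' @export
cell_meta <- function(cell_id,
                      phenotype = c("linear", "circular"),
                      trap_region = c("tail", "midpiece", "head"),
                      sample_group = c("prog100", "prog80_20"),
                      trap_pressure_mbar = -20,
                      sampling_rate_hz = 1000,
                      duration_s = 120) {
  phenotype <- match.arg(phenotype)
  trap_region <- match.arg(trap_region)
  sample_group <- match.arg(sample_group)
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id)) {
    abort("`cell_id` must be a non-empty character scalar.")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive.")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.")
  }
  structure(
    list(
      cell_id = cell_id,
      phenotype = phenotype,
      trap_region = trap_region,
      sample_group = sample_group,
      trap_pressure_mbar = as.numeric(trap_pressure_mbar),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      duration_s = as.numeric(duration_s)
    ),
    class = "cell_meta"
  )
}

#' Cantilever calibration constants
#'
#' The two constants of the standard optical-beam-deflection force
#' conversion `F[nN] = V[volt] * S[nm/volt] * K[nN/nm]`, plus the bath
#' temperature used by the thermal-noise spring-constant calibration.
#' `K` in nN/nm is numerically equal to N/m.
#'
#' @param sensitivity_nm_per_V Deflection sensitivity S, nm per volt (> 0).
#' @param spring_constant_nN_per_nm Spring constant K, nN per nm (> 0).
#' @param temperature_K Bath temperature in kelvin (> 0).
#'
#' @return A list of class `"calibration_constants"`.
#' @examples
#' calibration_constants(20, 0.3)
#' @export
calibration_constants <- function(sensitivity_nm_per_V = 20,
                                  spring_constant_nN_per_nm = 0.3,
                                  temperature_K = 298) {
  for (nm in c("sensitivity_nm_per_V", "spring_constant_nN_per_nm",
               "temperature_K")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a positive finite scalar.", nm))
    }
  }
  structure(
    list(
      sensitivity_nm_per_V = as.numeric(sensitivity_nm_per_V),
      spring_constant_nN_per_nm = as.numeric(spring_constant_nN_per_nm),
      temperature_K = as.numeric(temperature_K)
    ),
    class = "calibration_constants"
  )
}

# Uniform-spacing check shared by the trace constructors. Tolerance 1e-9 s.
check_uniform_time <- function(time_s, sampling_rate_hz) {
  if (length(time_s) < 2L) abort("A trace needs at least two samples.")
  dt <- diff(time_s)
  if (any(dt <= 0)) abort("`time_s` must be strictly increasing.")
  if (max(abs(dt - 1 / sampling_rate_hz)) > 1e-9) {
    abort("`time_s` must be uniformly spaced at 1/sampling_rate_hz (tolerance 1e-9 s).")
  }
  invisible(TRUE)
}

#' Construct a raw deflection trace
#'
#' Bundles the photodetector voltage samples with the cell metadata and the
#' calibration constants needed to convert them to force. The sample block
#' is a tibble so the object pipes into dplyr/ggplot2 directly; metadata
#' travel as attributes and are read back with [trace_meta()] and
#' [trace_calib()].
#'
#' @param data Data frame with numeric columns `time_s` and `deflection_V`,
#'   uniformly sampled at `meta$sampling_rate_hz`.
#' @param meta A [cell_meta()] object.
#' @param calib A [calibration_constants()] object.
#'
#' @return A tibble of class `"deflection_trace"` with columns `time_s`,
#'   `deflection_V`.
#' @export
deflection_trace <- function(data, meta, calib) {
  stopifnot(inherits(meta, "cell_meta"), inherits(calib, "calibration_constants"))
  data <- as_tibble(data)
  if (!all(c("time_s", "deflection_V") %in% names(data))) {
    abort("`data` must have columns `time_s` and `deflection_V`.")
  }
  if (nrow(data) == 0L) abort("Empty sample block.")
  check_uniform_time(data$time_s, meta$sampling_rate_hz)
  n_expected <- round(meta$duration_s * meta$sampling_rate_hz)
  if (nrow(data) != n_expected) {
    abort(sprintf(
      "Trace has %d samples but duration_s x sampling_rate_hz = %d.",
      nrow(data), n_expected
    ))
  }
  structure(
    data[c("time_s", "deflection_V")],
    meta = meta, calib = calib,
    class = c("deflection_trace", class(tibble()))
  )
}

#' Construct a calibrated force trace
#'
#' Usually produced by [deflection_to_force()]; the constructor is exported
#' so that analytically known force signals can be fed straight into the
#' spectral module.
#'
#' @param data Data frame with numeric columns `time_s` and `force_nN`.
#' @param meta A [cell_meta()] object.
#' @param baseline_removed Logical; `TRUE` once the static bending baseline
#'   has been subtracted. [band_decompose()] requires `TRUE`.
#'
#' @return A tibble of class `"force_trace"`.
#' @export
force_trace <- function(data, meta, baseline_removed = FALSE) {
  stopifnot(inherits(meta, "cell_meta"), is.logical(baseline_removed))
  data <- as_tibble(data)
  if (!all(c("time_s", "force_nN") %in% names(data))) {
    abort("`data` must have columns `time_s` and `force_nN`.")
  }
  if (nrow(data) == 0L) abort("Empty sample block.")
  check_uniform_time(data$time_s, meta$sampling_rate_hz)
  structure(
    data[c("time_s", "force_nN")],
    meta = meta, baseline_removed = isTRUE(baseline_removed),
    class = c("force_trace", class(tibble()))
  )
}

#' Metadata accessors for trace objects
#'
#' @param x A `deflection_trace`, `force_trace` or `band_signals` object.
#' @return `trace_meta()` returns the [cell_meta()]; `trace_calib()` the
#'   [calibration_constants()] (deflection traces only); `sampling_rate()`
#'   the sampling rate in Hz.
#' @export
trace_meta <- function(x) attr(x, "meta", exact = TRUE)

#' @rdname trace_meta
#' @export
trace_calib <- function(x) attr(x, "calib", exact = TRUE)

#' @rdname trace_meta
#' @export
sampling_rate <- function(x) trace_meta(x)$sampling_rate_hz
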