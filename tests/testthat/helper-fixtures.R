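# Shared fixtures: everything is generated in code, nothing is stored.

quick_calib <- function() calibration_constants(20, 0.3, 298)

quick_meta <- function(cell_id = "cell", duration_s = 120,
                       sampling_rate_hz = 1000, ...) {
  cell_meta(cell_id, sampling_rate_hz = sampling_rate_hz,
            duration_s = duration_s, ...)
}

# A deflection trace whose underlying force is a pure tone (or a sum of
# tones) with known amplitude, bypassing the generator.
tone_deflection <- function(freq_hz, amp_nN, phase = 0, duration_s = 120,
                            sampling_rate_hz = 1000, cell_id = "tone",
                            calib = quick_calib()) {
  n <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  f <- rowSums(mapply(
    function(fr, a, ph) a * sin(2 * pi * fr * t + ph),
    freq_hz, amp_nN, phase
  ))
  v <- f / (calib$sensitivity_nm_per_V * calib$spring_constant_nN_per_nm)
  deflection_trace(
    tibble::tibble(time_s = t, deflection_V = v),
    quick_meta(cell_id, duration_s, sampling_rate_hz), calib
  )
}

# A force trace built directly from a numeric signal.
make_force <- function(x, sampling_rate_hz = 1000, cell_id = "sig",
                       baseline_removed = TRUE, ...) {
  n <- length(x)
  force_trace(
    tibble::tibble(time_s = (seq_len(n) - 1) / sampling_rate_hz, force_nN = x),
    quick_meta(cell_id, duration_s = n / sampling_rate_hz,
               sampling_rate_hz = sampling_rate_hz, ...),
    baseline_removed = baseline_removed
  )
}

# Small two-group cohort recipe for fast pipeline tests.
small_recipe <- function(n_lin = 3, n_cir = 3) {
  list(
    lin = list(n = n_lin, profile = linear_profile(), trap_region = "tail",
               sample_group = "prog80_20"),
    cir = list(n = n_cir, profile = circular_profile(), trap_region = "head",
               sample_group = "prog80_20")
  )
}
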