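#' Spectral components of a synthetic beat
#'
#' One row per oscillatory component of the flagellar thrust. Each
#' component is a sinusoid at `frequency_hz` whose amplitude is slowly
#' modulated at `am_rate_hz`, modelling the cell reorienting on the probe:
#' the full thrust registers only when the motion is perpendicular to the
#' cantilever plane, so each band's amplitude waxes and wanes and peaks at
#' its own time. `phase = NA` means "draw uniformly at generation time".
#'
#' @param frequency_hz Component frequency in Hz (>= 0, below Nyquist at
#'   generation time).
#' @param amplitude_nN Peak thrust amplitude in nN (>= 0).
#' @param phase Carrier phase in radians, or `NA` to randomize.
#' @param am_rate_hz Amplitude-modulation rate in Hz (>= 0, slow compared
#'   with `frequency_hz`); 0 disables modulation.
#'
#' @return A tibble with one row per component.
#' @export
beat_component <- function(frequency_hz, amplitude_nN, phase = NA_real_,
                           am_rate_hz = 0.05) {
  if (any(frequency_hz < 0)) abort("`frequency_hz` must be >= 0.")
  if (any(amplitude_nN < 0)) abort("`amplitude_nN` must be >= 0.")
  if (any(am_rate_hz < 0)) abort("`am_rate_hz` must be >= 0.")
  tibble(
    frequency_hz = as.numeric(frequency_hz),
    amplitude_nN = as.numeric(amplitude_nN),
    phase = as.numeric(phase),
    am_rate_hz = as.numeric(am_rate_hz)
  )
}

#' Phenotype-specific beat profile
#'
#' Everything the generator needs to emulate one motility phenotype: the
#' spectral components of the thrust, the static suction-induced bending
#' baseline, the sensor noise level, and the burst structure. Linearly
#' motile cells beat continuously (`burst_duty = 1`, numerous and frequent
#' oscillations); circularly motile cells produce fewer oscillations
#' separated in time, modelled as on/off bursts occupying `burst_duty` of
#' the recording in alternating exponential on/off runs with mean cycle
#' `burst_cycle_s`.
#'
#' @param name `"linear"` or `"circular"`.
#' @param components A [beat_component()] tibble.
#' @param baseline_offset_nN Constant suction-induced bending, nN.
#' @param noise_sd_nN Gaussian sensor noise SD, nN (>= 0).
#' @param burst_duty Fraction of time the cell actively beats, in [0, 1].
#' @param burst_cycle_s Mean on+off cycle length of the burst process, s.
#'
#' @return A list of class `"phenotype_profile"`.
#' @export
phenotype_profile <- function(name = c("linear", "circular"), components,
                              baseline_offset_nN = -1, noise_sd_nN = 0.02,
                              burst_duty = 1, burst_cycle_s = 6) {
  name <- match.arg(name)
  stopifnot(is.data.frame(components))
  if (!all(c("frequency_hz", "amplitude_nN", "phase", "am_rate_hz") %in%
           names(components))) {
    abort("`components` must come from beat_component().")
  }
  if (noise_sd_nN < 0) abort("`noise_sd_nN` must be >= 0.")
  if (burst_duty < 0 || burst_duty > 1) abort("`burst_duty` must be in [0, 1].")
  if (burst_cycle_s <= 0) abort("`burst_cycle_s` must be positive.")
  structure(
    list(
      name = name,
      components = as_tibble(components),
      baseline_offset_nN = as.numeric(baseline_offset_nN),
      noise_sd_nN = as.numeric(noise_sd_nN),
      burst_duty = as.numeric(burst_duty),
      burst_cycle_s = as.numeric(burst_cycle_s)
    ),
    class = "phenotype_profile"
  )
}

#' Default phenotype profiles
#'
#' `linear_profile()` places components at 1, 4, 7, 10, 13 and 25 Hz with
#' amplitudes decreasing from `low_band_amplitude_nN` (default 0.6 nN, the
#' reported human low-frequency beating force) and continuous beating.
#' `circular_profile()` uses the same frequencies at `scale` (default 40%)
#' of the linear amplitudes with burst beating at 30% duty, encoding the
#' observed ordering linear > circular with the strongest contrast at low
#' frequencies. Exact per-band spectra of real cells are not published;
#' these defaults are free parameters of the generator.
#'
#' @param low_band_amplitude_nN Amplitude of the lowest-frequency
#'   component, nN; the other components scale proportionally.
#' @param scale Circular-to-linear amplitude ratio.
#' @param ... Passed on to [phenotype_profile()].
#'
#' @return A [phenotype_profile()].
#' @export
linear_profile <- function(low_band_amplitude_nN = 0.6, ...) {
  rel <- c(0.6, 0.45, 0.35, 0.30, 0.25, 0.15) / 0.6
  phenotype_profile(
    "linear",
    beat_component(
      frequency_hz = c(1, 4, 7, 10, 13, 25),
      amplitude_nN = low_band_amplitude_nN * rel
    ),
    burst_duty = 1,
    ...
  )
}

#' @rdname linear_profile
#' @export
circular_profile <- function(scale = 0.4, low_band_amplitude_nN = 0.6, ...) {
  lin <- linear_profile(low_band_amplitude_nN)
  phenotype_profile(
    "circular",
    dplyr::mutate(lin$components, amplitude_nN = .data$amplitude_nN * scale),
    burst_duty = 0.3,
    ...
  )
}

# Burst gate: alternating exponential on/off runs with the requested duty,
# raised-cosine smoothed over ramp_s. Returns a vector in [0, 1].
burst_gate <- function(t, duty, cycle_s, ramp_s = 0.25) {
  n <- length(t)
  if (duty >= 1) return(rep(1, n))
  if (duty <= 0) return(rep(0, n))
  dur <- t[n] + (t[2] - t[1])
  mean_on <- duty * cycle_s
  mean_off <- (1 - duty) * cycle_s
  # draw enough alternating runs to cover the trace
  state <- runif(1) < duty
  edges <- numeric(0)
  states <- logical(0)
  pos <- 0
  while (pos < dur) {
    len <- rexp(1, 1 / if (state) mean_on else mean_off)
    edges <- c(edges, pos)
    states <- c(states, state)
    pos <- pos + len
    state <- !state
  }
  gate <- states[findInterval(t, edges)]
  gate <- as.numeric(gate)
  if (ramp_s > 0) {
    fs <- 1 / (t[2] - t[1])
    k <- max(3L, as.integer(round(ramp_s * fs)))
    if (k %% 2L == 0L) k <- k + 1L
    w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
    w <- w / sum(w)
    padded <- c(rep(gate[1], k), gate, rep(gate[n], k))
    sm <- stats::filter(padded, w, sides = 2)
    gate <- as.numeric(sm[(k + 1):(k + n)])
  }
  pmin(pmax(gate, 0), 1)
}

# Raised-cosine step from 1 to 0 at t0 over ramp_s; models a cell ceasing
# to beat at t0.
stop_envelope <- function(t, t0, ramp_s = 0.5) {
  e <- numeric(length(t))
  e[t < t0 - ramp_s / 2] <- 1
  mid <- t >= t0 - ramp_s / 2 & t <= t0 + ramp_s / 2
  e[mid] <- 0.5 * (1 - sin(pi * (t[mid] - t0) / ramp_s))
  e
}

#' Generate one synthetic deflection trace
#'
#' Synthesizes the force signal
#' `baseline + sum_c A_c * env_c(t) * sin(2 pi f_c t + phi_c) + noise`
#' and converts it to photodetector volts with `V = F / (S * K)`, the
#' inverse of the calibration equation. Each component's envelope is the
#' product of the cell-level burst gate (see [phenotype_profile()]) and a
#' raised-cosine slow modulation `0.5 * (1 - cos(2 pi am_rate t + psi_c))`
#' with per-component random phase, so every band peaks at a different,
#' seed-dependent time and the envelope reaches 1. `am_rate_hz = 0` and
#' `burst_duty = 1` give a constant envelope of 1. The result is fully
#' deterministic given `seed`.
#'
#' @param profile A [phenotype_profile()].
#' @param meta A [cell_meta()].
#' @param calib A [calibration_constants()].
#' @param seed Integer seed; same seed, same trace.
#' @param stop_time_s Optional time (s) at which the cell ceases to beat:
#'   all oscillatory components are switched off (raised-cosine, 0.5 s)
#'   from there on, leaving baseline and sensor noise. For quality-control
#'   validation.
#'
#' @return A [deflection_trace()].
#' @export
generate_cell_trace <- function(profile, meta, calib, seed,
                                stop_time_s = NULL) {
  stopifnot(inherits(profile, "phenotype_profile"), inherits(meta, "cell_meta"),
            inherits(calib, "calibration_constants"))
  fs <- meta$sampling_rate_hz
  comp <- profile$components
  if (any(comp$frequency_hz >= fs / 2)) {
    abort("Component frequency at or above Nyquist (sampling_rate / 2).")
  }
  if (profile$noise_sd_nN < 0) abort("`noise_sd_nN` must be >= 0.")
  n <- round(meta$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  force <- withr::with_seed(as.integer(seed), {
    gate <- burst_gate(t, profile$burst_duty, profile$burst_cycle_s)
    f <- rep(profile$baseline_offset_nN, n)
    for (i in seq_len(nrow(comp))) {
      phi <- comp$phase[i]
      if (is.na(phi)) phi <- runif(1, 0, 2 * pi)
      am <- if (comp$am_rate_hz[i] > 0) {
        0.5 * (1 - cos(2 * pi * comp$am_rate_hz[i] * t + runif(1, 0, 2 * pi)))
      } else {
        1
      }
      osc <- comp$amplitude_nN[i] * gate * am *
        sin(2 * pi * comp$frequency_hz[i] * t + phi)
      if (!is.null(stop_time_s)) osc <- osc * stop_envelope(t, stop_time_s)
      f <- f + osc
    }
    if (profile$noise_sd_nN > 0) f <- f + rnorm(n, 0, profile$noise_sd_nN)
    f
  })

  v <- force / (calib$sensitivity_nm_per_V * calib$spring_constant_nN_per_nm)
  deflection_trace(tibble(time_s = t, deflection_V = v), meta, calib)
}

#' Simulate the thermal motion of a free cantilever
#'
#' Gaussian white positional noise whose variance satisfies equipartition,
#' `Var(z) = kB * T / k_true` (z in nm, k in nN/nm = N/m). The flat
#' spectrum is a deliberate simplification: the equipartition estimator in
#' [thermal_noise_spring_constant()] uses only the total variance, for
#' which the spectral shape is irrelevant.
#'
#' @param k_true_N_per_m True spring constant, N/m (> 0).
#' @param temperature_K Bath temperature, K (> 0).
#' @param sampling_rate_hz Sampling rate, Hz (> 0).
#' @param duration_s Duration, s (> 0).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `time_s`, `deflection_nm`.
#' @export
generate_thermal_trace <- function(k_true_N_per_m = 0.3, temperature_K = 298,
                                   sampling_rate_hz = 10000, duration_s = 10,
                                   seed = 1) {
  for (nm in c("k_true_N_per_m", "temperature_K", "sampling_rate_hz",
               "duration_s")) {
    if (get(nm) <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  n <- round(duration_s * sampling_rate_hz)
  sd_nm <- sqrt(KB_NN_NM_PER_K * temperature_K / k_true_N_per_m)
  z <- withr::with_seed(as.integer(seed), rnorm(n, 0, sd_nm))
  tibble(time_s = (seq_len(n) - 1) / sampling_rate_hz, deflection_nm = z)
}

#' Cohort recipes mirroring the measured groups
#'
#' Group layout of the reference study: a 100% progressive sample with 15
#' linear cells trapped by the tail, and an 80-20% progressive sample with
#' 16 linear cells trapped by the tail, 10 linear cells trapped by the
#' head/midpiece, and 17 circular cells trapped by the head. Residual
#' holding pressures (-20 mbar linear, -200 mbar circular) are metadata
#' only.
#'
#' @param sample Which sample to lay out: the 80-20% progressive sample
#'   (43 cells), the 100% progressive sample (15 cells), or both (58).
#' @param linear,circular Profiles to use for the two phenotypes.
#'
#' @return A named list of group definitions, each a list with `n`,
#'   `profile`, `trap_region`, `sample_group`, `trap_pressure_mbar`;
#'   suitable for [generate_cohort()].
#' @export
study_cohort_recipe <- function(sample = c("prog80_20", "prog100", "full"),
                                linear = linear_profile(),
                                circular = circular_profile()) {
  sample <- match.arg(sample)
  g80 <- list(
    linear_tail = list(n = 16, profile = linear, trap_region = "tail",
                       sample_group = "prog80_20", trap_pressure_mbar = -20),
    linear_headmid = list(n = 10, profile = linear, trap_region = "midpiece",
                          sample_group = "prog80_20", trap_pressure_mbar = -20),
    circular_head = list(n = 17, profile = circular, trap_region = "head",
                         sample_group = "prog80_20", trap_pressure_mbar = -200)
  )
  g100 <- list(
    linear_tail_100 = list(n = 15, profile = linear, trap_region = "tail",
                           sample_group = "prog100", trap_pressure_mbar = -20)
  )
  switch(sample,
    prog80_20 = g80,
    prog100 = g100,
    full = c(g100, g80)
  )
}

#' Generate a cohort of synthetic traces
#'
#' Generates `n` traces per group with per-cell log-normal jitter of the
#' component amplitudes: each cell draws one vigor factor with median 1
#' and coefficient of variation `jitter_cv` that scales all its components,
#' so cohort band-force distributions have realistic spread (the default
#' CV 0.33 matches the reported 0.6 +/- 0.2 nN dispersion). Deterministic
#' given `seed`.
#'
#' @param recipe Named list of groups as returned by
#'   [study_cohort_recipe()]; each element needs at least `n` (>= 1) and
#'   `profile` (a [phenotype_profile()]).
#' @param seed Integer seed.
#' @param sampling_rate_hz,duration_s Acquisition grid shared by all cells
#'   (defaults: 1000 Hz for 120 s, the study's conditions).
#' @param jitter_cv Coefficient of variation of the per-cell amplitude
#'   factor; 0 disables jitter.
#' @param calib Shared [calibration_constants()].
#'
#' @return A named list of [deflection_trace()] objects (names = cell ids).
#' @export
generate_cohort <- function(recipe, seed, sampling_rate_hz = 1000,
                            duration_s = 120, jitter_cv = 0.33,
                            calib = calibration_constants()) {
  if (!is.list(recipe) || is.null(names(recipe)) || any(!nzchar(names(recipe)))) {
    abort("`recipe` must be a named list of group definitions.")
  }
  for (g in names(recipe)) {
    gr <- recipe[[g]]
    if (is.null(gr$profile) || !inherits(gr$profile, "phenotype_profile")) {
      abort(sprintf("Group '%s' has no phenotype profile.", g))
    }
    if (is.null(gr$n) || gr$n < 1) {
      abort(sprintf("Group '%s' needs n >= 1.", g))
    }
  }
  if (jitter_cv < 0) abort("`jitter_cv` must be >= 0.")
  sdlog <- if (jitter_cv > 0) sqrt(log(1 + jitter_cv^2)) else 0

  plan <- withr::with_seed(as.integer(seed), {
    purrr::map(names(recipe), function(g) {
      gr <- recipe[[g]]
      purrr::map(seq_len(gr$n), function(i) {
        list(
          group = g,
          cell_id = sprintf("%s_%02d", g, i),
          vigor = if (sdlog > 0) rlnorm(1, 0, sdlog) else 1,
          cell_seed = sample.int(.Machine$integer.max, 1)
        )
      })
    })
  })

  traces <- purrr::map(purrr::flatten(plan), function(cell) {
    gr <- recipe[[cell$group]]
    prof <- gr$profile
    prof$components$amplitude_nN <- prof$components$amplitude_nN * cell$vigor
    meta <- cell_meta(
      cell_id = cell$cell_id,
      phenotype = prof$name,
      trap_region = gr$trap_region %||% "tail",
      sample_group = gr$sample_group %||% "prog80_20",
      trap_pressure_mbar = gr$trap_pressure_mbar %||% -20,
      sampling_rate_hz = sampling_rate_hz,
      duration_s = duration_s
    )
    tr <- generate_cell_trace(prof, meta, calib, seed = cell$cell_seed)
    # audit trail: lets callers reproduce any single cell in isolation
    attr(tr, "generator") <- list(group = cell$group, vigor = cell$vigor,
                                  cell_seed = cell$cell_seed)
    tr
  })
  names(traces) <- purrr::map_chr(purrr::flatten(plan), "cell_id")
  traces
}
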