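---
title: "Methods: flagellar beating-force analysis with flagellabeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flagellar beating-force analysis with flagellabeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagellabeat)
```

## The measurement and its model

A single spermatozoon is held on a hollow atomic-force-microscopy
cantilever (a FluidFM probe) by gentle suction, leaving the flagellum free
to beat. The beating transmits a thrust to the lever whose vertical
deflection is read out by optical beam deflection as a photodetector
voltage $V(t)$, recorded for two minutes at 1000 Hz. The force is the
standard cantilever conversion

$$F\,[\mathrm{nN}] = V\,[\mathrm{V}] \cdot S\,[\mathrm{nm/V}] \cdot
K\,[\mathrm{nN/nm}],$$

with $S$ the deflection sensitivity and $K$ the spring constant
(numerically equal in nN/nm and N/m). The residual suction bends the lever
by a constant amount; this static bending carries no beating information
and is removed as a baseline before any spectral step
(`deflection_to_force()`, default full-trace mean removal; a linear
detrend is available via `baseline = "linear"` for drifting recordings —
whether the original data pipeline used mean removal, detrending or
implicit high-pass behaviour is not documented, so the minimal reading is
the default).

Only the vertical component of the thrust is measured, and the cell's
orientation on the probe changes during the recording; the amplitude of
every spectral component therefore waxes and wanes, and the maximum over
the recording is taken as the thrust estimate. That motivates the core
statistic below.

## Spring-constant calibration

`thermal_noise_spring_constant()` implements the thermal-noise
(equipartition) method: for the free lever,
$K \langle z^2 \rangle = k_B T$, so
$K = \beta\, k_B T / \mathrm{Var}(z)$ with $z$ the tip deflection in nm,
$k_B = 1.380649 \times 10^{-5}\ \mathrm{nN\,nm/K}$, and Var the unbiased
sample variance after mean removal. $\beta$ is the dimensionless
mode-shape correction, default 1 (ideal point mass), which keeps the
estimator exactly invertible against the closed form; for real
rectangular levers the standard first-mode value $\beta \approx 0.817$
can be supplied. The companion generator `generate_thermal_trace()`
produces Gaussian white positional noise at the equipartition variance; a
flat spectrum is a deliberate simplification because the estimator uses
total variance only, for which the spectral shape is irrelevant.

## Band decomposition and the maximum-force statistic

Human flagellar beat frequencies lie in 0–30 Hz; the conventional
resolution is ten contiguous 3-Hz bands, labelled 0–2 Hz up to 27–29 Hz
(`make_band_scheme(0, 30, 3)`). Bands are implemented half-open,
$[3k, 3k+3)$, so every spectral bin belongs to exactly one band; labels
keep the conventional integer style.

`band_decompose()` takes one FFT of the baseline-free force trace (full
complex spectrum), zeroes all coefficients outside a band — keeping the
conjugate-symmetric negative-frequency partners so the inverse transform
is real — and inverse transforms back. Numerical choices:

* **DC exclusion.** The 0 Hz coefficient is excluded from every band,
  including 0–2 Hz: the suction bending is a baseline, not a beating
  force, and including DC would make the first band's maximum depend on
  residual offset.
* **Residual channel.** Everything the scheme does not cover (DC plus
  out-of-scheme frequencies) is returned as `residual_nN`, so band
  signals plus residual always reconstruct the input to floating
  precision — a property the test suite asserts at $10^{-8}$ nN on
  full-length traces.
* **No taper.** No window is applied before the FFT (rectangular window),
  the most literal reading of the FFT/IFFT procedure. Rectangular masking
  rings at the trace edges, so `band_max_force()` excludes a guard
  interval (default 1 s per end) before searching for the maximum.
* **Magnitude maximum.** The per-band statistic is
  $\max_t |x_b(t)|$ over the guarded window. The sign of the force only
  encodes the instantaneous swimming direction, so magnitude is the
  physically meaningful thrust; a peak-to-peak variant is available via
  `statistic = "peak_to_peak"`.

On traces whose length admits a direct check, the masked-FFT path agrees
with time-domain circular convolution against the kernel built from the
same frequency mask to $10^{-9}$ nN (see the test suite and the
acceptance script).

## Quality control

Cells that stop moving during the recording are in distress and were
excluded in the original workflow by simultaneous video. This package has
no video, so `assess_motility()` substitutes a trace-based detector: the
beating-band (0–30 Hz, DC-free) force is split into contiguous windows
(default 5 s), each window's RMS is compared against a threshold (default
0.05 nN), and a cell fails when less than half its windows are active or
when the trace ends with an inactive run longer than a grace period
(default 10 s) — the signature of a cell that went quiet and stayed
quiet. Window, threshold and fractions are operational defaults validated
on the synthetic generator, not values derived from any reference
measurement; they are fully configurable. Excluded cells are kept in the
QC report with `passed = FALSE` (auditable), and every exclusion is
logged with its cell id.

## Group statistics

`compare_bands()` reproduces the conventional nonparametric chain per
band: a Kruskal–Wallis omnibus test on midranks with tie correction
(delegated to `stats::kruskal.test`; all-tied data are defined as
$H = 0$, $p = 1$), followed by Dunn's post hoc pairwise $z$ tests on
pooled midranks with tie-corrected standard errors. The adjustment for
Dunn's p-values is not documented in the source workflow; Bonferroni over
all pairs (the convention of common graphing software) is the default,
with `"none"` available. Stars follow the usual thresholds:
`*` $p \le 0.05$, `**` $p \le 0.01$, `***` $p \le 0.001$. Box summaries
use the inclusive linear-interpolation quartile convention (R type 7).
Each band is annotated on its own with no cross-band multiplicity
correction, matching the per-band annotation style of the field; with ten
bands, isolated single stars should be read accordingly.

With two groups, Dunn's $z$ reduces algebraically to the tie-corrected
normal-approximation rank-sum test; the test suite checks that reduction
numerically against an independently coded oracle.

## The synthetic generator

`generate_cell_trace()` synthesizes the force signal

$$F(t) = B + \sum_c A_c\, e_c(t) \sin(2\pi f_c t + \varphi_c) +
\varepsilon(t),$$

then converts it to volts with $V = F/(SK)$. $B$ is the static suction
baseline (default $-1$ nN; it drops out at calibration), $\varepsilon$ is
Gaussian sensor noise (default SD 0.02 nN), and each component's envelope
$e_c(t) \in [0,1]$ is the product of

* a **slow raised-cosine modulation** $\tfrac12(1 - \cos(2\pi r t +
  \psi_c))$ at rate $r$ (default 0.05 Hz) with per-component random
  phase — every band peaks at its own, seed-dependent time, emulating
  reorientation of the cell on the probe; and
* a **cell-level burst gate**: alternating exponential on/off runs with
  duty `burst_duty` and mean cycle 6 s, raised-cosine smoothed over
  0.25 s. Linear cells beat continuously (duty 1); circular cells beat in
  bursts (duty 0.3), reproducing the qualitative contrast of few
  oscillations separated in time.

Default profiles place components at 1, 4, 7, 10, 13 and 25 Hz. Linear
amplitudes decrease from 0.6 nN (the reported human low-frequency beating
force) to 0.15 nN; circular amplitudes are 40% of linear. The exact
per-band spectra of real cells are not published, so these are free,
configurable parameters chosen to land one component in each of six
bands while leaving four bands signal-free for leakage checks.
`generate_cohort()` adds one log-normal vigor factor per cell (median 1,
CV 0.33, matching the reported 0.6 ± 0.2 nN dispersion) applied to all of
that cell's components, and mirrors the measured group layout: 15 linear
tail-trapped cells (100% progressive sample) and 16 + 10 linear plus 17
circular cells (80–20% progressive sample).

What the generator does **not** emulate: hydrodynamic coupling between
lever and flagellum, 1/f instrument drift, harmonic distortion of the
beat, cross-band phase coupling, trapping-pressure dynamics, or any true
3-D waveform. Passing tests therefore demonstrate that the analysis chain
is correct and well calibrated for band-limited amplitude-modulated
signals in white noise — not that it is robust to every artifact of real
instrument data.

## Validation choices and problem sizes

* **Amplitude recovery** is scored per cell: the cohort median of
  (estimated band maximum) / (that cell's realized component amplitude,
  i.e. nominal amplitude × vigor) must sit within 15% of 1 for every
  component band, on the full 43-cell cohort at 2 min / 1000 Hz. Scoring
  against each cell's realized amplitude isolates exactly what the
  tolerance is meant to cover — envelope modulation and noise — rather
  than the sampling spread of a 17-cell median, and it is insensitive to
  QC's preferential exclusion of low-vigor cells. Observed worst-band
  errors are 2–9% across seeds.
* **Null calibration** uses 2000 simulated null cohorts at the study's
  group sizes (26 vs 17) drawn from the generator's band-force law
  (log-normal, CV 0.33); the Kruskal–Wallis type-I error at
  $\alpha = 0.05$ must lie within three Monte-Carlo standard errors of
  0.05. Simulating at the band-force level rather than re-running the
  full trace pipeline 2000 times is valid because the statistic depends
  on the per-cell band forces only.
* **Effect detection** uses 30 replicate cohorts at a reduced acquisition
  grid (30 s at 500 Hz — all components stay well below Nyquist and the
  slow envelope still completes a cycle), requiring the 0–2 Hz
  linear-vs-circular comparison to be starred in at least 90% of
  replicates. At the default 2.5:1 amplitude ratio the observed rate is
  100%.
* Oracle-equivalence checks run on 1200- and 2048-sample traces where the
  $O(n^2)$ direct convolution is affordable.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(
  list(simulate = list(recipe = "prog80_20")),
  seed = 1
)
res$band_force_table
tidy(res$comparisons$phenotype)
autoplot(res$comparisons$phenotype)
```

## Known limitations

* The QC detector cannot distinguish a cell that truly ceased from one
  whose beating force sits persistently below threshold; with the default
  profiles a few percent of weak circular cells are excluded as inactive.
  This mirrors real exclusions but means cohort medians of survivors are
  slightly biased upward relative to the configured population.
* The chi-squared approximation to the Kruskal–Wallis null is slightly
  conservative at these group sizes; exact permutation p-values are not
  implemented.
* Band edges are half-open on a fixed 3-Hz grid; beat components drifting
  across an edge split their energy between adjacent bands, as they would
  in any fixed-band scheme.
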