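Package: flagellabeat
Title: Flagellar Beating-Force Analysis for Single-Cell Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for flagellar beating forces of single
    spermatozoa trapped on a microfluidic atomic-force-microscopy (FluidFM)
    cantilever. Converts photodetector deflection traces to force using the
    deflection sensitivity and spring constant, estimates the spring constant
    from thermal fluctuations by the equipartition method, decomposes each
    force trace into contiguous frequency bands by FFT masking and inverse
    FFT, extracts the per-band maximum beating force, screens out cells that
    cease to beat during recording, and compares band forces across motility
    phenotypes with Kruskal-Wallis and Dunn post hoc tests. Includes a
    synthetic-trace generator that emulates the band-limited, amplitude-
    modulated thrust of linearly and circularly motile cells for validation
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
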