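#' Reference values from published FluidFM beating-force measurements
#'
#' Printed summary numbers from published single-cell force-spectroscopy
#' work on flagellar beating, used to contextualize pipeline output and as
#' inputs to the package's arithmetic consistency checks. They are typed-in
#' literature values, not measurements made by this package.
#'
#' `published_forces()` returns the reported low-frequency (0-2 Hz) band
#' maximum beating forces: mouse spermatozoa (3.77 +/- 2.11) nN and human
#' spermatozoa (0.6 +/- 0.2) nN, the mouse value being reported as more
#' than 5 times the human one.
#'
#' `published_cohort()` returns the reported group sizes: 15 linear cells
#' trapped by the tail (100% progressive sample); 16 linear by the tail,
#' 10 linear by the head/midpiece, and 17 circular by the head (80-20%
#' progressive sample). The 26 linear cells of the 80-20% sample were
#' pooled for the phenotype comparison.
#'
#' @return A tibble of reference values.
#' @examples
#' published_forces()
#' published_cohort()
#' @export
published_forces <- function() {
  tibble(
    species = c("mouse", "human"),
    band = "0-2 Hz",
    mean_nN = c(3.77, 0.6),
    sd_nN = c(2.11, 0.2)
  )
}

#' @rdname published_forces
#' @export
published_cohort <- function() {
  tibble(
    sample_group = c("prog100", "prog80_20", "prog80_20", "prog80_20"),
    phenotype = c("linear", "linear", "linear", "circular"),
    trap_region = c("tail", "tail", "midpiece", "head"),
    n = c(15L, 16L, 10L, 17L),
    pooled_linear_n = c(NA_integer_, 26L, 26L, NA_integer_)
  )
}
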