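#' Build a contiguous frequency-band scheme
#'
#' Partitions `[f_min, f_max)` into contiguous, non-overlapping half-open
#' bands of equal `width`. The default reproduces the ten bands used for
#' human flagellar beating, 0-2 Hz up to 27-29 Hz: beat frequencies of
#' human spermatozoa lie in 0-30 Hz and a 3-Hz interval is the conventional
#' resolution. Band `k` covers `[f_min + k*width, f_min + (k+1)*width)`;
#' the label names the integer frequencies it contains (`[0, 3)` ->
#' `"0-2 Hz"`).
#'
#' @param f_min Lower edge in Hz (>= 0).
#' @param f_max Upper edge in Hz (> `f_min`).
#' @param width Band width in Hz; must divide `f_max - f_min` exactly.
#'
#' @return A tibble of class `"band_scheme"` with columns `lo_hz`, `hi_hz`
#'   (half-open edges) and `label`.
#' @examples
#' make_band_scheme()            # the ten 3-Hz bands
#' make_band_scheme(0, 30, 30)   # one wide band
#' @export
make_band_scheme <- function(f_min = 0, f_max = 30, width = 3) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || !is.numeric(width)) {
    abort("`f_min`, `f_max`, `width` must be numeric scalars.")
  }
  if (f_min < 0 || f_max <= f_min) abort("Require f_max > f_min >= 0.")
  if (width <= 0) abort("`width` must be positive.")
  k <- (f_max - f_min) / width
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("`width` (%g) must divide f_max - f_min (%g) exactly.",
                  width, f_max - f_min))
  }
  k <- as.integer(round(k))
  lo <- f_min + (seq_len(k) - 1) * width
  hi <- lo + width
  label <- sprintf("%g-%g Hz", ceiling(lo), ceiling(lo) + width - 1)
  structure(
    tibble(lo_hz = lo, hi_hz = hi, label = label),
    f_min = f_min, f_max = f_max, width = width,
    class = c("band_scheme", class(tibble()))
  )
}

# "0-2 Hz" -> "band_0_2_nN": the CSV-safe column key for a band label.
band_column <- function(label) {
  paste0("band_", gsub("-", "_", sub(" Hz$", "", label)), "_nN")
}

# Inverse of band_column(): "band_0_2_nN" -> "0-2 Hz".
band_label_from_column <- function(column) {
  paste0(sub("_", "-", sub("^band_", "", sub("_nN$", "", column))), " Hz")
}
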