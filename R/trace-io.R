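TRACE_META_KEYS <- c(
  "cell_id", "phenotype", "trap_region", "sample_group",
  "trap_pressure_mbar", "sampling_rate_hz", "duration_s",
  "sensitivity_nm_per_V", "spring_constant_nN_per_nm", "temperature_K"
)

#' Read and write deflection traces
#'
#' Traces are stored in a plain-text, diff-friendly dialect
#' (`*.trace.tsv`): `#`-prefixed `key=value` header lines carrying the
#' cell metadata and calibration constants, a `time_s<TAB>deflection_V`
#' column header, then tab-separated numeric rows. Samples are written
#' with 9 significant digits, which preserves float32-class instrument
#' data exactly; `read_trace(write_trace(x))` reproduces `x` with
#' bit-identical metadata and samples equal to that printed precision.
#'
#' @param path File path.
#' @param trace A [deflection_trace()].
#'
#' @return `read_trace()`: a [deflection_trace()]. `write_trace()`:
#'   the path, invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0L) abort("Format error: no metadata header lines.")
  kv <- sub("^#\\s*", "", lines[hdr])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- trimws(keys)
  vals <- trimws(vals)
  missing <- setdiff(TRACE_META_KEYS, names(vals))
  if (length(missing) > 0L) {
    abort(sprintf("Format error: missing metadata key '%s'.", missing[1]))
  }
  body <- lines[-hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || !grepl("^time_s\tdeflection_V$", body[1])) {
    abort("Format error: expected 'time_s<TAB>deflection_V' column header.")
  }
  data <- utils::read.table(
    text = body[-1], sep = "\t", col.names = c("time_s", "deflection_V"),
    colClasses = "numeric"
  )
  if (nrow(data) == 0L) abort("Format error: empty sample block.")
  meta <- cell_meta(
    cell_id = vals[["cell_id"]],
    phenotype = vals[["phenotype"]],
    trap_region = vals[["trap_region"]],
    sample_group = vals[["sample_group"]],
    trap_pressure_mbar = as.numeric(vals[["trap_pressure_mbar"]]),
    sampling_rate_hz = as.numeric(vals[["sampling_rate_hz"]]),
    duration_s = as.numeric(vals[["duration_s"]])
  )
  calib <- calibration_constants(
    sensitivity_nm_per_V = as.numeric(vals[["sensitivity_nm_per_V"]]),
    spring_constant_nN_per_nm = as.numeric(vals[["spring_constant_nN_per_nm"]]),
    temperature_K = as.numeric(vals[["temperature_K"]])
  )
  deflection_trace(data, meta, calib)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "deflection_trace")) {
    abort("`trace` must be a deflection_trace.")
  }
  if (nrow(trace) == 0L) abort("Refusing to write an empty trace.")
  meta <- trace_meta(trace)
  calib <- trace_calib(trace)
  header <- c(
    sprintf("# cell_id=%s", meta$cell_id),
    sprintf("# phenotype=%s", meta$phenotype),
    sprintf("# trap_region=%s", meta$trap_region),
    sprintf("# sample_group=%s", meta$sample_group),
    sprintf("# trap_pressure_mbar=%.9g", meta$trap_pressure_mbar),
    sprintf("# sampling_rate_hz=%.9g", meta$sampling_rate_hz),
    sprintf("# duration_s=%.9g", meta$duration_s),
    sprintf("# sensitivity_nm_per_V=%.9g", calib$sensitivity_nm_per_V),
    sprintf("# spring_constant_nN_per_nm=%.9g", calib$spring_constant_nN_per_nm),
    sprintf("# temperature_K=%.9g", calib$temperature_K),
    "time_s\tdeflection_V"
  )
  rows <- sprintf("%.9g\t%.9g", trace$time_s, trace$deflection_V)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
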