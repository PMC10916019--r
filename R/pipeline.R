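#' Per-cell band-force table for a set of traces
#'
#' Runs [band_decompose()] and [band_max_force()] on each calibrated trace
#' and assembles the wide per-cell table that feeds the group statistics:
#' one row per cell, metadata columns, and one `band_*_nN` column per band
#' of the scheme.
#'
#' @param forces A list of [force_trace()] objects (baseline removed), or
#'   a single one.
#' @param scheme A [make_band_scheme()].
#' @param guard_s Edge guard passed to [band_max_force()].
#'
#' @return A tibble with columns `cell_id`, `phenotype`, `trap_region`,
#'   `sample_group` and one `band_*_nN` column per band.
#' @export
band_force_table <- function(forces, scheme = make_band_scheme(), guard_s = 1) {
  if (inherits(forces, "force_trace")) forces <- list(forces)
  purrr::map_dfr(forces, function(f) {
    meta <- trace_meta(f)
    prof <- band_max_force(band_decompose(f, scheme), guard_s = guard_s)
    row <- tibble(
      cell_id = meta$cell_id,
      phenotype = meta$phenotype,
      trap_region = meta$trap_region,
      sample_group = meta$sample_group
    )
    wide <- stats::setNames(
      as.list(prof$max_force_nN),
      band_column(prof$band)
    )
    dplyr::bind_cols(row, as_tibble(wide))
  })
}

parse_band_spec <- function(bands) {
  if (inherits(bands, "band_scheme")) return(bands)
  if (is.character(bands) && length(bands) == 1L) {
    p <- as.numeric(strsplit(bands, ":", fixed = TRUE)[[1]])
    if (length(p) != 3L || anyNA(p)) {
      abort("Band spec string must look like \"0:30:3\" (min:max:width).")
    }
    return(make_band_scheme(p[1], p[2], p[3]))
  }
  if (is.numeric(bands) && length(bands) == 3L) {
    return(make_band_scheme(bands[1], bands[2], bands[3]))
  }
  abort("`bands` must be a band_scheme, \"min:max:width\" string, or numeric triple.")
}

default_pipeline_config <- function() {
  list(
    simulate = list(recipe = "prog80_20", jitter_cv = 0.33,
                    sampling_rate_hz = 1000, duration_s = 120),
    traces = NULL,
    bands = "0:30:3",
    guard_s = 1,
    qc = list(enabled = TRUE, band = c(0, 30), window_s = 5,
              threshold_nN = 0.05, min_active_fraction = 0.5,
              cessation_grace_s = 10),
    comparisons = list(list(name = "phenotype", group_by = "phenotype"))
  )
}

#' Run the full beating-force pipeline
#'
#' Orchestrates calibration, quality control, band decomposition,
#' per-band maximum-force extraction and group statistics for a whole
#' cohort, from either simulated or stored traces:
#' `calibrate -> qc -> band_decompose -> band_max_force -> compare_bands`.
#' Every calibration constant and every QC exclusion is reported via
#' `message()` with the cell id so exclusions are auditable.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognized fields (all optional, defaults in parentheses):
#'   * `simulate`: list with `recipe` (`"prog80_20"`, `"prog100"` or
#'     `"full"`, or a [study_cohort_recipe()]-style list), `jitter_cv`
#'     (0.33), `sampling_rate_hz` (1000), `duration_s` (120). Ignored when
#'     `traces` is given.
#'   * `traces`: character vector of `.trace.tsv` paths to analyze instead
#'     of simulating.
#'   * `bands`: band scheme as `"min:max:width"` (`"0:30:3"`).
#'   * `guard_s`: edge guard for the maxima (1).
#'   * `qc`: arguments of [assess_motility()] plus `enabled` (TRUE).
#'   * `comparisons`: list of `list(name, group_by, subset)` where
#'     `subset` optionally restricts cells by metadata column values, e.g.
#'     `list(phenotype = "linear")`.
#' @param seed Integer seed for the simulation (required when simulating).
#' @param out_dir Optional directory; when given, writes
#'   `band_force_table.csv`, `qc_report.csv` and one
#'   `comparison_<name>.csv` per comparison.
#'
#' @return A list of class `"pipeline_result"`: `band_force_table`
#'   (QC-passing cells), `qc` (all cells), `comparisons` (named list of
#'   [compare_bands()] results), `n_included`, `n_excluded`, `scheme`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  # one-level merge: `qc` and `simulate` merge by key, everything else
  # (including `comparisons` and `simulate$recipe`) replaces wholesale
  cfg <- default_pipeline_config()
  for (nm in names(config)) {
    if (nm %in% c("qc", "simulate") && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) cfg[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  scheme <- parse_band_spec(cfg$bands)

  if (!is.null(cfg$traces)) {
    traces <- purrr::map(cfg$traces, read_trace)
    names(traces) <- purrr::map_chr(traces, ~ trace_meta(.x)$cell_id)
  } else {
    if (is.null(seed)) abort("`seed` is required when simulating traces.")
    recipe <- cfg$simulate$recipe
    if (is.character(recipe)) recipe <- study_cohort_recipe(recipe)
    traces <- generate_cohort(
      recipe, seed = seed,
      sampling_rate_hz = cfg$simulate$sampling_rate_hz %||% 1000,
      duration_s = cfg$simulate$duration_s %||% 120,
      jitter_cv = cfg$simulate$jitter_cv %||% 0.33
    )
  }
  if (anyDuplicated(names(traces))) abort("Duplicate cell ids in input.")

  forces <- purrr::map(traces, function(tr) {
    calib <- trace_calib(tr)
    message(sprintf(
      "calibrate %s: S = %g nm/V, K = %g nN/nm",
      trace_meta(tr)$cell_id, calib$sensitivity_nm_per_V,
      calib$spring_constant_nN_per_nm
    ))
    deflection_to_force(tr)
  })

  if (isTRUE(cfg$qc$enabled)) {
    qc_tbl <- purrr::map_dfr(forces, function(f) {
      assess_motility(
        f,
        band = cfg$qc$band %||% c(0, 30),
        window_s = cfg$qc$window_s %||% 5,
        threshold_nN = cfg$qc$threshold_nN %||% 0.05,
        min_active_fraction = cfg$qc$min_active_fraction %||% 0.5,
        cessation_grace_s = cfg$qc$cessation_grace_s %||% 10
      )
    })
    for (id in qc_tbl$cell_id[!qc_tbl$passed]) {
      message(sprintf("qc: excluding %s (ceased or inactive)", id))
    }
  } else {
    qc_tbl <- tibble(
      cell_id = names(forces), passed = TRUE, active_fraction = NA_real_,
      cessation_time_s = NA_real_, window_s = NA_real_, threshold_nN = NA_real_
    )
  }
  included <- qc_tbl$cell_id[qc_tbl$passed]
  message(sprintf("qc: %d included, %d excluded",
                  length(included), nrow(qc_tbl) - length(included)))

  bft <- band_force_table(forces[included], scheme, guard_s = cfg$guard_s)

  comparisons <- list()
  for (cmp in cfg$comparisons) {
    d <- bft
    if (!is.null(cmp$subset)) {
      for (col in names(cmp$subset)) {
        d <- d[d[[col]] %in% cmp$subset[[col]], , drop = FALSE]
      }
    }
    lv <- unique(d[[cmp$group_by]])
    # a group present before QC but emptied by it is an error, not a silent drop
    pre <- purrr::map_chr(forces, ~ trace_meta(.x)[[cmp$group_by]])
    pre_lv <- unique(pre)
    empty <- setdiff(pre_lv, lv)
    if (length(empty) > 0L) {
      abort(sprintf("No cells surviving QC in group '%s' (comparison '%s').",
                    empty[1], cmp$name %||% cmp$group_by))
    }
    comparisons[[cmp$name %||% cmp$group_by]] <-
      compare_bands(d, group_by = cmp$group_by,
                    adjust = cmp$adjust %||% "bonferroni")
  }

  result <- structure(
    list(
      band_force_table = bft, qc = qc_tbl, comparisons = comparisons,
      n_included = length(included),
      n_excluded = nrow(qc_tbl) - length(included),
      scheme = scheme
    ),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(bft, file.path(out_dir, "band_force_table.csv"))
    readr::write_csv(qc_tbl, file.path(out_dir, "qc_report.csv"))
    for (nm in names(comparisons)) {
      readr::write_csv(
        tidy(comparisons[[nm]]),
        file.path(out_dir, sprintf("comparison_%s.csv", nm))
      )
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Beating-force pipeline: %d cells analyzed (%d excluded by QC), %d bands\n",
    x$n_included, x$n_excluded, nrow(x$scheme)
  ))
  for (nm in names(x$comparisons)) {
    cat(sprintf("\n-- comparison '%s' --\n", nm))
    print(x$comparisons[[nm]])
  }
  invisible(x)
}
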