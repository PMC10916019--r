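resolve_groups <- function(x, g) {
  if (is.list(x) && !is.data.frame(x) && is.null(g)) {
    g <- rep(names(x) %||% as.character(seq_along(x)), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (!is.numeric(x)) abort("Observations must be numeric.")
  if (length(x) != length(g)) abort("`x` and `g` must have equal length.")
  g <- factor(g)
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (any(tabulate(g) == 0L)) abort("Every group must be nonempty.")
  if (length(x) < 3L) abort("Need at least three observations in total.")
  list(x = x, g = g)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of two or more groups, computed on
#' midranks with tie correction and a chi-squared approximation on
#' `k - 1` degrees of freedom. When every observation is identical the
#' statistic is defined as 0 with p = 1 (no rank separation is possible).
#'
#' @param x Numeric vector of observations, or a list of numeric groups
#'   (then `g` is ignored).
#' @param g Group labels, same length as `x`.
#'
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  d <- resolve_groups(x, g)
  if (length(unique(d$x)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(d$g) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(d$x, d$g)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Dunn's post hoc pairwise comparisons
#'
#' Follow-up to [kruskal_wallis()]: for every pair of groups the z
#' statistic is the difference of mean pooled midranks scaled by its
#' tie-corrected standard error,
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_a + 1/n_b))`,
#' with two-sided normal p-values adjusted for the number of pairs
#' (Bonferroni by default, the convention of common graphing software for
#' "Dunn's comparison").
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"bonferroni"` (default) or `"none"`.
#'
#' @return A tibble with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `z`, `p_value` (unadjusted), `p_adjusted`.
#' @export
dunn_posthoc <- function(x, g = NULL, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  d <- resolve_groups(x, g)
  x <- d$x
  g <- d$g
  n_tot <- length(x)
  r <- rank(x) # midranks
  tab <- table(x)
  tie_sum <- sum(tab^3 - tab)
  var_unit <- n_tot * (n_tot + 1) / 12 - tie_sum / (12 * (n_tot - 1))
  mean_rank <- tapply(r, g, mean)
  n_g <- tabulate(g)
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt(var_unit * (1 / n_g[a] + 1 / n_g[b]))
    z <- if (se > 0) (mean_rank[[a]] - mean_rank[[b]]) / se else 0
    tibble(
      group_a = lev[a], group_b = lev[b],
      n_a = n_g[a], n_b = n_g[b],
      z = z, p_value = 2 * stats::pnorm(-abs(z))
    )
  })
  res$p_adjusted <- if (adjust == "bonferroni") {
    pmin(1, res$p_value * nrow(res))
  } else {
    res$p_value
  }
  res
}

#' Box-plot summary of one group
#'
#' The six summaries drawn in the group box plots: mean (the "+" marker),
#' median (the "-" marker), first and third quartiles (box), minimum and
#' maximum (whiskers). Quartiles use the inclusive linear-interpolation
#' convention (R type 7).
#'
#' @param x Nonempty numeric vector.
#' @return A one-row tibble: `n`, `mean`, `median`, `q1`, `q3`, `min`,
#'   `max`.
#' @examples
#' summarize_box(c(1, 2, 3, 4, 5))
#' @export
summarize_box <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) abort("`x` must be nonempty numeric.")
  tibble(
    n = length(x),
    mean = mean(x),
    median = stats::median(x),
    q1 = unname(stats::quantile(x, 0.25, type = 7)),
    q3 = unname(stats::quantile(x, 0.75, type = 7)),
    min = min(x),
    max = max(x)
  )
}

star_for_p <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare band forces across cell groups
#'
#' For every frequency band of a band-force table (see
#' [band_force_table()]), runs the Kruskal-Wallis omnibus test across the
#' groups defined by `group_by`, Dunn's post hoc pairwise comparisons, and
#' the box-plot summaries per group. Pairwise significance is annotated
#' with the conventional stars: `*` p <= 0.05, `**` p <= 0.01, `***`
#' p <= 0.001, `ns` otherwise. Each band is tested on its own; no
#' cross-band multiplicity correction is applied (the per-band annotation
#' style of the source field), so stars on many bands should be read
#' band-wise, not experiment-wise.
#'
#' @param table A band-force table: one row per cell with metadata columns
#'   and `band_*_nN` force columns.
#' @param group_by Name of the metadata column defining the groups
#'   (e.g. `"phenotype"`, `"trap_region"`, `"sample_group"`).
#' @param adjust Dunn adjustment, `"bonferroni"` (default) or `"none"`.
#'
#' @return An object of class `"band_comparison"`: a list with tibbles
#'   `omnibus` (per band), `pairs` (per band and pair, with stars),
#'   `summaries` (per band and group) and the long-format `data`. Use
#'   [tidy()], [glance()] and [autoplot()] on it.
#' @export
compare_bands <- function(table, group_by = "phenotype",
                          adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table))
  if (!group_by %in% names(table)) {
    abort(sprintf("Grouping column '%s' not found.", group_by))
  }
  band_cols <- grep("^band_.*_nN$", names(table), value = TRUE)
  if (length(band_cols) == 0L) abort("No `band_*_nN` columns found.")
  groups <- table[[group_by]]
  # keep declared-but-empty factor levels visible so they error loudly
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(is.na(groups))) abort("Missing group labels.")
  counts <- table(groups)
  if (any(counts == 0L)) {
    abort(sprintf("Group '%s' has no cells.", names(counts)[counts == 0][1]))
  }
  if (nlevels(groups) < 2L) abort("Need at least two groups to compare.")

  long <- tidyr::pivot_longer(
    table[, c(group_by, band_cols)],
    cols = dplyr::all_of(band_cols),
    names_to = "band_column", values_to = "max_force_nN"
  )
  long$band <- band_label_from_column(long$band_column)
  long$band <- factor(long$band, levels = band_label_from_column(band_cols))
  long$group <- factor(long[[group_by]])

  per_band <- split(long, long$band)
  omnibus <- purrr::map_dfr(names(per_band), function(b) {
    d <- per_band[[b]]
    dplyr::bind_cols(tibble(band = b), kruskal_wallis(d$max_force_nN, d$group))
  })
  pairs <- purrr::map_dfr(names(per_band), function(b) {
    d <- per_band[[b]]
    dplyr::bind_cols(
      tibble(band = b),
      dunn_posthoc(d$max_force_nN, d$group, adjust = adjust)
    )
  })
  pairs$stars <- star_for_p(pairs$p_adjusted)
  summaries <- long |>
    dplyr::group_by(.data$band, .data$group) |>
    dplyr::group_modify(~ summarize_box(.x$max_force_nN)) |>
    dplyr::ungroup()

  structure(
    list(
      omnibus = omnibus, pairs = pairs, summaries = summaries,
      data = long[, c("band", "group", "max_force_nN")],
      group_by = group_by, adjust = adjust
    ),
    class = "band_comparison"
  )
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf(
    "Band-force comparison by '%s' (%d bands, %d cells, Dunn %s)\n",
    x$group_by, nrow(x$omnibus), nrow(x$data) / nrow(x$omnibus), x$adjust
  ))
  merged <- dplyr::left_join(
    x$omnibus,
    dplyr::select(x$pairs, "band", "group_a", "group_b", "p_adjusted", "stars"),
    by = "band"
  )
  print(as.data.frame(merged), digits = 3)
  invisible(x)
}

#' Tidy a band comparison
#'
#' @param x A [compare_bands()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per band and group pair with the omnibus H
#'   and p, Dunn z, adjusted p and stars. `glance()`: a one-row summary.
#' @method tidy band_comparison
#' @export
tidy.band_comparison <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(x$pairs, p_dunn_adjusted = "p_adjusted"),
    dplyr::rename(x$omnibus, kw_H = "statistic", kw_df = "df", kw_p = "p_value"),
    by = "band"
  )
}

#' @rdname tidy.band_comparison
#' @method glance band_comparison
#' @export
glance.band_comparison <- function(x, ...) {
  tibble(
    n_bands = nrow(x$omnibus),
    n_cells = nrow(x$data) / nrow(x$omnibus),
    n_groups = nlevels(x$data$group),
    adjust = x$adjust,
    n_significant_bands = sum(x$omnibus$p_value <= 0.05)
  )
}
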