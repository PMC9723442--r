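#' Resolve a constraint metric descriptor against a plan
#' @noRd
resolve_metric <- function(descriptor, dose, mask, prescription_dose) {
  if (grepl("@", descriptor, fixed = TRUE)) {
    parts <- strsplit(descriptor, "@", fixed = TRUE)[[1]]
    kind <- parts[1]
    x <- as.numeric(parts[2])
    if (is.na(x)) {
      stop(sprintf("unresolvable metric descriptor '%s'", descriptor),
           call. = FALSE)
    }
  } else {
    kind <- descriptor
    x <- NA_real_
  }
  d <- structure_doses(dose, mask)
  vvox <- voxel_volume_cc(mask)
  switch(kind,
    d_max = max(d),
    d_mean = mean(d),
    d_min = min(d),
    "v_pct" = 100 * sum(d >= x) / length(d),
    "v_cc" = sum(d >= x) * vvox,
    "v_below_cc" = sum(d < x) * vvox,
    "d_cc" = d_at_cc_from_doses(d, x, vvox),
    coverage = 100 * sum(d >= prescription_dose) / length(d),
    pidl = pidl(max(d), prescription_dose),
    stop(sprintf("unresolvable metric descriptor '%s'", descriptor),
         call. = FALSE)
  )
}

apply_comparator <- function(achieved, comparator, threshold, pidl_band) {
  switch(comparator,
    "<"  = achieved < threshold,
    ">"  = achieved > threshold,
    "<=" = achieved <= threshold,
    ">=" = achieved >= threshold,
    "~"  = abs(achieved - threshold) <= pidl_band,
    stop(sprintf("unknown comparator '%s'", comparator), call. = FALSE)
  )
}

#' Audit a plan against dose-volume constraints
#'
#' Evaluates each constraint row (see [default_constraints()] for the
#' descriptor grammar) against a plan's dose and structure set. A
#' constraint whose structure is missing from the structure set is
#' reported as not evaluable rather than raising an error; an
#' unresolvable metric descriptor is a configuration error.
#'
#' Comparators are strict as written: an achieved value exactly at a
#' `<` threshold fails. The `~` comparator passes within `pidl_band`
#' (default 10) units of the objective. The signed `margin` is positive
#' when the constraint passes with room to spare, negative when
#' violated.
#'
#' @param plan a [plan_dose()].
#' @param structures a [structure_set()] on the plan's geometry.
#' @param constraints constraint tibble; default [default_constraints()].
#' @param pidl_band half-width of the soft band for the `~` comparator.
#' @return A tibble: `structure`, `metric`, `comparator`, `threshold`,
#'   `units`, `achieved`, `pass` (logical, NA when not evaluable),
#'   `margin`.
#' @export
evaluate_constraints <- function(plan, structures,
                                 constraints = default_constraints(),
                                 pidl_band = 10) {
  stopifnot(inherits(plan, "plan_dose"), inherits(structures, "structure_set"))
  purrr::pmap_dfr(constraints, function(structure, metric, comparator,
                                        threshold, units, ...) {
    if (is.null(structures[[structure]])) {
      achieved <- NA_real_
      pass <- NA
      margin <- NA_real_
    } else {
      achieved <- resolve_metric(metric, plan$grid, structures[[structure]],
                                 plan$prescription_dose_gy)
      pass <- apply_comparator(achieved, comparator, threshold, pidl_band)
      margin <- switch(comparator,
        "<" = , "<=" = threshold - achieved,
        ">" = , ">=" = achieved - threshold,
        "~" = pidl_band - abs(achieved - threshold)
      )
    }
    tibble::tibble(structure = structure, metric = metric,
                   comparator = comparator, threshold = threshold,
                   units = units, achieved = achieved, pass = pass,
                   margin = margin)
  })
}

#' Audit published cohort mean metrics against the constraint table
#'
#' Checks already-computed summary metrics (e.g. the printed
#' organ-at-risk cohort means from [reference_cohort_summary()])
#' against a constraint table, matching on `structure` + `metric`
#' descriptor. Constraints with no matching metric in the summary are
#' reported as not evaluable.
#'
#' @param metrics tibble with columns `structure`, `metric` and a value
#'   column named by `value_col`.
#' @param constraints constraint tibble; default [default_constraints()].
#' @param value_col which column of `metrics` holds the achieved value.
#' @param pidl_band soft band for the `~` comparator.
#' @return Same shape as [evaluate_constraints()].
#' @export
audit_summary_metrics <- function(metrics,
                                  constraints = default_constraints(),
                                  value_col = "mean_s", pidl_band = 10) {
  purrr::pmap_dfr(constraints, function(structure, metric, comparator,
                                        threshold, units, ...) {
    hit <- metrics[metrics$structure == structure &
                     metrics$metric %in% metric_aliases(metric), ]
    if (nrow(hit) == 0) {
      achieved <- NA_real_; pass <- NA; margin <- NA_real_
    } else {
      achieved <- hit[[value_col]][1]
      pass <- apply_comparator(achieved, comparator, threshold, pidl_band)
      margin <- switch(comparator,
        "<" = , "<=" = threshold - achieved,
        ">" = , ">=" = achieved - threshold,
        "~" = pidl_band - abs(achieved - threshold)
      )
    }
    tibble::tibble(structure = structure, metric = metric,
                   comparator = comparator, threshold = threshold,
                   units = units, achieved = achieved, pass = pass,
                   margin = margin)
  })
}

# summary tables label coverage as coverage_pct etc.
metric_aliases <- function(metric) {
  switch(metric,
    coverage = c("coverage", "coverage_pct"),
    metric
  )
}
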