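#' Paired t test on single-plan vs double-plan values
#'
#' Classical paired t on the differences `s - d`: `t = mean(diff) /
#' (sd(diff) / sqrt(n))` with `df = n - 1` and a two-sided p value from
#' the t distribution. When every difference is identical (zero sample
#' SD of the differences) the statistic is undefined and the result is
#' flagged rather than returned as +/-Inf.
#'
#' @param s,d numeric vectors of paired per-patient values (same order,
#'   same length, n >= 2).
#' @return A one-row tibble: `n`, `mean_diff`, `t`, `df`, `p_value`,
#'   `defined` (FALSE when the statistic is degenerate, in which case
#'   `t` and `p_value` are NA).
#' @export
paired_t_test <- function(s, d) {
  stopifnot(length(s) == length(d), length(s) >= 2,
            !anyNA(s), !anyNA(d))
  diffs <- s - d
  n <- length(diffs)
  s_diff <- sd(diffs)
  if (s_diff == 0) {
    return(tibble::tibble(n = n, mean_diff = mean(diffs), t = NA_real_,
                          df = n - 1L, p_value = NA_real_,
                          defined = FALSE))
  }
  tstat <- mean(diffs) / (s_diff / sqrt(n))
  tibble::tibble(n = n, mean_diff = mean(diffs), t = tstat, df = n - 1L,
                 p_value = 2 * pt(-abs(tstat), df = n - 1),
                 defined = TRUE)
}

#' Paired cohort comparison report
#'
#' Summarizes a paired cohort of per-patient metrics into the standard
#' comparison table: per metric, mean +/- sample SD in each arm, the
#' percent reduction of the double-plan mean relative to the single-plan
#' mean, and a two-sided paired t test. Significance is flagged at
#' p < 0.05; no multiple-testing correction is applied (the number of
#' tests is recorded in the `glance()` summary instead).
#'
#' @param metrics a tibble with columns `patient`, `arm` (`"S"` or
#'   `"D"`), `structure`, `metric`, `value`; one row per patient x arm x
#'   structure x metric. Both arms must contain the same patients and
#'   metrics.
#' @return An object of class `cohort_comparison`; `tidy()` (or the
#'   object itself, a tibble) has columns `structure`, `metric`,
#'   `mean_s`, `sd_s`, `mean_d`, `sd_d`, `pct_reduction`, `t`,
#'   `p_value`, `significant`.
#' @export
cohort_report <- function(metrics) {
  required <- c("patient", "arm", "structure", "metric", "value")
  stopifnot(all(required %in% names(metrics)))
  pats_s <- sort(unique(metrics$patient[metrics$arm == "S"]))
  pats_d <- sort(unique(metrics$patient[metrics$arm == "D"]))
  if (!identical(pats_s, pats_d)) {
    missing <- c(setdiff(pats_s, pats_d), setdiff(pats_d, pats_s))
    stop(sprintf("arms cover different patients; unmatched: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(metrics, names_from = "arm",
                             values_from = "value")
  if (anyNA(wide$S) || anyNA(wide$D)) {
    stop("some patient/metric cells are present in only one arm",
         call. = FALSE)
  }
  out <- wide |>
    dplyr::group_by(.data$structure, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_s = mean(.data$S), sd_s = sd(.data$S),
      mean_d = mean(.data$D), sd_d = sd(.data$D),
      pct_reduction = percent_reduction(mean(.data$S), mean(.data$D)),
      test = list(paired_t_test(.data$S, .data$D)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test", names_sep = NULL, names_repair = "minimal")
  out <- out[, !duplicated(names(out))]
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  structure(out, class = c("cohort_comparison", class(out)))
}

#' @exportS3Method generics::tidy
tidy.cohort_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c(
    "structure", "metric", "mean_s", "sd_s", "mean_d", "sd_d",
    "pct_reduction", "t", "p_value", "significant")]
}

#' @exportS3Method generics::glance
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(
    n_metrics = nrow(x),
    n_patients = x$n[1],
    n_tests = sum(!is.na(x$p_value)),
    n_significant = sum(x$significant),
    alpha = 0.05
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d metrics, %d patients\n",
              nrow(x), x$n[1]))
  df <- tidy(x)
  df$mean_s <- round(df$mean_s, 2); df$sd_s <- round(df$sd_s, 2)
  df$mean_d <- round(df$mean_d, 2); df$sd_d <- round(df$sd_d, 2)
  df$pct_reduction <- round(df$pct_reduction, 2)
  df$p_value <- round(df$p_value, 3)
  print(tibble::as_tibble(df), n = nrow(df))
  invisible(x)
}

#' Plot a paired cohort comparison
#'
#' Dot-and-interval (mean +/- SD) display per metric and arm.
#'
#' @param object a `cohort_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_comparison <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(cols = c("mean_s", "mean_d"),
                        names_to = "arm", values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$arm == "mean_s", .data$sd_s, .data$sd_d),
      arm = ifelse(.data$arm == "mean_s", "Plan S", "Plan D"),
      label = paste(.data$structure, .data$metric)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$label,
                                   color = .data$arm)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$mean - .data$sd,
                   xmax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Value (mean ± SD)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Write a cohort comparison report
#'
#' Emits the tidy table as CSV and a nested JSON document (metrics plus
#' the `glance()` summary and the run seed) so reruns can be compared
#' byte-for-byte.
#'
#' @param comparison a `cohort_comparison`.
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the JSON for provenance.
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(comparison, dir, seed = NULL) {
  stopifnot(inherits(comparison, "cohort_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, "cohort_comparison.csv")
  json_path <- file.path(dir, "cohort_comparison.json")
  readr::write_csv(tidy(comparison), csv_path)
  jsonlite::write_json(
    list(seed = seed, summary = glance(comparison),
         metrics = tidy(comparison)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read back a cohort comparison CSV
#'
#' @param path a CSV written by [write_cohort_report()].
#' @return A tibble with the same columns as `tidy(comparison)`.
#' @export
read_cohort_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
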