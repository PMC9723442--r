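#' Clinical dose constraints for bilateral-lung SBRT (50 Gy / 5 fx)
#'
#' The planning objectives and organ-at-risk constraints used for
#' 50 Gy in 5 fraction bilateral lung SBRT plan review. Each row is one
#' constraint: a structure, a metric descriptor, a comparator and a
#' threshold. Metric descriptors are resolved by
#' [evaluate_constraints()]:
#' `d_max`/`d_mean` (Gy), `v_pct@x` (% of structure receiving >= x Gy),
#' `v_cc@x` (cc receiving >= x Gy), `v_below_cc@x` (cc receiving
#' < x Gy), `d_cc@x` (Gy to the hottest x cc), `coverage` (% of target
#' at the prescription dose), `pidl` (%).
#'
#' The `~` comparator (the ~70% prescription isodose line objective) is
#' a soft band, evaluated as a pass within `pidl_band` percentage points
#' in [evaluate_constraints()]; all other comparators are strict.
#'
#' @return A tibble with columns `structure`, `metric`, `comparator`,
#'   `threshold`, `units`.
#' @export
default_constraints <- function() {
  tibble::tribble(
    ~structure,          ~metric,           ~comparator, ~threshold, ~units,
    "ptv1",              "coverage",        ">=",        95,         "%",
    "ptv2",              "coverage",        ">=",        95,         "%",
    "ptv12",             "coverage",        ">=",        95,         "%",
    "ptv12",             "pidl",            "~",         70,         "%",
    "lungs",             "v_pct@5",         "<",         60,         "%",
    "lungs",             "v_pct@20",        "<",         25,         "%",
    "lungs",             "v_below_cc@12.5", ">",         1500,       "cc",
    "lungs",             "v_below_cc@13.5", ">",         1000,       "cc",
    "heart",             "d_max",           "<",         38,         "Gy",
    "heart",             "d_mean",          "<",         12,         "Gy",
    "heart",             "v_cc@32",         "<",         15,         "cc",
    "cord",              "d_max",           "<",         27,         "Gy",
    "cord",              "d_cc@0.25",       "<",         22,         "Gy",
    "cord",              "d_cc@1.2",        "<",         13.5,       "Gy",
    "trachea",           "d_max",           "<",         40,         "Gy",
    "trachea",           "v_cc@16.5",       "<",         4,          "cc",
    "bronchus",          "d_max",           "<",         40,         "Gy",
    "bronchus",          "v_cc@16.5",       "<",         4,          "cc",
    "esophagus",         "d_max",           "<",         35,         "Gy",
    "esophagus",         "v_cc@19.5",       "<",         5,          "cc"
  )
}

#' Published reference cohort summaries (10-patient bilateral-lung SBRT)
#'
#' Per-arm mean +/- SD summaries from a published 10-patient
#' single-planning (Plan S) versus double-planning (Plan D) CyberKnife
#' bilateral-lung SBRT comparison, prescription 50 Gy in 5 fractions.
#' These printed cohort means are shipped as reference inputs for
#' worked-example arithmetic (index-convention checks, percent-reduction
#' recomputation, constraint audits of the published means); they are
#' not outputs of this package.
#'
#' `table` is one of `"ptv"` (target dosimetry: coverage, Dmax, Dmin,
#' Dmean, CI, nCI, HI, GI per target), `"oar"` (organ-at-risk
#' dosimetry), `"eud"` (equivalent uniform doses).
#'
#' @param table which summary table to return.
#' @return A tibble with columns `structure`, `metric`, `units`,
#'   `mean_s`, `sd_s`, `mean_d`, `sd_d`, `p_value`.
#' @export
reference_cohort_summary <- function(table = c("ptv", "oar", "eud")) {
  table <- match.arg(table)
  switch(table,
    ptv = tibble::tribble(
      ~structure, ~metric,    ~units, ~mean_s, ~sd_s, ~mean_d, ~sd_d, ~p_value,
      "ptv1",  "coverage_pct", "%",   96.32, 1.56, 95.58, 0.90, 0.155,
      "ptv1",  "d_max",        "Gy",  70.21, 4.12, 72.89, 2.06, 0.050,
      "ptv1",  "d_min",        "Gy",  46.05, 1.18, 45.20, 1.42, 0.023,
      "ptv1",  "d_mean",       "Gy",  56.42, 1.50, 57.83, 1.33, 0.032,
      "ptv1",  "ci",           "",    1.20,  0.13, 1.14,  0.08, 0.100,
      "ptv1",  "nci",          "",    1.25,  0.14, 1.19,  0.08, 0.130,
      "ptv1",  "hi",           "",    1.40,  0.08, 1.46,  0.04, 0.050,
      "ptv1",  "gi",           "",    5.76,  1.32, 5.19,  0.81, 0.070,
      "ptv2",  "coverage_pct", "%",   96.18, 1.53, 96.14, 1.55, 0.962,
      "ptv2",  "d_max",        "Gy",  71.74, 3.78, 73.38, 1.61, 0.248,
      "ptv2",  "d_min",        "Gy",  45.86, 1.04, 46.76, 3.83, 0.434,
      "ptv2",  "d_mean",       "Gy",  56.82, 1.48, 58.75, 1.47, 0.006,
      "ptv2",  "ci",           "",    1.19,  0.15, 1.23,  0.14, 0.647,
      "ptv2",  "nci",          "",    1.24,  0.14, 1.27,  0.13, 0.596,
      "ptv2",  "hi",           "",    1.43,  0.08, 1.47,  0.03, 0.248,
      "ptv2",  "gi",           "",    6.28,  1.25, 5.29,  0.70, 0.036,
      "ptv12", "coverage_pct", "%",   96.42, 0.83, 95.83, 0.65, 0.056,
      "ptv12", "d_max",        "Gy",  73.22, 2.22, 74.42, 1.58, 0.184,
      "ptv12", "d_min",        "Gy",  45.22, 0.89, 44.74, 1.26, 0.162,
      "ptv12", "d_mean",       "Gy",  56.68, 1.26, 58.17, 0.98, 0.013,
      "ptv12", "ci",           "",    1.19,  0.13, 1.16,  0.06, 0.422,
      "ptv12", "nci",          "",    1.24,  0.13, 1.21,  0.06, 0.537,
      "ptv12", "hi",           "",    1.46,  0.04, 1.49,  0.03, 0.184,
      "ptv12", "gi",           "",    5.85,  1.03, 5.18,  0.58, 0.031
    ),
    oar = tibble::tribble(
      ~structure, ~metric,      ~units, ~mean_s, ~sd_s, ~mean_d, ~sd_d, ~p_value,
      "lungs",    "d_mean",          "Gy", 6.61,    3.08,   6.21,    2.96,  0.082,
      "lungs",    "v_pct@5",         "%",  38.78,   17.70,  37.06,   20.35, 0.951,
      "lungs",    "v_pct@20",        "%",  8.01,    5.07,   7.16,    4.84,  0.017,
      "lungs",    "v_below_cc@12.5", "cc", 2574.08, 833.09, 2598.05, 827.63, 0.096,
      "lungs",    "v_below_cc@13.5", "cc", 2608.84, 829.77, 2649.26, 847.18, 0.05,
      "heart",    "d_mean",          "Gy", 3.26,    1.63,   3.04,    1.60,  0.333,
      "heart",    "d_cc@15",         "Gy", 11.11,   5.09,   9.49,    3.69,  0.049,
      "cord",     "d_mean",          "Gy", 2.25,    1.37,   2.36,    1.42,  0.406,
      "cord",     "d_cc@0.25",       "Gy", 9.76,    4.77,   9.235,   4.09,  0.506,
      "cord",     "d_cc@1.2",        "Gy", 8.34,    4.30,   8.15,    3.73,  0.776,
      "trachea",  "d_mean",          "Gy", 4.21,    2.17,   3.86,    3.15,  0.328,
      "trachea",  "d_max",           "Gy", 12.69,   8.79,   11.51,   7.43,  0.354,
      "bronchus", "d_mean",          "Gy", 6.11,    4.60,   4.96,    3.81,  0.012,
      "bronchus", "d_max",           "Gy", 19.82,   9.31,   16.07,   9.14,  0.003,
      "trachea_bronchus", "d_mean",  "Gy", 5.23,    3.45,   4.44,    3.03,  0.068,
      "trachea_bronchus", "d_max",   "Gy", 20.17,   9.48,   16.51,   8.54,  0.011,
      "trachea_bronchus", "d_cc@4",  "Gy", 11.79,   6.34,   10.47,   5.54,  0.066,
      "esophagus", "d_mean",         "Gy", 4.09,    1.91,   3.33,    1.91,  0.068,
      "esophagus", "d_max",          "Gy", 15.95,   6.26,   12.7,    4.94,  0.013,
      "esophagus", "d_cc@5",         "Gy", 9.75,    4.04,   7.96,    3.38,  0.064
    ),
    eud = tibble::tribble(
      ~structure, ~metric,  ~units, ~mean_s, ~sd_s, ~mean_d, ~sd_d, ~p_value,
      "ptv1",      "eud", "Gy", 94.18, 1.67, 95.18, 0.93, 0.229,
      "ptv2",      "eud", "Gy", 94.58, 1.91, 96.97, 1.83, 0.105,
      "ptv12",     "eud", "Gy", 94.41, 1.51, 95.55, 0.67, 0.140,
      "lungs",     "eud", "Gy", 9.21,  4.12, 8.61,  3.97, 0.049,
      "heart",     "eud", "Gy", 6.21,  3.15, 4.98,  2.38, 0.022,
      "cord",      "eud", "Gy", 8.80,  4.48, 8.02,  3.64, 0.471,
      "esophagus", "eud", "Gy", 13.33, 5.58, 9.72,  4.30, 0.099
    )
  )
}
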