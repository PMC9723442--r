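#' Evaluate one plan against one structure set
#'
#' Computes, for a single plan: the full target index set
#' ([conformity_indices()]) per target, the DVH metric families used in
#' plan review for every organ at risk, and the gEUD of each structure
#' that has accepted model parameters. Returns everything as one long
#' tidy table keyed by structure and metric — the per-patient building
#' block of the cohort comparison.
#'
#' @param plan a [plan_dose()] (for a double plan, the superimposed
#'   total from [sum_doses()]).
#' @param structures a [structure_set()] on the plan's geometry.
#' @param eud_params gEUD parameter table, see [default_eud_params()].
#' @param targets character vector of target structure names to score
#'   with conformity indices.
#' @param bin_width DVH bin width, Gy, for the gEUD path.
#' @return A tibble with columns `structure`, `metric`, `value`,
#'   `units`.
#' @export
evaluate_plan <- function(plan, structures,
                          eud_params = default_eud_params(),
                          targets = c("ptv1", "ptv2", "ptv12"),
                          bin_width = 0.01) {
  stopifnot(inherits(plan, "plan_dose"), inherits(structures, "structure_set"))
  pd <- plan$prescription_dose_gy
  rows <- list()

  for (tg in intersect(targets, names(structures))) {
    ci <- conformity_indices(plan$grid, structures[[tg]], structures$body, pd)
    base <- dvh_metrics(plan$grid, structures[[tg]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      structure = tg,
      metric = c("coverage_pct", "d_max", "d_min", "d_mean",
                 "ci", "nci", "hi", "gi", "pidl_pct"),
      value = c(ci$coverage_pct,
                base$value[base$metric == "d_max"],
                base$value[base$metric == "d_min"],
                base$value[base$metric == "d_mean"],
                ci$ci, ci$nci, ci$hi, ci$gi, ci$pidl_pct),
      units = c("%", "Gy", "Gy", "Gy", "", "", "", "", "%")
    )
  }

  oar_queries <- list(
    lungs = list(v_pct_at = c(5, 20), v_below_cc_at = c(12.5, 13.5)),
    heart = list(d_at_cc = 15),
    cord = list(d_at_cc = c(0.25, 1.2)),
    trachea = list(),
    bronchus = list(),
    trachea_bronchus = list(d_at_cc = 4),
    esophagus = list(d_at_cc = 5)
  )
  for (nm in intersect(names(oar_queries), names(structures))) {
    q <- oar_queries[[nm]]
    m <- do.call(dvh_metrics, c(list(dose = plan$grid,
                                     mask = structures[[nm]]), q))
    m <- m[m$metric != "d_min", ]
    names(m)[names(m) == "value"] <- "value"
    rows[[length(rows) + 1]] <- m[, c("structure", "metric", "value",
                                      "units")]
  }

  eud_structs <- intersect(
    c("ptv1", "ptv2", "ptv12", "lungs", "heart", "cord", "esophagus"),
    names(structures))
  for (nm in eud_structs) {
    dvh <- cumulative_dvh(plan$grid, structures[[nm]],
                          bin_width = bin_width)
    res <- geud(dvh, n_fractions = plan$n_fractions, params = eud_params)
    rows[[length(rows) + 1]] <- tibble::tibble(
      structure = nm, metric = "eud", value = res$eud_gy, units = "Gy")
  }
  dplyr::bind_rows(rows)
}

#' Run the full single-plan vs double-plan comparison
#'
#' End-to-end pipeline over a synthetic paired cohort: generate (or
#' accept) `n` phantoms, superimpose each patient's double-plan
#' components, evaluate every plan ([evaluate_plan()]), audit each total
#' plan against the clinical constraints, and produce the paired cohort
#' comparison ([cohort_report()]). Optionally writes the report CSV/JSON
#' plus a run manifest to `output_dir`. Fully reproducible from
#' `master_seed`.
#'
#' @param n cohort size (default 10).
#' @param master_seed integer master seed.
#' @param cohort optionally, a pre-generated [generate_cohort()] result
#'   (then `n`/`master_seed` only label the manifest).
#' @param constraints constraint table for the audit.
#' @param eud_params gEUD parameter table.
#' @param output_dir if non-NULL, report files are written here.
#' @param phantom_args,dose_args generator overrides, see
#'   [generate_cohort()].
#' @return A list: `per_plan` (long tibble of every metric, with
#'   `patient` and `arm`), `audit` (constraint results per patient and
#'   arm, with `patient`/`arm` columns), `comparison` (a
#'   `cohort_comparison`), `seed`.
#' @export
run_compare <- function(n = 10, master_seed = 20221121, cohort = NULL,
                        constraints = default_constraints(),
                        eud_params = default_eud_params(),
                        output_dir = NULL,
                        phantom_args = list(), dose_args = list()) {
  set.seed(master_seed)
  child_seeds <- sample.int(2^31 - 2, n)
  per_plan <- list()
  audits <- list()
  for (i in seq_len(n)) {
    pat <- if (is.null(cohort)) {
      generate_patient(child_seeds[i], phantom_args, dose_args,
                       patient = sprintf("P%02d", i))
    } else {
      cohort[[i]]
    }
    plan_d <- sum_doses(pat$plan_d_components[[1]],
                        pat$plan_d_components[[2]])
    for (arm in c("S", "D")) {
      plan <- if (arm == "S") pat$plan_s else plan_d
      ev <- evaluate_plan(plan, pat$phantom$structures,
                          eud_params = eud_params)
      ev$patient <- pat$patient
      ev$arm <- arm
      per_plan[[length(per_plan) + 1]] <- ev
      aud <- evaluate_constraints(plan, pat$phantom$structures,
                                  constraints = constraints)
      aud$patient <- pat$patient
      aud$arm <- arm
      audits[[length(audits) + 1]] <- aud
    }
  }
  per_plan <- dplyr::bind_rows(per_plan)
  audit <- dplyr::bind_rows(audits)
  comparison <- cohort_report(per_plan[, c("patient", "arm", "structure",
                                           "metric", "value")])
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_report(comparison, output_dir, seed = master_seed)
    readr::write_csv(per_plan, file.path(output_dir, "per_plan_metrics.csv"))
    readr::write_csv(audit, file.path(output_dir, "constraint_audit.csv"))
    jsonlite::write_json(
      list(n = n, master_seed = master_seed,
           child_seeds = child_seeds,
           package_version = as.character(utils::packageVersion("sbrteval"))),
      file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(per_plan = per_plan, audit = audit, comparison = comparison,
       seed = master_seed)
}
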