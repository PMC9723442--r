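#' Homogeneity index
#'
#' HI = Dmax / prescription dose: the maximum dose in the plan relative
#' to the prescription. For CyberKnife-style plans prescribed to a ~70%
#' isodose line, HI is typically ~1.4.
#'
#' @param d_max maximum dose, Gy (> 0).
#' @param prescription_dose prescription dose, Gy (> 0).
#' @return Dimensionless HI.
#' @export
homogeneity_index <- function(d_max, prescription_dose) {
  stopifnot(d_max > 0, prescription_dose > 0)
  d_max / prescription_dose
}

#' Prescription isodose line
#'
#' PIDL = 100 x prescription dose / Dmax, the isodose level (as percent of
#' the maximum dose) at which the plan is prescribed; the reciprocal of
#' the homogeneity index, as a percentage. Clinically targeted near 70%
#' for CyberKnife SBRT.
#'
#' @inheritParams homogeneity_index
#' @return PIDL in percent.
#' @export
pidl <- function(d_max, prescription_dose) {
  stopifnot(d_max > 0, prescription_dose > 0)
  100 * prescription_dose / d_max
}

#' Conformity indices of a target at the prescription isodose
#'
#' Computes, from the voxel dose distribution:
#' \itemize{
#'   \item `piv_cc` — prescription isodose volume, the body volume
#'     receiving at least the prescription dose;
#'   \item `tv_piv_cc` — the part of the target inside the prescription
#'     isodose;
#'   \item `coverage_pct` — 100 x TV_PIV / TV;
#'   \item `ci` — conformity index PIV / TV_PIV;
#'   \item `nci` — new conformity index (TV x PIV) / TV_PIV^2, i.e.
#'     CI divided by the coverage fraction (the CyberKnife/MultiPlan
#'     convention);
#'   \item `hi`, `gi`, `pidl_pct` — homogeneity index, gradient index and
#'     prescription isodose line for the same plan.
#' }
#' `nci >= ci >= 1` always; both equal 1 only for a perfectly conformal,
#' fully covering plan. If no target voxel reaches the prescription dose
#' the indices are undefined and an error is raised.
#'
#' @param dose a [dose_grid()] of total plan dose.
#' @param target target [roi_mask()] (non-empty).
#' @param body body [roi_mask()] over which PIV and GI volumes are
#'   counted.
#' @param prescription_dose Gy, > 0.
#' @param gi_reference `"prescription"` (default) computes the gradient
#'   index against half the prescription dose; `"maximum"` against half
#'   the maximum dose.
#' @return A one-row tibble with columns `coverage_pct`, `tv_cc`,
#'   `piv_cc`, `tv_piv_cc`, `ci`, `nci`, `hi`, `gi`, `pidl_pct`.
#' @export
conformity_indices <- function(dose, target, body, prescription_dose,
                               gi_reference = c("prescription", "maximum")) {
  stopifnot(prescription_dose > 0)
  gi_reference <- match.arg(gi_reference)
  dt <- structure_doses(dose, target)
  if (length(dt) == 0) {
    stop(sprintf("target '%s' has an empty mask", target$name),
         call. = FALSE)
  }
  assert_same_geometry(dose, body)
  vvox <- voxel_volume_cc(dose)
  tv <- length(dt) * vvox
  tv_piv <- sum(dt >= prescription_dose) * vvox
  if (tv_piv == 0) {
    stop(sprintf(
      "no voxel of target '%s' reaches the prescription dose %g Gy; %s",
      target$name, prescription_dose,
      "conformity indices are undefined"), call. = FALSE)
  }
  db <- dose$values[body$occupancy]
  piv <- sum(db >= prescription_dose) * vvox
  cov <- 100 * tv_piv / tv
  d_max <- max(dt)
  tibble::tibble(
    structure = target$name,
    coverage_pct = cov,
    tv_cc = tv,
    piv_cc = piv,
    tv_piv_cc = tv_piv,
    ci = piv / tv_piv,
    nci = tv * piv / tv_piv^2,
    hi = homogeneity_index(d_max, prescription_dose),
    gi = gradient_index(dose, body, prescription_dose,
                        reference = gi_reference),
    pidl_pct = pidl(d_max, prescription_dose)
  )
}

#' Gradient index
#'
#' GI = V(half reference dose) / V(reference dose), counted over the body
#' mask — the factor by which the half-prescription isodose volume
#' exceeds the prescription isodose volume. Smaller GI means steeper dose
#' falloff outside the target; SBRT lung plans typically score 3-6.
#'
#' @inheritParams conformity_indices
#' @param reference `"prescription"` (default, the Paddick form: the
#'   half-dose threshold is PD/2) or `"maximum"` (half-dose threshold
#'   Dmax/2); the denominator is the prescription isodose volume in both.
#'   Only the prescription form is used by the shipped pipeline.
#' @return Dimensionless GI (> 1 whenever any dose falls between the two
#'   thresholds).
#' @export
gradient_index <- function(dose, body, prescription_dose,
                           reference = c("prescription", "maximum")) {
  stopifnot(prescription_dose > 0)
  reference <- match.arg(reference)
  assert_same_geometry(dose, body)
  db <- dose$values[body$occupancy]
  half <- if (reference == "prescription") {
    prescription_dose / 2
  } else {
    max(db) / 2
  }
  v_pd <- sum(db >= prescription_dose)
  if (v_pd == 0) {
    stop(sprintf(
      "no body voxel reaches the prescription dose %g Gy; %s",
      prescription_dose, "gradient index is undefined"), call. = FALSE)
  }
  sum(db >= half) / v_pd
}
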