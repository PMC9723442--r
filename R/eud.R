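#' Default gEUD model parameters per structure
#'
#' Volume-effect exponent `a` and linear-quadratic `alpha/beta` (Gy) for
#' the structures evaluated by the pipeline, as used by the
#' phenomenological (Gay-Niemierko) gEUD model with EQD2 fractionation
#' correction. `a = 1` gives the mean dose (parallel organ, lung);
#' large positive `a` weights hot spots (serial organs: cord,
#' esophagus). The tumor target is evaluated with the positive `a`
#' convention by default (see `tumor_a_negative` in [geud()]).
#'
#' No validated parameters exist for trachea or bronchus; they are
#' deliberately absent and [geud()] refuses to evaluate them rather than
#' guessing.
#'
#' @return A tibble with columns `structure`, `a`, `alpha_beta`.
#' @export
default_eud_params <- function() {
  tibble::tribble(
    ~structure,  ~a,    ~alpha_beta,
    "ptv",        10,    10,
    "lungs",      1,     4,
    "heart",      3,     3.7,
    "cord",       20,    3,
    "esophagus",  16.67, 4.9
  )
}

#' Look up gEUD parameters for a named structure
#'
#' Target structures `ptv1`, `ptv2`, `ptv12` map to the `ptv` row.
#'
#' @param structure canonical structure name.
#' @param params parameter tibble as from [default_eud_params()].
#' @return A one-row tibble, or an error for structures with no
#'   accepted model parameters (trachea, bronchus).
#' @export
eud_params_for <- function(structure, params = default_eud_params()) {
  key <- if (grepl("^ptv", structure)) "ptv" else structure
  row <- params[params$structure == key, ]
  if (nrow(row) == 0) {
    stop(sprintf(
      "no accepted gEUD model parameters for structure '%s'", structure),
      call. = FALSE)
  }
  row
}

#' Fractionation (EQD2) correction of a total dose
#'
#' Converts a total dose `D` delivered in `n_fractions` equal fractions
#' to the biologically equivalent dose delivered at the reference 2 Gy
#' per fraction, via the linear-quadratic model:
#' \deqn{EQD = D \frac{\alpha/\beta + D/n_f}{\alpha/\beta + d_{ref}}}
#' with \eqn{d_{ref} = 2} Gy. When the fraction dose already equals
#' 2 Gy, EQD equals the physical dose.
#'
#' @param total_dose numeric vector of total physical doses, Gy (>= 0).
#' @param alpha_beta tissue alpha/beta ratio, Gy (> 0).
#' @param n_fractions number of fractions (>= 1).
#' @param reference_fraction_dose reference fraction size, Gy (default 2).
#' @return EQD values, Gy, same length as `total_dose`.
#' @export
eqd_correct <- function(total_dose, alpha_beta, n_fractions = 5,
                        reference_fraction_dose = 2) {
  stopifnot(alpha_beta > 0, n_fractions >= 1, all(total_dose >= 0))
  total_dose * (alpha_beta + total_dose / n_fractions) /
    (alpha_beta + reference_fraction_dose)
}

#' Generalized equivalent uniform dose
#'
#' The gEUD is the uniform dose that would produce the same
#' radiobiological effect as the actual inhomogeneous distribution: the
#' power mean of exponent `a` of the per-volume-element
#' fractionation-corrected doses,
#' \deqn{EUD = \left(\sum_i v_i \, EQD_i^{a}\right)^{1/a},}
#' where the \eqn{v_i} are fractional volumes of the differential DVH
#' (summing to 1) and \eqn{EQD_i} is the [eqd_correct()] conversion of
#' bin dose \eqn{D_i} assuming it was delivered in `n_fractions` equal
#' fractions. `a = 1` yields the mean EQD; large positive `a` approaches
#' the maximum, large negative `a` the minimum.
#'
#' @param dvh a [cumulative_dvh()] (the differential form is derived
#'   internally), or a numeric vector of raw voxel doses via
#'   `geud_from_doses()`.
#' @param structure canonical structure name used to look up `(a,
#'   alpha/beta)`; alternatively pass `a` and `alpha_beta` directly.
#' @param a,alpha_beta model parameters; default looked up from `params`.
#' @param n_fractions fractions the total dose was delivered in.
#' @param params parameter table, see [default_eud_params()].
#' @param tumor_a_negative if TRUE and the structure is a target, the
#'   sign of `a` is flipped (the tumor-conventional negative exponent,
#'   penalizing cold spots). Default FALSE: parameters used exactly as
#'   tabulated.
#' @param eps zero-dose floor (Gy) applied when `a < 0` so the power
#'   mean stays finite; irrelevant for the shipped all-positive
#'   parameters.
#' @return A one-row tibble: `structure`, `eud_gy`, `a`, `alpha_beta`,
#'   `n_fractions`.
#' @export
geud <- function(dvh, structure = dvh$structure, a = NULL,
                 alpha_beta = NULL, n_fractions = 5,
                 params = default_eud_params(),
                 tumor_a_negative = FALSE, eps = 1e-6) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  if (dvh$total_volume_cc <= 0) {
    stop("zero total volume in DVH", call. = FALSE)
  }
  diff_dvh <- differential_dvh(dvh)
  keep <- diff_dvh$frac_volume > 0
  geud_core(diff_dvh$dose_gy[keep], diff_dvh$frac_volume[keep],
            structure, a, alpha_beta, n_fractions, params,
            tumor_a_negative, eps)
}

#' @rdname geud
#' @param doses numeric vector of raw structure voxel doses, Gy (the
#'   unbinned validation path; equal voxel volumes assumed).
#' @export
geud_from_doses <- function(doses, structure, a = NULL, alpha_beta = NULL,
                            n_fractions = 5, params = default_eud_params(),
                            tumor_a_negative = FALSE, eps = 1e-6) {
  stopifnot(length(doses) > 0)
  geud_core(doses, rep(1 / length(doses), length(doses)),
            structure, a, alpha_beta, n_fractions, params,
            tumor_a_negative, eps)
}

geud_core <- function(dose, frac_volume, structure, a, alpha_beta,
                      n_fractions, params, tumor_a_negative, eps) {
  if (is.null(a) || is.null(alpha_beta)) {
    row <- eud_params_for(structure, params)
    if (is.null(a)) a <- row$a
    if (is.null(alpha_beta)) alpha_beta <- row$alpha_beta
  }
  if (a == 0) stop("gEUD exponent a must be nonzero", call. = FALSE)
  if (tumor_a_negative && grepl("^ptv", structure)) a <- -abs(a)
  frac_volume <- frac_volume / sum(frac_volume)
  if (a < 0) dose <- pmax(dose, eps)
  eqd <- eqd_correct(dose, alpha_beta, n_fractions)
  # log-space power mean for numerical stability at large |a|
  lw <- log(frac_volume) + a * log(pmax(eqd, eps))
  m <- max(lw)
  eud <- exp((m + log(sum(exp(lw - m)))) / a)
  tibble::tibble(structure = structure, eud_gy = eud, a = a,
                 alpha_beta = alpha_beta, n_fractions = n_fractions)
}

#' Percent reduction of a metric between paired plans
#'
#' `100 * (value_s - value_d) / value_s`: the signed percentage by which
#' the double-planning value is lower than the single-planning value.
#' Positive when the double plan spares more.
#'
#' @param value_s single-plan value (nonzero).
#' @param value_d double-plan value.
#' @return Signed percent reduction.
#' @export
percent_reduction <- function(value_s, value_d) {
  if (any(value_s == 0)) {
    stop("percent reduction undefined for a zero reference value",
         call. = FALSE)
  }
  100 * (value_s - value_d) / value_s
}
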