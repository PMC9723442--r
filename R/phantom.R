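#' Specification of a synthetic bilateral-lung phantom
#'
#' Geometry of a voxelized thorax phantom: a body ellipsoid, two lung
#' ellipsoids, mediastinal tube structures (spinal cord, trachea
#' branching into two bronchi, esophagus), a heart ellipsoid between the
#' lungs, and one spherical gross tumor per lung that is expanded
#' isotropically by `gtv_to_ptv_margin` to its planning target volume.
#' A voxel belongs to a structure iff its center lies inside the
#' analytic solid.
#'
#' Defaults state the world the evaluation emulates: 2.5 mm isotropic
#' voxels, a 5 mm GTV-to-PTV margin, and PTV volumes drawn log-uniformly
#' within the clinically observed ranges 1.67-62.31 cc (PTV1, left) and
#' 4.49-26.21 cc (PTV2, right); both targets are peripheral (lateral in
#' their lung) and never overlap.
#'
#' @param spacing_mm isotropic voxel spacing, mm.
#' @param dims voxel counts (x = left-right, y = anterior-posterior,
#'   z = cranio-caudal).
#' @param ptv1_volume_cc,ptv2_volume_cc target PTV volumes, cc; `NULL`
#'   (default) draws them log-uniformly within the observed ranges.
#' @param gtv_to_ptv_margin_mm isotropic GTV to PTV expansion, mm.
#' @param seed integer seed controlling every random draw for this
#'   phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing_mm = 2.5, dims = c(110, 84, 96),
                         ptv1_volume_cc = NULL, ptv2_volume_cc = NULL,
                         gtv_to_ptv_margin_mm = 5, seed = 1L) {
  stopifnot(spacing_mm > 0, length(dims) == 3, all(dims >= 16),
            gtv_to_ptv_margin_mm >= 0)
  structure(
    list(spacing_mm = spacing_mm, dims = as.integer(dims),
         ptv1_volume_cc = ptv1_volume_cc, ptv2_volume_cc = ptv2_volume_cc,
         ptv1_range_cc = c(1.67, 62.31), ptv2_range_cc = c(4.49, 26.21),
         gtv_to_ptv_margin_mm = gtv_to_ptv_margin_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

sphere_radius_mm <- function(volume_cc) (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)

# voxel-center coordinate arrays for a spec geometry, centered on 0
phantom_coords <- function(spacing, dims) {
  ext <- (dims - 1) * spacing
  origin <- -ext / 2
  spacing <- rep(spacing, length.out = 3)
  list(
    origin = origin,
    x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
    y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
    z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  )
}

# broadcast per-axis coordinate vectors to full-grid arrays
expand_axis <- function(v, dims, axis) {
  if (axis == 1) array(rep(v, times = dims[2] * dims[3]), dim = dims)
  else if (axis == 2) array(rep(rep(v, each = dims[1]), times = dims[3]),
                            dim = dims)
  else array(rep(v, each = dims[1] * dims[2]), dim = dims)
}

ellipsoid_mask <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

cylinder_z_mask <- function(X, Y, Z, cx, cy, radius, z_lo, z_hi) {
  (X - cx)^2 + (Y - cy)^2 <= radius^2 & Z >= z_lo & Z <= z_hi
}

#' Generate a synthetic bilateral-lung phantom
#'
#' Builds the full [structure_set()] of a thorax phantom from a
#' [phantom_spec()]: body, combined lungs, heart, spinal cord, trachea,
#' left/right bronchus (plus the combined trachea+bronchus structure),
#' esophagus, and one spherical GTV-derived PTV per lung (`ptv1` left,
#' `ptv2` right, `ptv12` their union). Reproducible: the same spec and
#' seed give a bit-identical structure set. The realized PTV mask volume
#' tracks the requested analytic volume to within voxelization error.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `structures` (a `structure_set`),
#'   `geometry` (an all-zero [dose_grid()] carrying the frame), and
#'   `params` (realized centers/radii, for the dose model).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  spacing <- rep(spec$spacing_mm, 3)
  dims <- spec$dims
  cc <- phantom_coords(spacing, dims)
  X <- expand_axis(cc$x, dims, 1)
  Y <- expand_axis(cc$y, dims, 2)
  Z <- expand_axis(cc$z, dims, 3)
  frame <- sprintf("phantom-seed%d", spec$seed)

  ext <- (dims - 1) * spacing
  body_semi <- c(0.46 * ext[1], 0.42 * ext[2], 0.48 * ext[3])
  body_occ <- ellipsoid_mask(X, Y, Z, c(0, 0, 0), body_semi)

  lung_semi <- c(0.42 * body_semi[1], 0.70 * body_semi[2],
                 0.78 * body_semi[3])
  lung_off <- 0.52 * body_semi[1]
  lungL <- ellipsoid_mask(X, Y, Z, c(-lung_off, 0, 0), lung_semi)
  lungR <- ellipsoid_mask(X, Y, Z, c(lung_off, 0, 0), lung_semi)

  heart_occ <- ellipsoid_mask(X, Y, Z, c(-4, 12, -0.15 * body_semi[3]),
                              c(0.16 * ext[1], 0.14 * ext[2],
                                0.16 * ext[3]))
  heart_occ <- heart_occ & !lungL & !lungR

  z_top <- 0.9 * body_semi[3]
  cord_occ <- cylinder_z_mask(X, Y, Z, 0, 0.72 * body_semi[2], 4.5,
                              -z_top, z_top) & body_occ
  trachea_occ <- cylinder_z_mask(X, Y, Z, 0, -6, 7,
                                 0.12 * body_semi[3], z_top) & body_occ
  bronchus_occ <-
    (cylinder_z_mask(X, Y, Z, -0.35 * lung_off, -6, 5.5,
                     -0.10 * body_semi[3], 0.12 * body_semi[3]) |
     cylinder_z_mask(X, Y, Z, 0.35 * lung_off, -6, 5.5,
                     -0.10 * body_semi[3], 0.12 * body_semi[3])) & body_occ
  esoph_occ <- cylinder_z_mask(X, Y, Z, 0, 0.45 * body_semi[2], 5,
                               -z_top, z_top) & body_occ

  # targets: peripheral (lateral) positions, jittered per phantom
  v1 <- spec$ptv1_volume_cc %||%
    exp(stats::runif(1, log(spec$ptv1_range_cc[1]),
                     log(spec$ptv1_range_cc[2])))
  v2 <- spec$ptv2_volume_cc %||%
    exp(stats::runif(1, log(spec$ptv2_range_cc[1]),
                     log(spec$ptv2_range_cc[2])))
  r1_ptv <- sphere_radius_mm(v1)
  r2_ptv <- sphere_radius_mm(v2)
  r1_gtv <- max(r1_ptv - spec$gtv_to_ptv_margin_mm, 1)
  r2_gtv <- max(r2_ptv - spec$gtv_to_ptv_margin_mm, 1)

  place_target <- function(side, r_ptv) {
    # keep the whole PTV inside its lung ellipsoid with a safety shell
    guard <- r_ptv + spacing[1]
    max_dx <- lung_semi[1] - guard
    if (max_dx < 0) {
      stop(sprintf("PTV radius %.1f mm incompatible with lung size",
                   r_ptv), call. = FALSE)
    }
    dx <- side * (lung_off + stats::runif(1, 0.2, 0.7) * max_dx)
    dy <- stats::runif(1, -0.3, 0.3) * (lung_semi[2] - guard)
    dz <- stats::runif(1, -0.35, 0.35) * (lung_semi[3] - guard)
    # shrink toward the lung center until fully inside
    ctr <- c(dx - side * lung_off, dy, dz)
    scale <- min(1, 0.98 / sqrt(sum((abs(ctr) + guard)^2 / lung_semi^2)))
    c(side * lung_off, 0, 0) + ctr * scale
  }
  c1 <- place_target(-1, r1_ptv)
  c2 <- place_target(+1, r2_ptv)

  sphere_mask <- function(center, r) {
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= r^2
  }
  gtv1 <- sphere_mask(c1, r1_gtv)
  gtv2 <- sphere_mask(c2, r2_gtv)
  ptv1 <- sphere_mask(c1, r1_gtv + spec$gtv_to_ptv_margin_mm)
  ptv2 <- sphere_mask(c2, r2_gtv + spec$gtv_to_ptv_margin_mm)

  mk <- function(name, occ) {
    roi_mask(name, occ, spacing = spacing, origin = cc$origin,
             frame_id = frame)
  }
  structures <- structure_set(list(
    body = mk("body", body_occ),
    lungs = mk("lungs", lungL | lungR),
    heart = mk("heart", heart_occ),
    cord = mk("cord", cord_occ),
    trachea = mk("trachea", trachea_occ),
    bronchus = mk("bronchus", bronchus_occ),
    esophagus = mk("esophagus", esoph_occ),
    gtv1 = mk("gtv1", gtv1),
    gtv2 = mk("gtv2", gtv2),
    ptv1 = mk("ptv1", ptv1),
    ptv2 = mk("ptv2", ptv2)
  ))
  geometry <- dose_grid(array(0, dim = dims), spacing = spacing,
                        origin = cc$origin, frame_id = frame)
  list(
    structures = structures,
    geometry = geometry,
    params = list(
      ptv1 = list(center = c1, radius_mm = r1_gtv +
                    spec$gtv_to_ptv_margin_mm, volume_cc = v1),
      ptv2 = list(center = c2, radius_mm = r2_gtv +
                    spec$gtv_to_ptv_margin_mm, volume_cc = v2)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of the synthetic dose model
#'
#' Phenomenological per-target dose kernel (not a beam model),
#' emulating a plan prescribed to the ~70% isodose surface at the PTV
#' boundary: a hot core at `prescription * peak` in the inner 30% of
#' the PTV radius, a Gaussian ramp meeting exactly the prescription
#' dose at the PTV surface, and a Gaussian shell falloff
#' `exp(-(r - R)^2 / (2 sigma^2))` outside it; plus a low-dose bath
#' over the body (smoothly apodized toward the body surface) and
#' optional Gaussian noise clipped at 0 Gy. With zero noise the
#' prescription isodose coincides with the PTV surface, so coverage is
#' 100% and the maximum dose is exactly `prescription * peak` (PIDL =
#' 100/peak %).
#'
#' The per-arm defaults state the contrast the evaluation emulates:
#' the double plan (arm D) has a steeper falloff (`sigma_d_mm <
#' sigma_s_mm`) and a smaller low-dose bath (`bath_d_gy < bath_s_gy`)
#' than the single plan, so its mid- and low-dose spill is smaller,
#' while its in-target peak is slightly hotter (`peak_d > peak_s`,
#' matching the clinically observed homogeneity indices near 1.40 for
#' single and 1.46 for double planning, i.e. a prescription isodose
#' line near 70%).
#'
#' @param prescription_dose_gy prescription, Gy (total).
#' @param n_fractions fraction count.
#' @param peak_s,peak_d in-target dose as a multiple of the
#'   prescription, per arm.
#' @param sigma_s_mm,sigma_d_mm Gaussian falloff scale, mm, per arm.
#' @param bath_s_gy,bath_d_gy low-dose bath amplitude, Gy, per arm
#'   (the double plan's bath is split evenly between its two component
#'   plans).
#' @param noise_sd_gy additive Gaussian noise SD, Gy.
#' @param seed integer seed for the noise stream.
#' @return A list of class `dose_model_spec`.
#' @export
dose_model_spec <- function(prescription_dose_gy = 50, n_fractions = 5,
                            peak_s = 1.40, peak_d = 1.46,
                            sigma_s_mm = 7, sigma_d_mm = 5.5,
                            bath_s_gy = 3.5, bath_d_gy = 2.5,
                            noise_sd_gy = 0.3, seed = 1L) {
  stopifnot(prescription_dose_gy > 0, n_fractions >= 1,
            peak_s > 1, peak_d > 1, sigma_s_mm > 0, sigma_d_mm > 0,
            bath_s_gy >= 0, bath_d_gy >= 0, noise_sd_gy >= 0)
  structure(
    list(prescription_dose_gy = prescription_dose_gy,
         n_fractions = as.integer(n_fractions),
         peak_s = peak_s, peak_d = peak_d,
         sigma_s_mm = sigma_s_mm, sigma_d_mm = sigma_d_mm,
         bath_s_gy = bath_s_gy, bath_d_gy = bath_d_gy,
         noise_sd_gy = noise_sd_gy, seed = as.integer(seed)),
    class = "dose_model_spec"
  )
}

# Dose kernel around one spherical target, emulating a plan prescribed
# to the ~(1/peak) isodose surface at the PTV boundary:
#   r <= core:          PD * peak (hot core)
#   core < r <= R:      Gaussian ramp from PD*peak down to exactly PD at R
#   r > R:              Gaussian falloff exp(-(r-R)^2 / (2 sigma^2))
# Continuous at both joins; the 100% isodose sits on the PTV surface.
target_kernel <- function(X, Y, Z, center, radius, prescription, peak,
                          sigma, core_frac = 0.3) {
  r <- sqrt((X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2)
  r_core <- core_frac * radius
  sigma_in <- (radius - r_core) / sqrt(2 * log(peak))
  inner <- pmax(r - r_core, 0)
  dose_in <- prescription * peak * exp(-inner^2 / (2 * sigma_in^2))
  outer <- pmax(r - radius, 0)
  dose_out <- prescription * exp(-outer^2 / (2 * sigma^2))
  ifelse(r <= radius, dose_in, dose_out)
}

# bath apodized by normalized distance from the body surface
body_bath <- function(structures, amplitude) {
  body <- structures$body
  if (amplitude == 0) return(0)
  dims <- body$dims
  cc <- phantom_coords(body$spacing, dims)
  X <- expand_axis(cc$x, dims, 1)
  Y <- expand_axis(cc$y, dims, 2)
  Z <- expand_axis(cc$z, dims, 3)
  ext <- (dims - 1) * body$spacing
  semi <- c(0.46 * ext[1], 0.42 * ext[2], 0.48 * ext[3])
  rho2 <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2
  amplitude * pmax(1 - rho2, 0) * body$occupancy
}

#' Generate the dose of one arm for a phantom
#'
#' Arm `"S"` (single planning) returns one [plan_dose()] containing both
#' targets' kernels plus the single-plan bath. Arm `"D"` (double
#' planning) returns a list of two component `plan_dose` objects — one
#' kernel each, plus half the double-plan bath each — that the caller
#' superimposes explicitly with [sum_doses()], mirroring the clinical
#' double-planning workflow. Doses outside the body are zeroed.
#'
#' If noise pushes target coverage at the prescription dose below 95%,
#' generation is retried with an inflated peak (up to 3 times) before
#' erroring.
#'
#' @param phantom result of [generate_phantom()].
#' @param dose_spec a [dose_model_spec()].
#' @param arm `"S"` or `"D"`.
#' @return A `plan_dose` (arm S) or list of two component `plan_dose`
#'   objects (arm D).
#' @export
generate_plan_dose <- function(phantom, dose_spec, arm = c("S", "D")) {
  arm <- match.arg(arm)
  stopifnot(inherits(dose_spec, "dose_model_spec"))
  geom <- phantom$geometry
  dims <- geom$dims
  cc <- phantom_coords(geom$spacing, dims)
  X <- expand_axis(cc$x, dims, 1)
  Y <- expand_axis(cc$y, dims, 2)
  Z <- expand_axis(cc$z, dims, 3)
  pd <- dose_spec$prescription_dose_gy
  body_occ <- phantom$structures$body$occupancy

  peak <- if (arm == "S") dose_spec$peak_s else dose_spec$peak_d
  sigma <- if (arm == "S") dose_spec$sigma_s_mm else dose_spec$sigma_d_mm
  bath_amp <- if (arm == "S") dose_spec$bath_s_gy else dose_spec$bath_d_gy

  set.seed(dose_spec$seed + if (arm == "S") 101L else 202L)
  mk_grid <- function(values) {
    values[!body_occ] <- 0
    dose_grid(values, spacing = geom$spacing, origin = geom$origin,
              frame_id = geom$frame_id)
  }
  add_noise <- function(values) {
    if (dose_spec$noise_sd_gy == 0) return(values)
    pmax(values + array(stats::rnorm(length(values), 0,
                                     dose_spec$noise_sd_gy),
                        dim = dim(values)), 0)
  }
  check_coverage <- function(grid) {
    all(vapply(c("ptv1", "ptv2"), function(nm) {
      coverage(grid, phantom$structures[[nm]], pd) >= 95
    }, logical(1)))
  }

  bath <- body_bath(phantom$structures, bath_amp)
  k1 <- function(pk) target_kernel(X, Y, Z, phantom$params$ptv1$center,
                                   phantom$params$ptv1$radius_mm,
                                   pd, pk, sigma)
  k2 <- function(pk) target_kernel(X, Y, Z, phantom$params$ptv2$center,
                                   phantom$params$ptv2$radius_mm,
                                   pd, pk, sigma)
  if (arm == "S") {
    for (attempt in 0:3) {
      pk <- peak * 1.02^attempt
      values <- add_noise(k1(pk) + k2(pk) + bath)
      grid <- mk_grid(values)
      if (check_coverage(grid)) {
        return(plan_dose(grid, n_fractions = dose_spec$n_fractions,
                         prescription_dose_gy = pd, arm = "single"))
      }
    }
    stop("could not reach 95% coverage for arm S", call. = FALSE)
  }
  for (attempt in 0:3) {
    pk <- peak * 1.02^attempt
    comp1 <- mk_grid(add_noise(k1(pk) + bath / 2))
    comp2 <- mk_grid(add_noise(k2(pk) + bath / 2))
    total <- mk_grid(comp1$values + comp2$values)
    if (check_coverage(total)) {
      return(list(
        plan_dose(comp1, n_fractions = dose_spec$n_fractions,
                  prescription_dose_gy = pd, arm = "component"),
        plan_dose(comp2, n_fractions = dose_spec$n_fractions,
                  prescription_dose_gy = pd, arm = "component")
      ))
    }
  }
  stop("could not reach 95% coverage for arm D", call. = FALSE)
}

#' Generate a paired synthetic cohort
#'
#' `n` independent bilateral-lung phantoms, each with a single-plan dose
#' and the two double-plan component doses, using per-patient child
#' seeds derived deterministically from `master_seed`.
#'
#' @param n number of phantoms (default 10, the size of the clinical
#'   cohort the generator emulates).
#' @param master_seed integer master seed.
#' @param phantom_args,dose_args optional named lists overriding
#'   [phantom_spec()] / [dose_model_spec()] defaults (except seeds).
#' @return A list of length `n`; each element has `patient`, `phantom`
#'   (structures + geometry + params), `plan_s` (a [plan_dose()]) and
#'   `plan_d_components` (list of two component [plan_dose()]s).
#' @export
generate_cohort <- function(n = 10, master_seed = 20221121,
                            phantom_args = list(), dose_args = list()) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  child_seeds <- sample.int(2^31 - 2, n)
  lapply(seq_len(n), function(i) {
    generate_patient(child_seeds[i], phantom_args, dose_args,
                     patient = sprintf("P%02d", i))
  })
}

#' @noRd
generate_patient <- function(child_seed, phantom_args = list(),
                             dose_args = list(), patient = "P01") {
  pspec <- do.call(phantom_spec,
                   c(phantom_args, list(seed = child_seed)))
  dspec <- do.call(dose_model_spec,
                   c(dose_args, list(seed = child_seed)))
  phantom <- generate_phantom(pspec)
  list(
    patient = patient,
    phantom = phantom,
    plan_s = generate_plan_dose(phantom, dspec, arm = "S"),
    plan_d_components = generate_plan_dose(phantom, dspec, arm = "D")
  )
}
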