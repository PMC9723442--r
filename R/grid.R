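#' Voxel dose grids and structure masks
#'
#' A `dose_grid` is a 3D array of absorbed dose (Gy, total over all
#' fractions) sampled at voxel centers, together with its geometry: a
#' physical `origin` (mm, position of voxel \[1,1,1\]), isotropic or
#' anisotropic `spacing` (mm per voxel along x, y, z), and a `frame_id`
#' token identifying the coordinate frame. The physical position of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' Doses are held in double precision regardless of the source dtype.
#'
#' @param values numeric 3D array of voxel doses in Gy; finite, >= 0.
#' @param spacing numeric length-3, voxel spacing in mm (> 0); a scalar is
#'   recycled to all three axes.
#' @param origin numeric length-3, position of the first voxel center, mm.
#' @param frame_id character scalar naming the geometry frame. Two grids
#'   can only be combined when their frames (and geometries) agree.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0),
                      frame_id = "frame-1") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("dose values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("dose values must be >= 0 Gy", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(
    list(
      values = values,
      dims = dim(values),
      spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      frame_id = as.character(frame_id)
    ),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm [%s]\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$spacing[1], x$spacing[2], x$spacing[3], x$frame_id
  ))
  cat(sprintf("  dose range: %.3f - %.3f Gy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a grid geometry
#'
#' @param x a `dose_grid` or `roi_mask`.
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

#' Structure mask on a grid geometry
#'
#' A boolean occupancy array on the same geometry as a [dose_grid()]: a
#' voxel belongs to the structure iff its center lies inside the contour
#' solid (no partial-volume weighting).
#'
#' @param name structure label, e.g. `"ptv1"`, `"lungs"`.
#' @param occupancy logical 3D array.
#' @inheritParams dose_grid
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, occupancy, spacing, origin = c(0, 0, 0),
                     frame_id = "frame-1") {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L) {
    stop("`occupancy` must be a 3D array", call. = FALSE)
  }
  storage.mode(occupancy) <- "logical"
  if (anyNA(occupancy)) stop("occupancy must not contain NA", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(
    list(
      name = as.character(name),
      occupancy = occupancy,
      dims = dim(occupancy),
      spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      frame_id = as.character(frame_id)
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %.2f cc (%d voxels) [%s]\n",
              x$name, mask_volume_cc(x), sum(x$occupancy), x$frame_id))
  invisible(x)
}

#' Structure volume in cc
#'
#' Number of occupied voxels times the voxel volume.
#'
#' @param m an `roi_mask`.
#' @return Volume in cubic centimetres.
#' @export
mask_volume_cc <- function(m) {
  stopifnot(inherits(m, "roi_mask"))
  sum(m$occupancy) * voxel_volume_cc(m)
}

#' Check that two grid-like objects share a geometry
#'
#' Compares `frame_id`, `dims`, `spacing` and `origin`. Used as a
#' precondition by every operation that combines grids or masks; dose
#' summation in particular never resamples silently.
#'
#' @param a,b `dose_grid` or `roi_mask` objects.
#' @param tol absolute tolerance (mm) for spacing/origin comparison.
#' @return `TRUE` invisibly, or an error naming the differing field.
#' @export
assert_same_geometry <- function(a, b, tol = 1e-6) {
  if (!identical(a$frame_id, b$frame_id)) {
    stop(sprintf("geometry mismatch in frame_id: '%s' vs '%s'",
                 a$frame_id, b$frame_id), call. = FALSE)
  }
  if (!identical(as.integer(a$dims), as.integer(b$dims))) {
    stop(sprintf("geometry mismatch in dims: %s vs %s",
                 paste(a$dims, collapse = "x"),
                 paste(b$dims, collapse = "x")), call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > tol) {
    stop("geometry mismatch in spacing", call. = FALSE)
  }
  if (max(abs(a$origin - b$origin)) > tol) {
    stop("geometry mismatch in origin", call. = FALSE)
  }
  invisible(TRUE)
}

#' A treatment plan's total dose
#'
#' Bundles a total-dose grid with its fractionation and prescription so
#' downstream metrics (coverage, EQD2 correction) know the plan context.
#'
#' @param grid a [dose_grid()] of total dose over all fractions, Gy.
#' @param n_fractions number of fractions the total dose is delivered in.
#' @param prescription_dose_gy prescription dose, Gy (total).
#' @param arm one of `"single"`, `"double"`, `"component"` — whether this
#'   is a single-plan dose, a superimposed double-plan dose, or one
#'   component of a double plan.
#' @return An object of class `plan_dose`.
#' @export
plan_dose <- function(grid, n_fractions = 5, prescription_dose_gy = 50,
                      arm = c("single", "double", "component")) {
  stopifnot(inherits(grid, "dose_grid"),
            n_fractions >= 1, prescription_dose_gy > 0)
  arm <- match.arg(arm)
  structure(
    list(grid = grid, n_fractions = as.integer(n_fractions),
         prescription_dose_gy = prescription_dose_gy, arm = arm),
    class = "plan_dose"
  )
}

#' @export
print.plan_dose <- function(x, ...) {
  cat(sprintf("<plan_dose> arm=%s, %g Gy in %d fx\n",
              x$arm, x$prescription_dose_gy, x$n_fractions))
  print(x$grid)
  invisible(x)
}

#' Superimpose two plan doses
#'
#' Voxelwise sum of two component doses on an identical geometry — the
#' double-planning workflow optimizes each target in its own plan and then
#' superimposes the two dose distributions. Geometry must match exactly;
#' grids computed on different geometries must be passed through
#' [resample_like()] first, as an explicit, auditable step.
#'
#' @param a,b `plan_dose` objects on identical geometry with the same
#'   fractionation and prescription convention.
#' @return A `plan_dose` with the voxelwise sum and `arm = "double"`.
#' @export
sum_doses <- function(a, b) {
  stopifnot(inherits(a, "plan_dose"), inherits(b, "plan_dose"))
  assert_same_geometry(a$grid, b$grid)
  if (a$n_fractions != b$n_fractions) {
    stop("component plans must share n_fractions", call. = FALSE)
  }
  if (a$prescription_dose_gy != b$prescription_dose_gy) {
    stop("component plans must share the prescription convention",
         call. = FALSE)
  }
  out <- a$grid
  out$values <- a$grid$values + b$grid$values
  plan_dose(out, n_fractions = a$n_fractions,
            prescription_dose_gy = a$prescription_dose_gy, arm = "double")
}

#' Resample a dose grid onto another geometry
#'
#' Trilinear interpolation of `src` at the voxel centers of
#' `target_geometry`. Points outside the source extent get 0 Gy. The
#' output adopts the target's frame. This is the explicit resampling step
#' required before [sum_doses()] when component plans were computed on
#' different grids.
#'
#' @param src `dose_grid` to resample.
#' @param target_geometry `dose_grid` (its values are ignored) supplying
#'   the output geometry.
#' @return A `dose_grid` on the target geometry.
#' @export
resample_like <- function(src, target_geometry) {
  stopifnot(inherits(src, "dose_grid"),
            inherits(target_geometry, "dose_grid"))
  if (any(src$spacing <= 0) || any(target_geometry$spacing <= 0)) {
    stop("degenerate spacing", call. = FALSE)
  }
  tg <- target_geometry
  # fractional source indices (0-based) of each target voxel center
  fidx <- lapply(1:3, function(ax) {
    x <- tg$origin[ax] + (seq_len(tg$dims[ax]) - 1) * tg$spacing[ax]
    (x - src$origin[ax]) / src$spacing[ax]
  })
  nx <- src$dims[1]; ny <- src$dims[2]; nz <- src$dims[3]
  out <- array(0, dim = tg$dims)

  fx <- fidx[[1]]; fy <- fidx[[2]]; fz <- fidx[[3]]
  FX <- array(rep(fx, times = tg$dims[2] * tg$dims[3]), dim = tg$dims)
  FY <- array(rep(rep(fy, each = tg$dims[1]), times = tg$dims[3]),
              dim = tg$dims)
  FZ <- array(rep(fz, each = tg$dims[1] * tg$dims[2]), dim = tg$dims)

  inside <- FX >= 0 & FX <= nx - 1 & FY >= 0 & FY <= ny - 1 &
    FZ >= 0 & FZ <= nz - 1
  if (any(inside)) {
    px <- FX[inside]; py <- FY[inside]; pz <- FZ[inside]
    i0 <- pmin(floor(px), nx - 2L); i0[nx == 1L] <- 0
    j0 <- pmin(floor(py), ny - 2L); j0[ny == 1L] <- 0
    k0 <- pmin(floor(pz), nz - 2L); k0[nz == 1L] <- 0
    # single-slab axes: clamp and use zero weight on the upper corner
    i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
    wx <- px - i0; wy <- py - j0; wz <- pz - k0
    i1 <- pmin(i0 + 1, nx - 1L); j1 <- pmin(j0 + 1, ny - 1L)
    k1 <- pmin(k0 + 1, nz - 1L)
    v <- src$values
    idx <- function(i, j, k) 1 + i + nx * (j + ny * k)
    val <-
      v[idx(i0, j0, k0)] * (1 - wx) * (1 - wy) * (1 - wz) +
      v[idx(i1, j0, k0)] * wx * (1 - wy) * (1 - wz) +
      v[idx(i0, j1, k0)] * (1 - wx) * wy * (1 - wz) +
      v[idx(i0, j0, k1)] * (1 - wx) * (1 - wy) * wz +
      v[idx(i1, j1, k0)] * wx * wy * (1 - wz) +
      v[idx(i1, j0, k1)] * wx * (1 - wy) * wz +
      v[idx(i0, j1, k1)] * (1 - wx) * wy * wz +
      v[idx(i1, j1, k1)] * wx * wy * wz
    out[inside] <- val
  }
  dose_grid(out, spacing = tg$spacing, origin = tg$origin,
            frame_id = tg$frame_id)
}

#' Union of two structure masks
#'
#' Voxelwise logical OR on a shared geometry; used to build the combined
#' target (PTV1 u PTV2 = PTV12) and the combined trachea+bronchus
#' structure.
#'
#' @param a,b `roi_mask` objects on the same geometry.
#' @param name label for the union (default `"a+b"` style).
#' @return An `roi_mask`.
#' @export
union_masks <- function(a, b, name = paste0(a$name, "+", b$name)) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  assert_same_geometry(a, b)
  roi_mask(name, a$occupancy | b$occupancy, spacing = a$spacing,
           origin = a$origin, frame_id = a$frame_id)
}

#' Set difference of two masks
#'
#' Voxels in `a` but not in `b` (e.g. lungs minus PTV).
#'
#' @inheritParams union_masks
#' @return An `roi_mask`.
#' @export
difference_masks <- function(a, b, name = paste0(a$name, "-", b$name)) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  assert_same_geometry(a, b)
  roi_mask(name, a$occupancy & !b$occupancy, spacing = a$spacing,
           origin = a$origin, frame_id = a$frame_id)
}

#' A named set of structure masks on one geometry
#'
#' Canonical names used by the pipeline: `ptv1`, `ptv2`, `ptv12`,
#' `lungs`, `heart`, `cord`, `trachea`, `bronchus`, `trachea_bronchus`,
#' `esophagus`, `body`. Derived unions (`ptv12`, `trachea_bronchus`) are
#' filled in automatically when absent. Every mask must share the
#' geometry of (and be contained in) `body`.
#'
#' @param masks named list of [roi_mask()] objects including `body`.
#' @return An object of class `structure_set` (a named list of masks).
#' @export
structure_set <- function(masks) {
  stopifnot(is.list(masks), !is.null(names(masks)), "body" %in% names(masks))
  body <- masks$body
  for (m in masks) {
    stopifnot(inherits(m, "roi_mask"))
    assert_same_geometry(m, body)
  }
  if (!is.null(masks$ptv1) && !is.null(masks$ptv2) && is.null(masks$ptv12)) {
    masks$ptv12 <- union_masks(masks$ptv1, masks$ptv2, name = "ptv12")
  }
  if (!is.null(masks$trachea) && !is.null(masks$bronchus) &&
      is.null(masks$trachea_bronchus)) {
    masks$trachea_bronchus <-
      union_masks(masks$trachea, masks$bronchus, name = "trachea_bronchus")
  }
  for (nm in setdiff(names(masks), "body")) {
    if (any(masks[[nm]]$occupancy & !body$occupancy)) {
      stop(sprintf("structure '%s' is not contained in body", nm),
           call. = FALSE)
    }
  }
  structure(masks, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %8.2f cc\n", nm, mask_volume_cc(x[[nm]])))
  }
  invisible(x)
}

#' Structure volumes as a tibble
#'
#' @param x a `structure_set`.
#' @param ... unused.
#' @return A tibble with columns `structure`, `volume_cc`, `n_voxels`.
#' @exportS3Method generics::tidy
tidy.structure_set <- function(x, ...) {
  tibble::tibble(
    structure = names(x),
    volume_cc = vapply(x, mask_volume_cc, numeric(1)),
    n_voxels = vapply(x, function(m) sum(m$occupancy), numeric(1))
  )
}
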