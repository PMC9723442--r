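#' Doses of the voxels inside a structure
#' @noRd
structure_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "roi_mask"))
  assert_same_geometry(dose, mask)
  dose$values[mask$occupancy]
}

#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH: for each bin edge `d` (Gy,
#' ascending from 0), the absolute volume (cc) of the structure receiving
#' at least `d` ("receiving x Gy" is the closed comparison `dose >= x`
#' throughout the package). The first entry equals the structure volume;
#' the curve is non-increasing.
#'
#' @param dose a [dose_grid()] of total dose, Gy.
#' @param mask an [roi_mask()] on the same geometry; must be non-empty.
#' @param bin_width histogram bin width in Gy (default 0.01).
#' @return An object of class `cumulative_dvh` with fields `structure`,
#'   `bin_edges` (Gy), `volume_at_or_above` (cc), `total_volume_cc`,
#'   `bin_width`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  d <- structure_doses(dose, mask)
  if (length(d) == 0) {
    stop(sprintf("structure '%s' has an empty mask", mask$name),
         call. = FALSE)
  }
  vvox <- voxel_volume_cc(mask)
  n_bins <- floor(max(d) / bin_width) + 1L
  edges <- (seq_len(n_bins + 1L) - 1L) * bin_width
  # volume receiving >= edge: count voxels with dose >= edge
  counts <- length(d) - findInterval(edges - 1e-12, sort(d))
  structure(
    list(
      structure = mask$name,
      bin_edges = edges,
      volume_at_or_above = counts * vvox,
      total_volume_cc = length(d) * vvox,
      bin_width = bin_width
    ),
    class = "cumulative_dvh"
  )
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("<cumulative_dvh> '%s': %.2f cc, %d edges @ %g Gy\n",
              x$structure, x$total_volume_cc,
              length(x$bin_edges), x$bin_width))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cumulative_dvh <- function(x, ...) {
  tibble::tibble(
    structure = x$structure,
    dose_gy = x$bin_edges,
    volume_cc = x$volume_at_or_above,
    volume_pct = 100 * x$volume_at_or_above / x$total_volume_cc
  )
}

#' Plot a cumulative DVH
#'
#' @param object a `cumulative_dvh` or a list of them.
#' @param relative plot percent volume (default) or absolute cc.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cumulative_dvh <- function(object, relative = TRUE, ...) {
  df <- tidy(object)
  y <- if (relative) "volume_pct" else "volume_cc"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data[[y]])) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (Gy)",
                  y = if (relative) "Volume (%)" else "Volume (cc)",
                  title = object$structure) +
    ggplot2::theme_minimal()
}

#' Differential DVH from a cumulative DVH
#'
#' Fractional volume per bin (sums to 1) with bin-center doses; the form
#' consumed by the gEUD power mean.
#' @param dvh a `cumulative_dvh`.
#' @return A tibble with `dose_gy` (bin centers) and `frac_volume`.
#' @export
differential_dvh <- function(dvh) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  v <- dvh$volume_at_or_above
  dv <- v[-length(v)] - v[-1]
  centers <- dvh$bin_edges[-length(dvh$bin_edges)] + dvh$bin_width / 2
  tibble::tibble(dose_gy = centers, frac_volume = dv / dvh$total_volume_cc)
}

# ---- voxel-exact metric queries -------------------------------------------

#' Minimum dose to the hottest `vol_cc` of a structure
#'
#' Sorts the structure's voxel doses descending, accumulates volume in
#' voxel steps, and linearly interpolates between voxel boundaries, so
#' the result is voxel-exact at integer multiples of the voxel volume.
#' Queries below one voxel volume return the hottest voxel's dose.
#'
#' @param doses numeric vector of structure voxel doses, Gy.
#' @param vol_cc query volume, cc; must be positive and at most the
#'   structure volume.
#' @param vvox voxel volume, cc.
#' @return Dose in Gy.
#' @noRd
d_at_cc_from_doses <- function(doses, vol_cc, vvox) {
  total <- length(doses) * vvox
  if (vol_cc <= 0) stop("volume query must be positive", call. = FALSE)
  if (vol_cc > total + 1e-9) {
    stop(sprintf("volume query %.3f cc exceeds structure volume %.3f cc",
                 vol_cc, total), call. = FALSE)
  }
  s <- sort(doses, decreasing = TRUE, method = "radix")
  cum <- seq_along(s) * vvox
  if (vol_cc <= cum[1]) return(s[1])
  approx(cum, s, xout = min(vol_cc, total), rule = 2, ties = "ordered")$y
}

#' DVH-derived metrics for one structure
#'
#' Computes the dose-volume metric families used in SBRT plan review
#' directly from voxel values (never from histogram bins): extrema and
#' mean (`d_max`, `d_mean`, `d_min` are true voxel statistics, not
#' percentile surrogates), `Vx` in percent and cc (volume receiving at
#' least x Gy, closed comparison), `V<x` in cc (volume receiving strictly
#' less than x Gy, so `Vx cc + V<x cc` equals the structure volume
#' exactly), `Dx cc` (minimum dose to the hottest x cc), `Dx %`
#' (minimum dose to the hottest x percent), and coverage at a
#' prescription dose.
#'
#' @inheritParams cumulative_dvh
#' @param v_pct_at,v_cc_at,v_below_cc_at numeric vectors of dose levels
#'   (Gy) for the Vx(%), Vx(cc) and V<x(cc) families.
#' @param d_at_cc numeric vector of volumes (cc) for the Dx cc family.
#' @param d_at_pct numeric vector of volume percentages for Dx %.
#' @param prescription_dose if non-NULL, adds `coverage_pct` at this dose.
#' @return A tibble with one row per metric: `metric`, `value`, `units`.
#' @export
dvh_metrics <- function(dose, mask,
                        v_pct_at = numeric(), v_cc_at = numeric(),
                        v_below_cc_at = numeric(),
                        d_at_cc = numeric(), d_at_pct = numeric(),
                        prescription_dose = NULL) {
  d <- structure_doses(dose, mask)
  if (length(d) == 0) {
    stop(sprintf("structure '%s' has an empty mask", mask$name),
         call. = FALSE)
  }
  if (any(c(v_pct_at, v_cc_at, v_below_cc_at, d_at_cc, d_at_pct) < 0)) {
    stop("negative metric query", call. = FALSE)
  }
  vvox <- voxel_volume_cc(mask)
  total <- length(d) * vvox
  rows <- list(
    tibble::tibble(metric = c("d_max", "d_mean", "d_min"),
                   value = c(max(d), mean(d), min(d)), units = "Gy")
  )
  add <- function(metric, value, units) {
    rows[[length(rows) + 1]] <<-
      tibble::tibble(metric = metric, value = value, units = units)
  }
  for (x in v_pct_at) {
    add(sprintf("v_%ggy_pct", x), 100 * sum(d >= x) / length(d), "%")
  }
  for (x in v_cc_at) add(sprintf("v_%ggy_cc", x), sum(d >= x) * vvox, "cc")
  for (x in v_below_cc_at) {
    add(sprintf("v_below_%ggy_cc", x), sum(d < x) * vvox, "cc")
  }
  for (q in d_at_cc) {
    add(sprintf("d_%gcc", q), d_at_cc_from_doses(d, q, vvox), "Gy")
  }
  for (q in d_at_pct) {
    add(sprintf("d_%gpct", q),
        d_at_cc_from_doses(d, q / 100 * total, vvox), "Gy")
  }
  if (!is.null(prescription_dose)) {
    add("coverage_pct", 100 * sum(d >= prescription_dose) / length(d), "%")
  }
  out <- dplyr::bind_rows(rows)
  out$structure <- mask$name
  dplyr::relocate(out, "structure")
}

#' Target coverage at the prescription dose
#'
#' Percentage of the target volume receiving at least the prescription
#' dose (the volume inside the prescribed isodose line relative to the
#' total target volume). A voxel exactly at the prescription dose counts
#' as covered.
#'
#' @param dose a [dose_grid()].
#' @param target an [roi_mask()]; must be non-empty.
#' @param prescription_dose Gy, > 0.
#' @return Coverage in percent.
#' @export
coverage <- function(dose, target, prescription_dose) {
  stopifnot(prescription_dose > 0)
  d <- structure_doses(dose, target)
  if (length(d) == 0) {
    stop(sprintf("target '%s' has an empty mask", target$name),
         call. = FALSE)
  }
  100 * sum(d >= prescription_dose) / length(d)
}

# ---- DVH CSV round-trip ----------------------------------------------------

#' Write a cumulative DVH to CSV
#'
#' Two-section plain-text format: a metadata header row
#' (`structure,total_volume_cc,bin_width_gy`) followed by the curve as
#' `dose_gy,volume_cc` rows. Round-trips through [read_dvh_csv()].
#'
#' @param dvh a `cumulative_dvh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("structure,total_volume_cc,bin_width_gy", con)
  writeLines(sprintf("%s,%.17g,%.17g", dvh$structure,
                     dvh$total_volume_cc, dvh$bin_width), con)
  writeLines("dose_gy,volume_cc", con)
  writeLines(sprintf("%.17g,%.17g", dvh$bin_edges,
                     dvh$volume_at_or_above), con)
  invisible(path)
}

#' Read a cumulative DVH from CSV
#'
#' @param path a file written by [write_dvh_csv()].
#' @return A `cumulative_dvh`.
#' @export
read_dvh_csv <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  curve <- readr::read_csv(I(lines[-(1:2)]), show_col_types = FALSE)
  structure(
    list(
      structure = meta[1],
      bin_edges = curve$dose_gy,
      volume_at_or_above = curve$volume_cc,
      total_volume_cc = as.numeric(meta[2]),
      bin_width = as.numeric(meta[3])
    ),
    class = "cumulative_dvh"
  )
}
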