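#' Write a dose grid in the native raw + JSON-sidecar format
#'
#' `path.raw` holds the voxel values as little-endian float64 in column-
#' major (x-fastest) order; `path.json` holds geometry and units. Masks
#' use the same sidecar with a uint8 payload via [write_roi_mask()].
#'
#' @param grid a [dose_grid()].
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.vector(grid$values), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(kind = "dose_grid", units = "Gy", dtype = "float64",
         dims = grid$dims, spacing_mm = grid$spacing,
         origin_mm = grid$origin, frame_id = grid$frame_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a native-format dose grid
#'
#' @param path base path used with [write_dose_grid()].
#' @return A [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "dose_grid")) {
    stop("sidecar does not describe a dose_grid", call. = FALSE)
  }
  if (!identical(meta$units, "Gy")) {
    stop(sprintf("unsupported dose units '%s' (expected Gy)", meta$units),
         call. = FALSE)
  }
  n <- prod(meta$dims)
  con <- file(paste0(path, ".raw"), "rb")
  vals <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  close(con)
  dose_grid(array(vals, dim = meta$dims), spacing = meta$spacing_mm,
            origin = meta$origin_mm, frame_id = meta$frame_id)
}

#' Write a structure mask in the native format
#'
#' @param mask an [roi_mask()].
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.integer(mask$occupancy), con, size = 1)
  close(con)
  jsonlite::write_json(
    list(kind = "roi_mask", name = mask$name, dtype = "uint8",
         dims = mask$dims, spacing_mm = mask$spacing,
         origin_mm = mask$origin, frame_id = mask$frame_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a native-format structure mask
#'
#' @param path base path used with [write_roi_mask()].
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "roi_mask")) {
    stop("sidecar does not describe a roi_mask", call. = FALSE)
  }
  n <- prod(meta$dims)
  con <- file(paste0(path, ".raw"), "rb")
  vals <- readBin(con, what = "integer", n = n, size = 1, signed = FALSE)
  close(con)
  roi_mask(meta$name, array(vals != 0, dim = meta$dims),
           spacing = meta$spacing_mm, origin = meta$origin_mm,
           frame_id = meta$frame_id)
}
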