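# small in-code fixtures shared across tests

# grid with given values (3D array or vector + dims)
mk_grid <- function(values, dims = NULL, spacing = 1, origin = c(0, 0, 0),
                    frame_id = "t") {
  if (!is.array(values)) values <- array(values, dim = dims)
  dose_grid(values, spacing = spacing, origin = origin, frame_id = frame_id)
}

# mask covering all voxels of a grid
mk_full_mask <- function(grid, name = "roi") {
  roi_mask(name, array(TRUE, dim = grid$dims), spacing = grid$spacing,
           origin = grid$origin, frame_id = grid$frame_id)
}

mk_mask <- function(occ, dims = NULL, spacing = 1, origin = c(0, 0, 0),
                    name = "roi", frame_id = "t") {
  if (!is.array(occ)) occ <- array(occ, dim = dims)
  roi_mask(name, occ, spacing = spacing, origin = origin,
           frame_id = frame_id)
}

# random dose field grid + full mask, for oracle tests
mk_random_field <- function(n = 12, seed = 1, max_dose = 60, spacing = 2) {
  set.seed(seed)
  g <- mk_grid(stats::runif(n^3, 0, max_dose), dims = rep(n, 3),
               spacing = spacing)
  list(grid = g, mask = mk_full_mask(g))
}

# digitized sphere mask centered in a cube grid
mk_sphere_mask <- function(radius_mm, spacing = 1, pad = 3) {
  n <- ceiling(2 * (radius_mm + pad) / spacing)
  half <- (n - 1) * spacing / 2
  x <- seq(0, (n - 1) * spacing, by = spacing) - half
  X <- array(rep(x, times = n * n), dim = rep(n, 3))
  Y <- array(rep(rep(x, each = n), times = n), dim = rep(n, 3))
  Z <- array(rep(x, each = n * n), dim = rep(n, 3))
  mk_mask(X^2 + Y^2 + Z^2 <= radius_mm^2, spacing = spacing,
          origin = rep(-half, 3))
}

# tiny fast phantom/dose settings for pipeline tests
small_phantom_args <- function() list(dims = c(60, 48, 52), spacing_mm = 4)
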