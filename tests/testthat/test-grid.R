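test_that("sum_doses adds voxelwise and respects the additive identity", {
  g <- mk_grid(c(1.0, 2.5, 0.5, 3.0, 4.0, 1.5, 2.0, 0.1), dims = c(2, 2, 2))
  zero <- mk_grid(rep(0, 8), dims = c(2, 2, 2))
  p <- plan_dose(g); pz <- plan_dose(zero)

  expect_equal(sum_doses(p, pz)$grid$values, g$values)
  h <- mk_grid(c(3.0, 4.0, 1, 1, 1, 1, 1, 1), dims = c(2, 2, 2))
  s <- sum_doses(p, plan_dose(h))
  expect_equal(s$grid$values[1:2], c(4.0, 6.5))
  expect_identical(s$arm, "double")

  # commutative and associative with a fixed voxel order
  q <- plan_dose(h)
  expect_identical(sum_doses(p, q)$grid$values, sum_doses(q, p)$grid$values)
  r <- plan_dose(mk_grid(runif(8), dims = c(2, 2, 2)))
  expect_equal(sum_doses(sum_doses(p, q), r)$grid$values,
               sum_doses(p, sum_doses(q, r))$grid$values)
})

test_that("sum_doses refuses mismatched geometry, naming the field", {
  a <- plan_dose(mk_grid(rep(1, 8), dims = c(2, 2, 2)))
  b <- plan_dose(mk_grid(rep(1, 8), dims = c(2, 2, 2),
                         origin = c(0.75, 0, 0)))
  expect_error(sum_doses(a, b), "origin")
  c2 <- plan_dose(mk_grid(rep(1, 12), dims = c(2, 2, 3)))
  expect_error(sum_doses(a, c2), "dims")
  d <- plan_dose(mk_grid(rep(1, 8), dims = c(2, 2, 2), frame_id = "other"))
  expect_error(sum_doses(a, d), "frame_id")
})

test_that("resample_like is the identity on identical geometry", {
  f <- mk_random_field(n = 8, seed = 3)
  out <- resample_like(f$grid, f$grid)
  expect_equal(out$values, f$grid$values, tolerance = 1e-12)
})

test_that("resample_like preserves constants and exactly reproduces affine fields", {
  const <- mk_grid(rep(7.5, 10^3), dims = rep(10, 3), spacing = 2)
  # target strictly interior to the source extent
  tgt <- mk_grid(array(0, dim = rep(6, 3)), spacing = 1.5,
                 origin = c(2, 2, 2), frame_id = "t2")
  out <- resample_like(const, tgt)
  expect_equal(out$values, array(7.5, dim = rep(6, 3)), tolerance = 1e-12)

  # linear ramp d(x,y,z) = 1 + 0.5x + 0.25y + 0.125z onto half spacing:
  # trilinear interpolation is exact on affine fields
  n <- 10
  co <- axis_vals <- seq(0, (n - 1) * 2, by = 2)
  X <- array(rep(co, times = n * n), dim = rep(n, 3))
  Y <- array(rep(rep(co, each = n), times = n), dim = rep(n, 3))
  Z <- array(rep(co, each = n * n), dim = rep(n, 3))
  ramp <- mk_grid(1 + 0.5 * X + 0.25 * Y + 0.125 * Z, spacing = 2)
  tgt2 <- mk_grid(array(0, dim = rep(12, 3)), spacing = 1,
                  origin = c(1, 1, 1), frame_id = "t3")
  out2 <- resample_like(ramp, tgt2)
  cx <- 1 + (0:11); direct <- array(0, dim = rep(12, 3))
  for (k in 1:12) for (j in 1:12) {
    direct[, j, k] <- 1 + 0.5 * cx + 0.25 * cx[j] + 0.125 * cx[k]
  }
  expect_equal(out2$values, direct, tolerance = 1e-10)

  # points outside the source extent are zero-filled
  far <- mk_grid(array(0, dim = rep(4, 3)), spacing = 1,
                 origin = c(100, 100, 100), frame_id = "t4")
  expect_true(all(resample_like(ramp, far)$values == 0))
})

test_that("mask volumes: unit conversion, sphere digitization, union algebra", {
  g <- mk_grid(rep(0, 1000), dims = c(10, 10, 10), spacing = 1)
  m <- mk_full_mask(g)
  expect_equal(mask_volume_cc(m), 1.0)  # 1000 voxels at 1 mm^3

  empty <- mk_mask(rep(FALSE, 1000), dims = c(10, 10, 10))
  expect_equal(mask_volume_cc(empty), 0)

  sph <- mk_sphere_mask(12, spacing = 1)
  expect_equal(mask_volume_cc(sph), 4 / 3 * pi * 1.2^3,
               tolerance = 0.02)

  # union: idempotent, monotone, additive on disjoint masks
  occ1 <- array(FALSE, dim = c(10, 10, 10)); occ1[1:5, , 1] <- TRUE
  occ2 <- array(FALSE, dim = c(10, 10, 10)); occ2[6:10, , 2] <- TRUE
  a <- mk_mask(occ1); b <- mk_mask(occ2)
  expect_equal(mask_volume_cc(union_masks(a, b)),
               mask_volume_cc(a) + mask_volume_cc(b))
  expect_identical(union_masks(a, a)$occupancy, a$occupancy)
  expect_equal(mask_volume_cc(union_masks(a, empty)), mask_volume_cc(a))
})

test_that("structure_set derives unions and enforces containment in body", {
  dims <- c(8, 8, 8)
  body <- mk_mask(array(TRUE, dims), name = "body")
  o1 <- array(FALSE, dims); o1[1:2, 1:2, 1:2] <- TRUE
  o2 <- array(FALSE, dims); o2[6:7, 6:7, 6:7] <- TRUE
  ss <- structure_set(list(body = body, ptv1 = mk_mask(o1, name = "ptv1"),
                           ptv2 = mk_mask(o2, name = "ptv2")))
  expect_identical(ss$ptv12$occupancy, o1 | o2)

  small_body <- mk_mask(array(c(rep(FALSE, 256), rep(TRUE, 256)), dims),
                        name = "body")
  expect_error(
    structure_set(list(body = small_body, ptv1 = mk_mask(o1, name = "ptv1"))),
    "not contained in body")
})

test_that("native grid and mask formats round-trip", {
  f <- mk_random_field(n = 6, seed = 9)
  base <- file.path(withr::local_tempdir(), "g")
  write_dose_grid(f$grid, base)
  back <- read_dose_grid(base)
  expect_equal(back$values, f$grid$values)
  expect_equal(back$spacing, f$grid$spacing)
  expect_identical(back$frame_id, f$grid$frame_id)

  m <- mk_sphere_mask(4, spacing = 1)
  basem <- file.path(withr::local_tempdir(), "m")
  write_roi_mask(m, basem)
  backm <- read_roi_mask(basem)
  expect_identical(backm$occupancy, m$occupancy)
  expect_identical(backm$name, m$name)
})
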