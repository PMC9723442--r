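test_that("cumulative DVH of uniform and two-level dose fields is a step function", {
  # uniform 10 Gy over 100 cc (100 voxels at 1 cc)
  g <- mk_grid(rep(10, 100), dims = c(10, 10, 1), spacing = 10)
  dvh <- cumulative_dvh(g, mk_full_mask(g), bin_width = 0.5)
  expect_equal(dvh$total_volume_cc, 100)
  expect_true(all(dvh$volume_at_or_above[dvh$bin_edges <= 10] == 100))
  expect_true(all(dvh$volume_at_or_above[dvh$bin_edges > 10] == 0))
  expect_equal(dvh$volume_at_or_above[1], dvh$total_volume_cc)

  # half at 4 Gy, half at 8 Gy
  g2 <- mk_grid(rep(c(4, 8), each = 50), dims = c(10, 10, 1), spacing = 10)
  dvh2 <- cumulative_dvh(g2, mk_full_mask(g2), bin_width = 0.5)
  td <- tidy(dvh2)
  expect_equal(td$volume_pct[td$dose_gy == 4], 100)
  expect_equal(td$volume_pct[td$dose_gy == 4.5], 50)
  expect_equal(td$volume_pct[td$dose_gy == 8], 50)
  expect_true(all(td$volume_pct[td$dose_gy > 8] == 0))
  expect_true(all(diff(dvh2$volume_at_or_above) <= 0))
})

test_that("empty masks are rejected with the structure named", {
  g <- mk_grid(rep(1, 8), dims = c(2, 2, 2))
  empty <- mk_mask(rep(FALSE, 8), dims = c(2, 2, 2), name = "cord")
  expect_error(cumulative_dvh(g, empty), "cord")
  expect_error(dvh_metrics(g, empty), "cord")
  expect_error(coverage(g, empty, 50), "cord")
})

test_that("two-voxel worked example: Dcc, Vcc and the closed/open split", {
  # 2 cc structure, voxels of 10 and 20 Gy (1 cc each)
  g <- mk_grid(c(10, 20), dims = c(2, 1, 1), spacing = 10)
  m <- mk_full_mask(g)
  met <- dvh_metrics(g, m, v_cc_at = 15, v_below_cc_at = 15, d_at_cc = 1.0)
  val <- function(nm) met$value[met$metric == nm]
  expect_equal(val("d_1cc"), 20)
  expect_equal(val("v_15gy_cc"), 1)
  expect_equal(val("v_below_15gy_cc"), 1)

  # uniform field: extrema collapse, V at the level is 100%
  gu <- mk_grid(rep(50, 27), dims = c(3, 3, 3))
  mu <- mk_full_mask(gu)
  metu <- dvh_metrics(gu, mu, v_pct_at = 50)
  expect_equal(metu$value[metu$metric %in% c("d_max", "d_mean", "d_min")],
               rep(50, 3))
  expect_equal(metu$value[metu$metric == "v_50gy_pct"], 100)

  expect_error(dvh_metrics(g, m, d_at_cc = 5), "exceeds")
  expect_error(dvh_metrics(g, m, v_pct_at = -1), "negative")
})

test_that("every DVH metric matches brute-force voxel counting on random fields", {
  for (seed in 1:3) {
    f <- mk_random_field(n = 14, seed = seed, max_dose = 70, spacing = 2.5)
    d <- as.vector(f$grid$values)
    vvox <- voxel_volume_cc(f$grid)
    total <- length(d) * vvox
    qd <- c(0.5, 5, 20, 35, 50, 65)
    met <- dvh_metrics(f$grid, f$mask, v_pct_at = qd, v_cc_at = qd,
                       v_below_cc_at = qd,
                       d_at_cc = c(1, 2, 5) * vvox * 7,
                       prescription_dose = 50)
    val <- function(nm) met$value[met$metric == nm]
    expect_equal(val("d_max"), max(d))
    expect_equal(val("d_mean"), mean(d))
    expect_equal(val("d_min"), min(d))
    for (x in qd) {
      expect_equal(val(sprintf("v_%ggy_pct", x)),
                   100 * sum(d >= x) / length(d))
      expect_equal(val(sprintf("v_%ggy_cc", x)), sum(d >= x) * vvox)
      expect_equal(val(sprintf("v_below_%ggy_cc", x)), sum(d < x) * vvox)
      # complementarity is exact
      expect_equal(val(sprintf("v_%ggy_cc", x)) +
                     val(sprintf("v_below_%ggy_cc", x)), total)
    }
    # d_at_cc at integer voxel multiples equals the k-th hottest voxel
    s <- sort(d, decreasing = TRUE)
    for (k in c(7, 14, 35)) {
      expect_equal(val(sprintf("d_%gcc", k * vvox)), s[k])
    }
    expect_equal(val("coverage_pct"), 100 * sum(d >= 50) / length(d))

    # the binned cumulative curve agrees with counting at every edge
    dvh <- cumulative_dvh(f$grid, f$mask, bin_width = 0.1)
    counts <- vapply(dvh$bin_edges, function(e) sum(d >= e), numeric(1))
    expect_equal(dvh$volume_at_or_above, counts * vvox)
  }
})

test_that("d_at_cc is non-increasing in volume; v_cc non-increasing in dose", {
  f <- mk_random_field(n = 10, seed = 7)
  d <- as.vector(f$grid$values)
  vvox <- voxel_volume_cc(f$grid)
  vols <- seq(vvox, length(d) * vvox, length.out = 25)
  dcc <- vapply(vols, function(v) {
    met <- dvh_metrics(f$grid, f$mask, d_at_cc = v)
    met$value[grepl("^d_.*cc$", met$metric)]
  }, numeric(1))
  expect_true(all(diff(dcc) <= 1e-9))
  doses <- seq(0, 60, by = 5)
  vcc <- vapply(doses, function(x) sum(d >= x) * vvox, numeric(1))
  expect_true(all(diff(vcc) <= 0))
})

test_that("coverage uses the closed comparison at the prescription dose", {
  g <- mk_grid(rep(50, 20), dims = c(20, 1, 1))
  m <- mk_full_mask(g)
  expect_equal(coverage(g, m, 50), 100)

  vals <- rep(50, 20); vals[1] <- 49.99
  g2 <- mk_grid(vals, dims = c(20, 1, 1))
  expect_equal(coverage(g2, m, 50), 95)

  vals3 <- c(rep(50 - 1e-9, 10), rep(55, 10))
  g3 <- mk_grid(vals3, dims = c(20, 1, 1))
  expect_equal(coverage(g3, m, 50), 50)
})

test_that("DVH CSV round-trips exactly", {
  f <- mk_random_field(n = 8, seed = 4)
  dvh <- cumulative_dvh(f$grid, f$mask, bin_width = 0.25)
  path <- file.path(withr::local_tempdir(), "dvh.csv")
  write_dvh_csv(dvh, path)
  back <- read_dvh_csv(path)
  expect_equal(back$bin_edges, dvh$bin_edges)
  expect_equal(back$volume_at_or_above, dvh$volume_at_or_above)
  expect_equal(back$total_volume_cc, dvh$total_volume_cc)
  expect_identical(back$structure, dvh$structure)
  # downstream consumers run from the file alone
  eud_file <- geud(back, structure = "lungs")
  eud_mem <- geud(dvh, structure = "lungs")
  expect_equal(eud_file$eud_gy, eud_mem$eud_gy)
})
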