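test_that("paired t statistic matches the closed form and the reference implementation", {
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(round(res$t, 4), 3.4641)
  expect_equal(res$df, 2)
  expect_equal(round(res$p_value, 4), 0.0742)

  # independent oracle: stats::t.test on random paired samples
  for (seed in 1:5) {
    set.seed(seed)
    s <- rnorm(10, 10, 2); d <- s - rnorm(10, 0.5, 1)
    ours <- paired_t_test(s, d)
    ref <- t.test(s, d, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("paired t: antisymmetry, shift/scale invariance, degenerate flagging", {
  set.seed(3)
  s <- rnorm(8, 50, 5); d <- rnorm(8, 48, 5)
  a <- paired_t_test(s, d); b <- paired_t_test(d, s)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  shifted <- paired_t_test(s + 100, d + 100)
  expect_equal(a$t, shifted$t, tolerance = 1e-9)
  scaled <- paired_t_test(s * 3, d * 3)
  expect_equal(a$t, scaled$t, tolerance = 1e-9)

  z <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_false(z$defined)
  expect_true(is.na(z$t) && is.na(z$p_value))
})

toy_cohort <- function() {
  tibble::tibble(
    patient = rep(c("P01", "P02"), each = 4),
    arm = rep(c("S", "S", "D", "D"), 2),
    structure = rep(c("lungs", "heart"), 4),
    metric = "d_mean",
    value = c(6.0, 3.0, 5.0, 2.5,   8.0, 4.0, 7.0, 3.1)
  )
}

test_that("cohort report reproduces hand arithmetic on a toy cohort", {
  rep_ <- cohort_report(toy_cohort())
  td <- tidy(rep_)
  lung <- td[td$structure == "lungs", ]
  expect_equal(lung$mean_s, 7.0)           # (6 + 8) / 2
  expect_equal(lung$sd_s, sd(c(6, 8)))
  expect_equal(lung$mean_d, 6.0)
  expect_equal(lung$pct_reduction, 100 * (7 - 6) / 7)
  heart <- td[td$structure == "heart", ]
  expect_equal(heart$mean_s, 3.5)
  expect_equal(heart$mean_d, 2.8)
  g <- glance(rep_)
  expect_equal(g$n_metrics, 2)
  expect_equal(g$n_patients, 2)
})

test_that("identical arms yield zero reductions and no significance flags", {
  tc <- toy_cohort()
  tc$value[tc$arm == "D"] <- tc$value[tc$arm == "S"]
  rep_ <- cohort_report(tc)
  td <- tidy(rep_)
  expect_true(all(td$pct_reduction == 0))
  expect_true(all(is.na(td$p_value)))  # degenerate zero-variance rule
  expect_true(all(!td$significant))
})

test_that("arm mismatch errors list the missing patients", {
  tc <- toy_cohort()
  expect_error(cohort_report(tc[tc$patient != "P02" | tc$arm != "D", ]),
               "P02")
})

test_that("cohort report CSV round-trips", {
  rep_ <- cohort_report(toy_cohort())
  dir <- withr::local_tempdir()
  paths <- write_cohort_report(rep_, dir, seed = 99)
  back <- read_cohort_report(paths["csv"])
  expect_equal(as.data.frame(back), as.data.frame(tidy(rep_)))
})

test_that("constraint audit: boundary semantics and pass margins", {
  dims <- c(6, 6, 6)
  body <- mk_mask(array(TRUE, dims), name = "body")
  all_occ <- array(TRUE, dims)
  specs <- tibble::tribble(
    ~structure, ~metric,   ~comparator, ~threshold, ~units,
    "cord",     "d_max",   "<",         27,         "Gy",
    "heart",    "d_mean",  "<",         12,         "Gy",
    "lungs",    "v_pct@20", "<",        25,         "%"
  )
  mk_plan <- function(val) {
    plan_dose(mk_grid(rep(val, prod(dims)), dims = dims))
  }
  ss <- structure_set(list(body = body,
                           cord = mk_mask(all_occ, name = "cord"),
                           heart = mk_mask(all_occ, name = "heart"),
                           lungs = mk_mask(all_occ, name = "lungs")))

  # cord exactly at 27 Gy fails the strict inequality
  res <- evaluate_constraints(mk_plan(27), ss, specs)
  expect_false(res$pass[res$structure == "cord"])
  expect_equal(res$margin[res$structure == "cord"], 0)

  # heart D_mean 12.5 vs < 12: fail with margin -0.5
  res2 <- evaluate_constraints(mk_plan(12.5), ss, specs)
  expect_false(res2$pass[res2$structure == "heart"])
  expect_equal(res2$margin[res2$structure == "heart"], -0.5)

  # lungs V20 = 0% passes with margin 25
  res3 <- evaluate_constraints(mk_plan(10), ss, specs)
  expect_true(res3$pass[res3$structure == "lungs"])
  expect_equal(res3$margin[res3$structure == "lungs"], 25)

  # missing structure -> not evaluable, not a crash
  ss2 <- structure_set(list(body = body,
                            cord = mk_mask(all_occ, name = "cord")))
  res4 <- evaluate_constraints(mk_plan(10), ss2, specs)
  expect_true(is.na(res4$pass[res4$structure == "heart"]))

  # unresolvable descriptor is a configuration error
  bad <- tibble::tibble(structure = "cord", metric = "nonsense@3",
                        comparator = "<", threshold = 1, units = "Gy")
  expect_error(evaluate_constraints(mk_plan(10), ss, bad), "nonsense")
})

test_that("published organ-at-risk cohort means violate no shipped constraint", {
  oar <- reference_cohort_summary("oar")
  ptv <- reference_cohort_summary("ptv")
  for (col in c("mean_s", "mean_d")) {
    audit <- audit_summary_metrics(rbind(oar, ptv), value_col = col)
    evaluated <- audit[!is.na(audit$pass), ]
    expect_gt(nrow(evaluated), 5)
    expect_true(all(evaluated$pass))
  }
})
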