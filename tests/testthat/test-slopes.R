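mk_meas <- function(times, cd4) data.frame(patient_id = "P", time = times,
                                           cd4 = cd4)

test_that("two-point slope uses the greedy latest admissible pair", {
  expect_equal(slope_two_point(mk_meas(c(2.0, 2.6), c(400, 343)))$slope, -95)
  # last pair 2.3 -> 2.5 is under the 6-month gap, so the earlier point
  # recedes to t = 1.0: slope = (470 - 500) / 1.5
  est <- slope_two_point(mk_meas(c(1.0, 2.3, 2.5), c(500, 480, 470)))
  expect_equal(est$slope, -20)
  expect_equal(c(est$t1, est$t2), c(1.0, 2.5))
  expect_equal(slope_two_point(mk_meas(c(0, 2), c(400, 400)))$slope, 0)
  # no admissible pair at all
  expect_null(slope_two_point(mk_meas(c(1.0, 1.2), c(500, 490))))
  expect_null(slope_two_point(mk_meas(1, 500)))
  # exactly invariant to measurements earlier than the chosen pair
  a <- slope_two_point(mk_meas(c(0.1, 0.4, 2.0, 2.6), c(900, 100, 400, 343)))
  expect_equal(a$slope, -95)
})

test_that("per-patient least squares matches hand-solved normal equations", {
  # n = 2 identity with the two-point slope
  m2 <- mk_meas(c(2.0, 2.6), c(400, 343))
  expect_equal(slope_ols(m2)$slope, slope_two_point(m2)$slope)
  expect_equal(slope_ols(mk_meas(0:2, c(600, 540, 480)))$slope, -60)
  expect_equal(slope_ols(mk_meas(0:2, c(600, 560, 560)))$slope, -20)
  expect_null(slope_ols(mk_meas(c(1, 1), c(500, 400))))  # one distinct time
})

test_that("sensitivity filters subset measurements deterministically", {
  cart <- as.Date("2002-01-01")
  fp <- as.Date("1998-12-31")
  p <- patient_row("F1", cart_date = cart, first_positive_date = fp,
                   last_negative_date = as.Date("1998-01-01"),
                   seroconversion_date = as.Date("1998-07-02"),
                   log10_vl_at_cart = 4)
  m <- meas_rows("F1", c(fp + 0.3 * 365.25,            # < 6 mo after test
                         cart - 2.1 * 365.25,          # outside 2-y window
                         cart - 1.9 * 365.25, cart - 100),
                 c(600, 550, 500, 450))
  co <- new_cohort(p, m, era = "cart")
  expect_identical(apply_slope_filter(co, "none"), co)
  f1 <- apply_slope_filter(co, "drop_first_6mo")
  expect_equal(nrow(f1$measurements), 3)
  # the 2-y window keeps the 1.9-y-old count, drops those 2.1 and 2.7 y old
  f2 <- apply_slope_filter(co, "last_2y_window")
  expect_equal(sort(f2$measurements$cd4), c(450, 500))
  # 1999 seroconverter is dropped by the 1996+ filter only via its date
  co96 <- new_cohort(rbind(p, patient_row("F2",
                                          seroconversion_date = as.Date("1995-06-01"))),
                     m, era = "cart")
  f3 <- apply_slope_filter(co96, "seroconversion_1996_plus")
  expect_equal(f3$patients$patient_id, "F1")
})

test_that("BLUP slopes shrink towards the population slope", {
  # dense, low-noise patients: BLUP ~ OLS
  m <- make_panel(60, seq(0.25, 4, 0.25), "linear", sd_eps = 10, seed = 21)
  co <- new_cohort(
    do.call(rbind, lapply(unique(m$patient_id), function(id)
      patient_row(id, cart_date = as.Date("2005-01-01"),
                  log10_vl_at_cart = 4))),
    cbind(m, date = as.Date("1999-07-02") + m$time * 365.25,
          log10_vl = NA_real_),
    era = "cart")
  blup <- estimate_slopes(co, "blup")
  ols <- estimate_slopes(co, "ols")
  d <- merge(blup, ols, by = "patient_id")
  expect_lt(max(abs(d$slope.x - d$slope.y)), 1)

  # a patient observed once at t = 0 carries no slope information:
  # with independent random effects the BLUP equals the population slope
  m1 <- rbind(m, data.frame(patient_id = "LONE", time = 0, cd4 = 500))
  f <- fit_lmm(m1, correlated = FALSE)
  lone <- f$blups[f$blups$patient_id == "LONE", ]
  expect_equal(lone$b1, 0, tolerance = 1e-6)
  expect_equal(lone$slope, f$beta1, tolerance = 1e-6)
})

test_that("slope variability ordering: two-point >= OLS >= BLUP", {
  sim <- simulate_cohort(simulation_config(n_patients = 400, seed = 23))
  el <- apply_eligibility(sim$cohort)$cohort
  v <- vapply(c("two_point", "ols", "blup"), function(m)
    var(estimate_slopes(el, m)$slope), 1)
  expect_true(v["two_point"] >= v["ols"])
  expect_true(v["ols"] >= v["blup"])
})

test_that("raw- and sqrt-scale slopes agree in rank", {
  sim <- simulate_cohort(simulation_config(n_patients = 300, seed = 24))
  el <- apply_eligibility(sim$cohort)$cohort
  raw <- estimate_slopes(el, "blup", scale = "raw")
  sq <- estimate_slopes(el, "blup", scale = "sqrt")
  d <- merge(raw, sq, by = "patient_id")
  expect_gt(cor(d$slope.x, d$slope.y, method = "spearman"), 0.9)
})

test_that("slope summaries report median, IQR and rapid-decliner fraction", {
  s <- data.frame(patient_id = c("a", "b"), method = "ols",
                  slope = c(-50, -150), n_points_used = 3, scale = "raw")
  sm <- summarize_slopes(s, threshold = 100)
  expect_equal(sm$prop_rapid, 0.5)
  s0 <- data.frame(slope = rep(0, 5))
  sm0 <- summarize_slopes(s0)
  expect_equal(sm0$median, 0)
  expect_equal(sm0$prop_rapid, 0)
  expect_true(sm0$iqr["q1"] <= sm0$median && sm0$median <= sm0$iqr["q3"])
  expect_error(summarize_slopes(s0[0, , drop = FALSE]), "no slope")
})
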