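four_subject_records <- function() {
  data.frame(patient_id = c("a", "b", "c", "d"),
             time = c(1, 2, 3, 4), event = c(TRUE, TRUE, TRUE, FALSE),
             slope = c(-10, 0, -10, 0) * 10,  # binary-like covariate via /10
             cd4_baseline = 300, cd4_stratum = factor("200-<350"),
             idu = FALSE, log10_vl = 4.5, age = 35, prior_aids = FALSE)
}

test_that("person-year event rates use the Poisson normal approximation", {
  er <- event_rate(255, 10296)
  expect_equal(round(er$rate_per_100py, 2), 2.48)
  expect_equal(round(unname(er$ci), 2), c(2.17, 2.78))
  er0 <- event_rate(0, 100)
  expect_equal(er0$rate_per_100py, 0)
  expect_equal(unname(er0$ci), c(0, 0))
  expect_equal(event_rate(10, 500)$rate_per_100py, 2.00)
  expect_error(event_rate(10, 0), "person_years")
})

test_that("Cox coefficient matches a brute-force partial-likelihood grid", {
  rec <- four_subject_records()
  rec$x <- c(1, 0, 1, 0)
  rec$slope <- rec$x * 10   # slope10 becomes exactly x
  fit <- cox_fit_stratified(rec, covariates = character(0), strata = "none")
  # hand-written Efron/Breslow partial likelihood (no ties)
  pl <- function(b) {
    (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2)) + (b - log(exp(b) + 1))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, 1))]
  b_fit <- log(fit$hr_slope_per10["hr"])
  expect_equal(unname(b_fit), b_grid, tolerance = 1e-4)
})

test_that("null covariates yield nominal coverage and no flags", {
  covered <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 300
    rec <- data.frame(patient_id = as.character(1:n),
                      time = rexp(n, 0.2), event = runif(n) < 0.5,
                      slope = rnorm(n, -60, 25),
                      cd4_baseline = runif(n, 50, 600),
                      idu = runif(n) < 0.1,
                      log10_vl = rnorm(n, 4.5, 0.8),
                      age = rnorm(n, 36, 8), prior_aids = runif(n) < 0.1)
    rec$cd4_stratum <- cd4slope:::cd4_stratum(rec$cd4_baseline)
    fit <- cox_fit_stratified(rec)
    hr <- fit$hr_slope_per10
    if (hr["lower"] <= 1 && 1 <= hr["upper"]) covered <- covered + 1
  }
  expect_gte(covered, 16)  # ~95% nominal over 20 replicates
})

test_that("degenerate covariates are flagged rather than reported", {
  rec <- four_subject_records()
  rec$slope <- 0  # constant
  fit <- cox_fit_stratified(rec, covariates = character(0), strata = "none")
  expect_true(fit$flagged)
  allb <- rapid_decline_binary_cox(rec, covariates = character(0),
                                   strata = "none")
  expect_true(allb$flagged)       # nobody is a rapid decliner
  expect_true(is.na(allb$hr_slope_per10["hr"]))
})

test_that("truncated c index agrees with explicit pair enumeration", {
  rec <- data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, FALSE))
  cc <- concordance_5y(rec, c(0.9, 0.5, 0.1), horizon = 5)
  expect_equal(cc$c, 1)
  expect_equal(cc$n_comparable_pairs, 3)

  # random data against a brute-force double loop
  set.seed(7)
  n <- 120
  rec <- data.frame(time = rexp(n, 0.3), event = runif(n) < 0.6)
  sc <- round(rnorm(n), 1)  # rounded to force some score ties
  cc <- concordance_5y(rec, sc, horizon = 5)
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (rec$event[i] && rec$time[i] < rec$time[j] && rec$time[i] <= 5) {
      den <- den + 1
      num <- num + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    }
  }
  expect_equal(cc$c, num / den)
  expect_equal(cc$n_comparable_pairs, den)

  # all scores tied: exactly 1/2
  expect_equal(concordance_5y(rec, rep(1, n))$c, 0.5)
  expect_error(concordance_5y(rec[rec$time > 10, ], sc[rec$time > 10]),
               "no comparable pairs")
})

test_that("uninformative scores discriminate at 0.5", {
  set.seed(9)
  n <- 2000
  rec <- data.frame(time = rexp(n, 0.3), event = runif(n) < 0.6)
  cc <- concordance_5y(rec, runif(n))
  expect_lt(abs(cc$c - 0.5), 0.03)
})

test_that("5-year risks reproduce a hand-built Breslow calculation", {
  rec <- four_subject_records()
  rec$x <- c(1, 0, 1, 0)
  rec$slope <- rec$x * 10
  fit <- cox_fit_stratified(rec, covariates = character(0), strata = "none")
  b <- unname(log(fit$hr_slope_per10["hr"]))
  H0 <- 1 / (2 * exp(b) + 2) + 1 / (exp(b) + 2) + 1 / (exp(b) + 1)
  expected <- 1 - exp(-H0 * exp(b * rec$x))
  expect_equal(unname(risk_scores_5y(fit, horizon = 5)), expected,
               tolerance = 1e-6)
  # monotone in the linear predictor within a stratum
  sc <- risk_scores_5y(fit, horizon = 5)
  expect_true(all(diff(sc[order(rec$x)]) >= -1e-12))
})

test_that("single-stratum zero-covariate model gives equal risks and c = 0.5", {
  rec <- four_subject_records()
  fit <- cox_fit_stratified(rec, covariates = character(0), strata = "none",
                            slope_term = "none")
  sc <- risk_scores_5y(fit)
  expect_equal(length(unique(round(sc, 12))), 1)
  expect_equal(concordance_5y(rec, sc)$c, 0.5)
})

test_that("unseen stratum in scoring data is an error", {
  rec <- four_subject_records()
  fit <- cox_fit_stratified(rec, covariates = character(0))
  new <- rec
  new$cd4_stratum <- factor("<100", levels = levels(cd4slope:::cd4_stratum(1)))
  expect_error(risk_scores_5y(fit, new), "stratum absent")
})

test_that("quartile event table: hand counts, tie rule, conservation", {
  rec <- data.frame(event = c(TRUE, rep(FALSE, 6), TRUE), slope = 1:8)
  qt <- quartile_event_table(rec)
  expect_equal(qt$events, c(1, 0, 0, 1))
  expect_equal(sum(qt$events), sum(rec$event))
  # a slope exactly at a cut point goes to the lower quartile
  rec2 <- data.frame(event = rep(TRUE, 5), slope = c(1, 2, 3, 4, 5))
  qt2 <- quartile_event_table(rec2)
  expect_equal(qt2$n, c(2, 1, 1, 1))  # cut at 2 -> slope 2 in quartile 1
  expect_error(quartile_event_table(data.frame(event = TRUE, slope = 1)),
               "distinct")
  # events independent of slope spread evenly
  set.seed(11)
  rec3 <- data.frame(event = runif(2000) < 0.3, slope = runif(2000))
  qt3 <- quartile_event_table(rec3)
  expect_gt(chisq.test(qt3$events)$p.value, 0.001)
})

test_that("dichotomising a null slope manufactures no signal", {
  set.seed(13)
  n <- 2000
  rec <- data.frame(patient_id = as.character(1:n),
                    time = rexp(n, 0.2), event = runif(n) < 0.4,
                    slope = rnorm(n, -90, 40),
                    cd4_baseline = runif(n, 50, 600),
                    idu = runif(n) < 0.1, log10_vl = rnorm(n, 4.5, 0.8),
                    age = rnorm(n, 36, 8), prior_aids = runif(n) < 0.1)
  rec$cd4_stratum <- cd4slope:::cd4_stratum(rec$cd4_baseline)
  fit <- rapid_decline_binary_cox(rec)
  expect_false(fit$flagged)
  expect_lt(abs(log(fit$hr_slope_per10["hr"])), 0.25)
  expect_true(fit$hr_slope_per10["lower"] < 1 && fit$hr_slope_per10["upper"] > 1)
})
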