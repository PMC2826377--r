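test_that("seroconversion midpoint rule and its guards", {
  t0 <- as.Date("2000-01-01")
  expect_equal(derive_seroconversion(t0, t0 + 365.25),
               t0 + 365.25 / 2)
  expect_equal(derive_seroconversion(t0, t0), t0)
  # the cohort's median test window is 0.82 y; midpoint falls at 0.41 y
  fp <- t0 + 0.82 * 365.25
  expect_equal(as.numeric(derive_seroconversion(t0, fp) - t0) / 365.25,
               0.41, tolerance = 1e-6)
  expect_error(derive_seroconversion(t0 + 10, t0), "after first positive")
  expect_error(derive_seroconversion(t0, t0 + 4 * 365.25), "interval too wide")
  expect_error(derive_seroconversion(as.Date(NA), t0), "invalid")
})

make_elig_cohort <- function() {
  cart <- as.Date("2003-06-01")
  pts <- rbind(
    patient_row("E1", cart_date = cart, log10_vl_at_cart = 4.5),   # eligible
    patient_row("E2", cart_date = cart),                           # 1 CD4 only
    patient_row("E3", cart_date = cart, log10_vl_at_cart = 4.5),   # CD4 too old
    patient_row("E4", cart_date = cart),                           # VL missing
    patient_row("E5", cart_date = cart),                           # both missing
    patient_row("E6", cart_date = cart, log10_vl_at_cart = 4.5),   # gap < 91 d
    patient_row("E7"))                                             # no cART
  meas <- rbind(
    meas_rows("E1", cart - c(30, 200), c(300, 420)),
    meas_rows("E2", cart - 10, 350),
    meas_rows("E3", cart - c(100, 300), c(310, 500)),
    meas_rows("E4", cart - c(20, 150), c(280, 390)),
    meas_rows("E5", cart - c(120, 400), c(330, 520)),
    meas_rows("E6", cart - c(5, 60), c(290, 310)),
    meas_rows("E7", cart - c(10, 100), c(400, 450)))
  new_cohort(pts, meas, era = "cart")
}

test_that("eligibility rules partition exclusions in the documented order", {
  co <- make_elig_cohort()
  res <- apply_eligibility(co)
  expect_equal(res$report$n_input, 6)  # E7 (no cART) dropped before accounting
  expect_equal(res$report$n_eligible, 1)
  expect_equal(res$cohort$patients$patient_id, "E1")
  ex <- res$report$exclusions
  expect_equal(unname(ex["fewer_than_two_cd4"]), 1)  # E2
  expect_equal(unname(ex["missing_cd4_window"]), 1)  # E3: 100 d > 91 d
  expect_equal(unname(ex["missing_vl_window"]), 1)   # E4
  expect_equal(unname(ex["missing_both"]), 1)        # E5
  expect_equal(unname(ex["interval_below_3mo"]), 1)  # E6: 55 d gap
  expect_equal(res$report$n_input,
               res$report$n_eligible + sum(ex))
  # baseline CD4 = window value closest to cART
  expect_equal(res$cohort$patients$baseline_cd4, 300)
})

test_that("eligibility is monotone in the window width", {
  co <- make_elig_cohort()
  ids_91 <- apply_eligibility(co, window_days = 91)$cohort$patients$patient_id
  for (w in c(120, 200, 400)) {
    ids_w <- apply_eligibility(co, window_days = w)$cohort$patients$patient_id
    expect_true(all(ids_91 %in% ids_w))
  }
  # wide enough windows admit the stale-window patient E3
  expect_true("E3" %in%
                apply_eligibility(co, window_days = 150)$cohort$patients$patient_id)
})

test_that("empty cohorts produce zeroed eligibility reports", {
  co <- new_cohort(patient_row("X")[0, ],
                   meas_rows("X", as.Date("2000-01-01"), 100)[0, ],
                   era = "cart")
  res <- apply_eligibility(co)
  expect_equal(res$report$n_input, 0)
  expect_equal(sum(res$report$exclusions), 0)
})

test_that("endpoint construction follows first-event-wins with censoring", {
  cart <- as.Date("2000-01-01")
  pts <- rbind(
    patient_row("A", cart_date = cart, death_date = cart + 2 * 365.25,
                last_visit_date = cart + 2 * 365.25),
    patient_row("B", cart_date = cart, last_visit_date = cart + 3.2 * 365.25),
    patient_row("C", cart_date = cart, aids_date = cart + 1 * 365.25,
                death_date = cart + 2 * 365.25,
                last_visit_date = cart + 2 * 365.25))
  co <- new_cohort(pts, meas_rows("A", cart - 10, 300), era = "cart")
  ep <- build_endpoint(co, "aids_or_death")
  expect_equal(ep$time[ep$patient_id == "A"], 2.0)
  expect_true(ep$event[ep$patient_id == "A"])
  expect_equal(ep$time[ep$patient_id == "B"], 3.2)
  expect_false(ep$event[ep$patient_id == "B"])
  expect_equal(ep$time[ep$patient_id == "C"], 1.0)  # AIDS precedes death
  epd <- build_endpoint(co, "death")
  expect_equal(epd$time[epd$patient_id == "C"], 2.0)
  expect_true(all(ep$time > 0))

  bad <- patient_row("Z", cart_date = cart, death_date = cart - 10,
                     last_visit_date = cart + 100)
  cobad <- new_cohort(bad, meas_rows("Z", cart - 5, 200), era = "cart")
  expect_error(build_endpoint(cobad), "invalid record")
})

test_that("pre-cART baseline: last 1993 CD4, prior-CD4 requirement, censoring", {
  mk <- function(id, dates, cd4 = 400, aids = as.Date(NA),
                 death = as.Date(NA), art = as.Date(NA)) {
    list(p = patient_row(id,
                         last_negative_date = as.Date("1988-01-01"),
                         first_positive_date = as.Date("1989-01-01"),
                         seroconversion_date = as.Date("1988-07-02"),
                         aids_date = aids, death_date = death,
                         last_visit_date = as.Date("1997-06-30"),
                         art_start_date = art),
         m = meas_rows(id, dates, cd4))
  }
  a <- mk("A", as.Date(c("1991-06-01", "1993-03-01", "1993-09-01")))
  b <- mk("B", as.Date(c("1991-06-01", "1992-03-01")))        # no 1993 CD4
  c3 <- mk("C", as.Date(c("1991-02-01", "1993-05-01")),
           aids = as.Date("1992-12-01"))                      # prior AIDS
  d <- mk("D", as.Date(c("1993-02-01", "1993-07-01")))        # no prior-window CD4? has one
  e <- mk("E", as.Date(c("1991-01-01", "1993-04-01")),
          death = as.Date("1996-02-15"))                      # event after censor
  f <- mk("F", as.Date(c("1991-01-01", "1993-04-01")),
          art = as.Date("1992-06-01"))                        # on ART by 1993
  co <- new_cohort(do.call(rbind, lapply(list(a, b, c3, d, e, f), `[[`, "p")),
                   do.call(rbind, lapply(list(a, b, c3, d, e, f), `[[`, "m")),
                   era = "pre_cart")
  base <- build_pre_cart_baseline(co)
  expect_setequal(base$patients$patient_id, c("A", "D", "E", "F"))
  expect_equal(base$patients$baseline_date[base$patients$patient_id == "A"],
               as.Date("1993-09-01"))
  ep <- build_endpoint(base, "death")
  # death 1996-02 is censored at 1995-12-31
  eE <- ep[ep$patient_id == "E", ]
  expect_false(eE$event)
  expect_equal(eE$time,
               as.numeric(as.Date("1995-12-31") - as.Date("1993-04-01")) / 365.25)
  # ART-naive sensitivity drops F and is a subset of the main population
  sens <- build_pre_cart_baseline(co, exclude_any_art = TRUE)
  expect_false("F" %in% sens$patients$patient_id)
  expect_true(all(sens$patients$patient_id %in% base$patients$patient_id))
})

test_that("cohort CSV round-trip and input validation", {
  sim <- simulate_cohort(simulation_config(n_patients = 12, seed = 42))
  dir <- tempfile("cohort")
  write_cohort(sim$cohort, dir)
  back <- read_cohort(file.path(dir, "patients.csv"),
                      file.path(dir, "measurements.csv"))
  expect_equal(back$patients$patient_id, sim$cohort$patients$patient_id)
  expect_equal(back$measurements$cd4, sim$cohort$measurements$cd4)
  expect_equal(back$measurements$time, sim$cohort$measurements$time,
               tolerance = 1e-3)  # dates serialised at day precision
  # write(read(x)) = read(x)
  dir2 <- tempfile("cohort2")
  write_cohort(back, dir2)
  again <- read_cohort(file.path(dir2, "patients.csv"),
                       file.path(dir2, "measurements.csv"))
  expect_equal(again$measurements, back$measurements)

  # negative CD4 is a hard error naming the row
  mf <- file.path(dir, "measurements.csv")
  m <- read.csv(mf, stringsAsFactors = FALSE)
  m$cd4[3] <- -5
  write.csv(m, mf, row.names = FALSE, na = "")
  expect_error(read_cohort(file.path(dir, "patients.csv"), mf),
               "negative CD4.*row 3")

  # empty measurement file is a valid degenerate cohort
  ef <- file.path(dir, "empty.csv")
  writeLines("patient_id,date,cd4,log10_vl", ef)
  co <- read_cohort(file.path(dir, "patients.csv"), ef)
  expect_equal(nrow(co$measurements), 0)

  # unknown columns warn; missing mandatory columns error
  p <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  p$favourite_colour <- "blue"
  pf <- file.path(dir, "patients2.csv")
  write.csv(p, pf, row.names = FALSE, na = "")
  expect_warning(read_cohort(pf, ef), "unknown patient column")
  p$patient_id <- NULL
  write.csv(p, pf, row.names = FALSE, na = "")
  expect_error(suppressWarnings(read_cohort(pf, ef)), "missing mandatory")
})
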