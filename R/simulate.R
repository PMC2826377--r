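# Synthetic seroconverter cohorts.
#
# Emulates the statistical design the pipeline assumes: bracketed
# seroconversion windows, irregular CD4 visit schedules, trajectories from a
# linear random-intercept/random-slope model or an integrated OU process,
# CD4-threshold-driven (informative) cART initiation, and post-cART
# AIDS/death times from a proportional-hazards model on baseline covariates.
# Ground truth (random intercepts and realised slopes) is returned alongside
# and is never consumed by estimation code.

#' Simulation configuration for a synthetic seroconverter cohort
#'
#' Defaults describe a cohort of European-style seroconverters initiating
#' cART under a 350 cells/ul guideline threshold: mean CD4 at seroconversion
#' 620 cells/ul declining 60 cells/ul per year, visit gaps averaging 0.4
#' years, measurement error SD 80 cells/ul, and a median
#' last-negative/first-positive test window of 0.82 years.  The post-cART
#' hazard acts on baseline covariates only; the coefficient on the true slope
#' defaults to 0 (slope carries no prognostic signal beyond baseline
#' covariates).
#'
#' @param n_patients number of patients.
#' @param seed integer seed; each patient consumes an independent substream
#'   derived from `(seed, patient index)`, so enlarging the cohort never
#'   perturbs earlier patients.
#' @param trajectory `"linear"` (random intercept + random slope) or `"iou"`
#'   (random intercept, population slope, integrated OU fluctuation).
#' @param beta0,beta1 population CD4 at seroconversion (cells/ul) and
#'   population slope (cells/ul/year, negative).
#' @param sd_b0 random-intercept SD (cells/ul).
#' @param sd_b1 random-slope SD (cells/ul/year; linear trajectory).
#' @param alpha IOU mean-reversion rate (1/years; iou trajectory).
#' @param tau stationary SD of the OU slope fluctuation (cells/ul/year); the
#'   diffusion scale is `sigma2 = 2 * alpha * tau^2`.
#' @param sd_eps measurement-error SD (cells/ul), applied to observations
#'   only; observed CD4 is floored at 0, the latent path is not.
#' @param visit_interval_mean mean visit gap (years); `visit_schedule =
#'   "fixed"` uses this as a deterministic interval instead.
#' @param visit_schedule `"exponential"` (memoryless gaps) or `"fixed"`.
#' @param cart_threshold CD4 threshold (cells/ul) triggering possible cART.
#' @param cart_prob_per_visit probability of initiating at a visit whose
#'   observed CD4 is below the threshold.
#' @param cart_above_frac initiation at visits at or above the threshold
#'   occurs at `cart_above_frac * cart_prob_per_visit` per visit (clinician
#'   or patient preference, symptomatic disease, changing guidelines); this
#'   yields the minority of initiations at CD4 above the guideline
#'   threshold seen in practice.  Set to 0 for a pure threshold rule.
#' @param cart_trigger `"observed"` (default: initiation reacts to the
#'   measured CD4, a missing-at-random mechanism under which
#'   likelihood-based trajectory fits remain valid) or `"latent"`
#'   (initiation reacts to the noise-free latent CD4 — clinicians acting on
#'   the patient's true immune state — which a naive mixed model cannot
#'   absorb and the joint model is designed to correct).
#' @param outcome named log-hazard-ratio vector for the post-cART hazard:
#'   `cd4_per100` (per +100 cells/ul baseline CD4), `log10_vl` (per log10
#'   copy/ml), `age_per10` (per +10 years), `prior_aids`, `slope_per10`
#'   (per +10 cells/ul/year higher true slope).  Covariates are centred at
#'   CD4 300, VL 4.5, age 36, slope -60.
#' @param baseline_hazard events per person-year at the centring point.
#' @param admin_censor administrative censoring (years after cART).
#' @param test_window_max maximum last-negative/first-positive interval
#'   (years, at most 3); widths are uniform on (0, max], so the default 1.64
#'   gives a median window of 0.82 years.
#' @param vl_mean,vl_sd,vl_slope_coef log10 viral load at cART: normal with
#'   this mean/SD plus `vl_slope_coef` times the standardised (negated) true
#'   slope; the default 0 leaves VL uncorrelated with slope.
#' @param vl_missing_prob probability the cART viral load is missing
#'   (exercises the eligibility exclusions).
#' @param death_frac fraction of first events that are deaths rather than
#'   new AIDS events.
#' @param max_pre_cart_years visit horizon for patients never initiating.
#' @param era `"cart"` or `"pre_cart"` (untreated 1989-1995 design; no cART,
#'   calendar seroconversions 1987-1992, events from the same hazard form on
#'   1993-baseline covariates).
#' @return a validated config (class `cd4_sim_config`).
#' @export
simulation_config <- function(n_patients = 1000, seed = 1,
                              trajectory = c("linear", "iou"),
                              beta0 = 620, beta1 = -60,
                              sd_b0 = 150, sd_b1 = 25,
                              alpha = 20, tau = 60,
                              sd_eps = 80,
                              visit_interval_mean = 0.4,
                              visit_schedule = c("exponential", "fixed"),
                              cart_threshold = 350,
                              cart_prob_per_visit = 0.8,
                              cart_above_frac = 0.04,
                              cart_trigger = c("observed", "latent"),
                              outcome = c(cd4_per100 = -0.30, log10_vl = 0.30,
                                          age_per10 = 0.30, prior_aids = 0.80,
                                          slope_per10 = 0),
                              baseline_hazard = 0.025,
                              admin_censor = 5,
                              test_window_max = 1.64,
                              vl_mean = 4.7, vl_sd = 0.8, vl_slope_coef = 0,
                              vl_missing_prob = 0.05,
                              death_frac = 0.36,
                              max_pre_cart_years = 10,
                              era = c("cart", "pre_cart")) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              trajectory = match.arg(trajectory),
              beta0 = beta0, beta1 = beta1, sd_b0 = sd_b0, sd_b1 = sd_b1,
              alpha = alpha, tau = tau, sd_eps = sd_eps,
              visit_interval_mean = visit_interval_mean,
              visit_schedule = match.arg(visit_schedule),
              cart_threshold = cart_threshold,
              cart_prob_per_visit = cart_prob_per_visit,
              cart_above_frac = cart_above_frac,
              cart_trigger = match.arg(cart_trigger),
              outcome = outcome, baseline_hazard = baseline_hazard,
              admin_censor = admin_censor,
              test_window_max = test_window_max,
              vl_mean = vl_mean, vl_sd = vl_sd,
              vl_slope_coef = vl_slope_coef,
              vl_missing_prob = vl_missing_prob,
              death_frac = death_frac,
              max_pre_cart_years = max_pre_cart_years,
              era = match.arg(era))
  validate_sim_config(cfg)
  structure(cfg, class = "cd4_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1) stop("n_patients must be positive")
    if (any(c(sd_b0, sd_b1, sd_eps, tau, vl_sd) < 0)) stop("SDs must be non-negative")
    if (trajectory == "iou" && alpha <= 0) stop("alpha must be positive for the IOU trajectory")
    if (cart_prob_per_visit < 0 || cart_prob_per_visit > 1) stop("cart_prob_per_visit must lie in [0, 1]")
    if (cart_above_frac < 0 || cart_above_frac > 1) stop("cart_above_frac must lie in [0, 1]")
    if (baseline_hazard < 0) stop("baseline_hazard must be non-negative")
    if (visit_interval_mean <= 0) stop("visit_interval_mean must be positive")
    if (test_window_max <= 0 || test_window_max > 3) stop("test_window_max must lie in (0, 3]")
    req <- c("cd4_per100", "log10_vl", "age_per10", "prior_aids", "slope_per10")
    if (!all(req %in% names(outcome))) stop("outcome must name coefficients: ",
                                            paste(req, collapse = ", "))
  })
  invisible(cfg)
}

# per-patient substream: deterministic function of (seed, index)
patient_seed <- function(seed, i) {
  s <- (as.numeric(seed %% 2147483647L) * 48271 + i * 7919) %% 2147483647
  as.integer(s) + 1L
}

# post-cART (or pre-cART era) log-hazard linear predictor
outcome_lp <- function(cfg, cd4, vl, age, prior_aids, slope_true) {
  oc <- cfg$outcome
  unname(oc["cd4_per100"] * (cd4 - 300) / 100 +
           oc["log10_vl"] * ((if (is.na(vl)) cfg$vl_mean else vl) - 4.5) +
           oc["age_per10"] * (age - 36) / 10 +
           oc["prior_aids"] * as.numeric(prior_aids) +
           oc["slope_per10"] * (slope_true + 60) / 10)
}

#' Latent CD4 values under the linear random-slope trajectory
#'
#' `value(t) = beta0 + b0 + (beta1 + b1) * t`; no measurement error.
#' @param times sorted non-negative times (years since seroconversion).
#' @param b0,b1 patient random intercept and random slope deviations.
#' @param config a `cd4_sim_config`.
#' @return latent CD4 values (cells/ul).
#' @export
draw_trajectory_linear <- function(times, b0, b1, config) {
  config$beta0 + b0 + (config$beta1 + b1) * times
}

#' Latent CD4 values under the IOU trajectory (exact joint draw)
#'
#' `value(t) = beta0 + b0 + beta1 * t + W(t)` with `W` the integral of a
#' stationary OU velocity (SD `tau`, mean reversion `alpha`).  `W` is drawn
#' exactly as one multivariate normal using [iou_kernel()] — not by Euler
#' discretisation.  Consumes random numbers.
#'
#' @inheritParams draw_trajectory_linear
#' @return latent CD4 values (cells/ul).
#' @export
draw_trajectory_iou <- function(times, b0, config) {
  sigma2 <- 2 * config$alpha * config$tau^2
  mean_part <- config$beta0 + b0 + config$beta1 * times
  pos <- times > 0
  if (!any(pos)) return(mean_part)
  tp <- times[pos]
  K <- iou_kernel(matrix(tp, length(tp), length(tp)),
                  matrix(tp, length(tp), length(tp), byrow = TRUE),
                  config$alpha, sigma2)
  U <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(U)) {
    U <- tryCatch(chol(K + diag(1e-8 * max(diag(K)), nrow(K))),
                  error = function(e) NULL)
    if (is.null(U)) stop("IOU kernel numerically non-positive-definite")
  }
  W <- numeric(length(times))
  W[pos] <- drop(crossprod(U, rnorm(length(tp))))
  mean_part + W
}

#' Simulate a seroconverter cohort with ground truth
#'
#' See [simulation_config()] for the generative design.  Reproducible:
#' identical config (including seed) gives a bit-identical cohort.
#'
#' @param config a `cd4_sim_config`.
#' @return list with `cohort` (a `cd4_cohort`) and `truth` (data.frame
#'   `patient_id`, `b0`, `slope_true` — the realised average pre-treatment
#'   slope; oracle only, never used by estimation stages).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cd4_sim_config"))
  cfg <- config
  n <- cfg$n_patients
  pre_cart <- cfg$era == "pre_cart"
  sc_range <- if (pre_cart) as.Date(c("1987-01-01", "1992-06-30"))
              else as.Date(c("1996-01-01", "2003-12-31"))
  pats <- vector("list", n)
  meas <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_seed(cfg$seed, i))
    id <- sprintf("P%05d", i)
    sc_true <- sc_range[1] + runif(1) * as.numeric(diff(sc_range))
    w <- runif(1, 0, cfg$test_window_max)                    # window width, years
    u <- runif(1)                                            # position inside it
    last_neg <- sc_true - u * w * DAYS_PER_YEAR
    first_pos <- sc_true + (1 - u) * w * DAYS_PER_YEAR
    sc_mid <- last_neg + as.numeric(first_pos - last_neg) / 2
    sex <- if (runif(1) < 0.20) "female" else "male"
    tg <- sample(c("msm", "heterosexual", "idu", "other"), 1,
                 prob = c(0.59, 0.26, 0.09, 0.06))
    age_sc <- max(16, rnorm(1, 33, 8))
    prior_aids <- runif(1) < 0.08
    b0 <- rnorm(1, 0, cfg$sd_b0)

    # candidate visit times from true seroconversion, first at diagnosis
    t_first <- years_between(sc_true, first_pos)
    horizon <- if (pre_cart) {
      max(0.5, years_between(sc_true, as.Date("1996-06-30")))
    } else cfg$max_pre_cart_years
    if (cfg$visit_schedule == "fixed") {
      # deterministic grid at multiples of the interval since seroconversion
      # (shared across patients whose diagnosis precedes the first grid point)
      times <- seq(cfg$visit_interval_mean, horizon,
                   by = cfg$visit_interval_mean)
      times <- times[times >= t_first]
      if (length(times) == 0) times <- t_first
    } else {
      gaps <- rexp(ceiling(3 * horizon / cfg$visit_interval_mean) + 20,
                   rate = 1 / cfg$visit_interval_mean)
      times <- t_first + cumsum(c(0, gaps))
      times <- times[times <= horizon]
      if (length(times) == 0) times <- t_first
    }

    if (cfg$trajectory == "linear") {
      b1 <- rnorm(1, 0, cfg$sd_b1)
      latent <- draw_trajectory_linear(times, b0, b1, cfg)
    } else {
      latent <- draw_trajectory_iou(times, b0, cfg)
    }
    obs <- pmax(0, latent + rnorm(length(times), 0, cfg$sd_eps))

    # informative cART initiation: first visit with observed CD4 below the
    # threshold where the Bernoulli fires
    cart_idx <- NA_integer_
    if (!pre_cart && cfg$cart_prob_per_visit > 0) {
      trigger_vals <- if (cfg$cart_trigger == "latent") latent else obs
      p_fire <- ifelse(trigger_vals < cfg$cart_threshold,
                       cfg$cart_prob_per_visit,
                       cfg$cart_above_frac * cfg$cart_prob_per_visit)
      fire <- runif(length(times)) < p_fire
      if (any(fire)) cart_idx <- which(fire)[1]
    }
    keep_idx <- if (is.na(cart_idx)) seq_along(times) else seq_len(cart_idx)
    vt <- times[keep_idx]; vo <- obs[keep_idx]

    t_last <- max(vt)
    # realised average slope over the observed pre-treatment period:
    # beta1 + b1 for the linear path, beta1 + W(T)/T for the IOU path
    slope_true <- if (cfg$trajectory == "linear") {
      cfg$beta1 + b1
    } else {
      W_T <- latent[length(keep_idx)] - (cfg$beta0 + b0) - cfg$beta1 * t_last
      if (t_last > 0) cfg$beta1 + W_T / t_last else cfg$beta1
    }

    vl <- cfg$vl_mean + cfg$vl_slope_coef * (-(slope_true - cfg$beta1) /
                                               max(cfg$sd_b1, cfg$tau, 1)) +
      rnorm(1, 0, cfg$vl_sd)
    vl_missing <- runif(1) < cfg$vl_missing_prob

    visit_dates <- sc_true + vt * DAYS_PER_YEAR
    vl_col <- rep(NA_real_, length(vt))
    cart_date <- as.Date(NA)
    aids_date <- death_date <- as.Date(NA)
    art_start <- as.Date(NA)

    if (!pre_cart && !is.na(cart_idx)) {
      cart_date <- visit_dates[length(visit_dates)]
      if (!vl_missing) vl_col[length(vl_col)] <- vl
      age_cart <- age_sc + years_between(sc_true, cart_date)
      lp <- outcome_lp(cfg, vo[length(vo)], if (vl_missing) NA else vl,
                       age_cart, prior_aids, slope_true)
      t_event <- rexp(1, rate = cfg$baseline_hazard * exp(lp))
      is_death <- runif(1) < cfg$death_frac
      post_aids_gap <- rexp(1, rate = 0.2)
      if (t_event <= cfg$admin_censor) {
        if (is_death) death_date <- cart_date + t_event * DAYS_PER_YEAR
        else {
          aids_date <- cart_date + t_event * DAYS_PER_YEAR
          if (t_event + post_aids_gap <= cfg$admin_censor) {
            death_date <- cart_date + (t_event + post_aids_gap) * DAYS_PER_YEAR
          }
        }
        last_visit <- cart_date +
          min(t_event + if (is_death) 0 else post_aids_gap, cfg$admin_censor) *
          DAYS_PER_YEAR
      } else {
        last_visit <- cart_date + cfg$admin_censor * DAYS_PER_YEAR
      }
    } else if (pre_cart) {
      # events 1994-1995(+) from baseline covariates at the last 1993 visit
      yrs <- as.integer(format(visit_dates, "%Y"))
      in93 <- which(yrs == 1993)
      cd4_93 <- if (length(in93) > 0) vo[in93[length(in93)]] else
        cfg$beta0 + b0 + cfg$beta1 * years_between(sc_true, as.Date("1993-07-01"))
      age_93 <- age_sc + years_between(sc_true, as.Date("1993-07-01"))
      # centring shifted to the untreated-era distribution (CD4 400, slope -46)
      oc <- cfg$outcome
      lp <- unname(oc["cd4_per100"] * (cd4_93 - 400) / 100 +
                     oc["age_per10"] * (age_93 - 32) / 10 +
                     oc["prior_aids"] * as.numeric(prior_aids) +
                     oc["slope_per10"] * (slope_true + 46) / 10)
      t_event <- rexp(1, rate = cfg$baseline_hazard * exp(lp))
      origin <- as.Date("1994-01-01")
      end_admin <- as.Date("1996-12-31")
      ev_date <- origin + t_event * DAYS_PER_YEAR
      if (ev_date <= end_admin) {
        if (runif(1) < cfg$death_frac) death_date <- ev_date else aids_date <- ev_date
        last_visit <- ev_date
      } else {
        last_visit <- end_admin
      }
      if (runif(1) < 0.40) {                     # mono/dual ART uptake
        art_start <- as.Date("1992-01-01") +
          runif(1) * as.numeric(as.Date("1995-12-31") - as.Date("1992-01-01"))
      }
    } else {
      last_visit <- visit_dates[length(visit_dates)]
    }

    pats[[i]] <- data.frame(
      patient_id = id, sex = sex, age_at_baseline = age_sc,
      transmission_group = tg, prior_aids = prior_aids,
      last_negative_date = last_neg, first_positive_date = first_pos,
      seroconversion_date = sc_mid, cart_date = cart_date,
      log10_vl_at_cart = if (!pre_cart && !is.na(cart_idx) && !vl_missing) vl else NA_real_,
      aids_date = aids_date, death_date = death_date,
      last_visit_date = as.Date(last_visit),
      art_start_date = art_start, stringsAsFactors = FALSE)
    meas[[i]] <- data.frame(patient_id = id, date = as.Date(visit_dates),
                            cd4 = vo, log10_vl = vl_col,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(patient_id = id, b0 = b0,
                             slope_true = slope_true, stringsAsFactors = FALSE)
  }

  patients <- do.call(rbind, pats)
  measurements <- do.call(rbind, meas)
  cohort <- new_cohort(patients, measurements, era = cfg$era)
  list(cohort = cohort, truth = do.call(rbind, truth))
}
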