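# Per-patient CD4-slope estimators: two-point interpolation, per-patient
# ordinary least squares, and mixed-model BLUPs, plus the sensitivity filters
# and the summaries (median, IQR, proportion of rapid decliners).
#
# Sign convention: negative slope = decline, everywhere.

#' Two-point interpolation slope
#'
#' Linear interpolation between the last two CD4 counts at least
#' `min_gap_years` apart: the later point is fixed as late as possible, then
#' the earlier point as late as possible subject to the gap; if no admissible
#' earlier point exists the later point recedes.  Returns `NULL` when no
#' admissible pair exists.
#'
#' @param measurements one patient's measurements (`time`, `cd4`), sorted,
#'   all at or before `at_time`.
#' @param min_gap_years minimum separation (years; 0.5 = "at least 6 mo").
#' @param at_time optional upper bound on measurement times (e.g. the cART
#'   time); measurements after it are dropped.
#' @return list `(slope, n_points_used = 2, t1, t2)` or `NULL`.
#' @export
slope_two_point <- function(measurements, min_gap_years = 0.5, at_time = NULL) {
  m <- measurements[!is.na(measurements$cd4), , drop = FALSE]
  if (!is.null(at_time)) m <- m[m$time <= at_time, , drop = FALSE]
  m <- m[order(m$time), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) return(NULL)
  for (j in n:2) {
    ok <- which(seq_len(n) < j & m$time <= m$time[j] - min_gap_years &
                  m$time < m$time[j])
    if (length(ok) > 0) {
      i <- max(ok)
      return(list(slope = (m$cd4[j] - m$cd4[i]) / (m$time[j] - m$time[i]),
                  n_points_used = 2L, t1 = m$time[i], t2 = m$time[j]))
    }
  }
  NULL
}

#' Per-patient ordinary least-squares slope
#'
#' @param measurements one patient's measurements (`time`, `cd4`).
#' @return list `(slope, n_points_used)` or `NULL` when fewer than two
#'   distinct times are available.
#' @export
slope_ols <- function(measurements) {
  m <- measurements[!is.na(measurements$cd4), , drop = FALSE]
  if (nrow(m) < 2 || length(unique(m$time)) < 2) return(NULL)
  tc <- m$time - mean(m$time)
  list(slope = sum(tc * m$cd4) / sum(tc^2), n_points_used = nrow(m))
}

#' Sensitivity filters on the measurements entering slope estimation
#'
#' * `none` — identity.
#' * `drop_first_6mo` — drop CD4 counts less than 6 months after the first
#'   positive HIV test.
#' * `last_2y_window` — keep only CD4 counts within 2 years before cART
#'   initiation (patients without a cART date keep all measurements).
#' * `seroconversion_1996_plus` — keep only patients who seroconverted in
#'   1996 or later (drops patients, not just measurements).
#'
#' @param cohort a `cd4_cohort`.
#' @param filter one of the names above.
#' @return the filtered `cd4_cohort`.
#' @export
apply_slope_filter <- function(cohort,
                               filter = c("none", "drop_first_6mo",
                                          "last_2y_window",
                                          "seroconversion_1996_plus")) {
  filter <- match.arg(filter)
  if (filter == "none") return(cohort)
  p <- cohort$patients
  m <- cohort$measurements
  if (filter == "drop_first_6mo") {
    fp <- p$first_positive_date[match(m$patient_id, p$patient_id)]
    m <- m[m$date >= fp + 0.5 * DAYS_PER_YEAR, , drop = FALSE]
  } else if (filter == "last_2y_window") {
    cart <- p$cart_date[match(m$patient_id, p$patient_id)]
    keep <- is.na(cart) | m$date >= cart - 2 * DAYS_PER_YEAR
    m <- m[keep, , drop = FALSE]
  } else {
    sc_year <- as.integer(format(p$seroconversion_date, "%Y"))
    p <- p[!is.na(sc_year) & sc_year >= 1996, , drop = FALSE]
    m <- m[m$patient_id %in% p$patient_id, , drop = FALSE]
  }
  out <- new_cohort(p, m, era = cohort$era)
  attr(out, "censor_date") <- attr(cohort, "censor_date")
  out
}

# restrict measurements to the pre-treatment period (<= cart date when known)
pre_cart_measurements <- function(cohort) {
  m <- cohort$measurements
  p <- cohort$patients
  if (cohort$era == "cart") {
    cart <- p$cart_date[match(m$patient_id, p$patient_id)]
    m <- m[is.na(cart) | m$date <= cart, , drop = FALSE]
  }
  m[!is.na(m$cd4), , drop = FALSE]
}

#' Slope estimates for every patient by one method
#'
#' Dispatches to the two-point, least-squares, BLUP or joint-model estimator
#' over all pre-treatment measurements of each patient.  BLUPs come from the
#' random-intercept/random-slope mixed model ([fit_lmm()]): a patient's
#' predicted slope is the population slope plus the predicted random slope,
#' shrunk towards the population according to how much data the patient has;
#' a patient with a single measurement is shrunk (almost) all the way.
#' On the `sqrt` scale the fitted slope is mapped back to cells/ul/year by
#' the delta method, `2 * m_i * s_i`, with `m_i` the patient's fitted
#' square-root CD4 at the midpoint of their observation span.
#'
#' @param cohort a `cd4_cohort` (eligible subset).
#' @param method `"two_point"`, `"ols"`, `"blup"` or `"joint"`.
#' @param filter sensitivity filter, see [apply_slope_filter()].
#' @param scale `"raw"` or `"sqrt"`.
#' @param min_gap_years two-point minimum separation.
#' @return data.frame `patient_id`, `method`, `slope` (cells/ul/year),
#'   `n_points_used`, `scale`; patients without an estimate are omitted.
#' @export
estimate_slopes <- function(cohort,
                            method = c("blup", "two_point", "ols", "joint"),
                            filter = "none", scale = c("raw", "sqrt"),
                            min_gap_years = 0.5) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  cohort <- apply_slope_filter(cohort, filter)
  meas <- pre_cart_measurements(cohort)
  if (scale == "sqrt" && method %in% c("two_point", "ols")) {
    meas$cd4_raw <- meas$cd4
    meas$cd4 <- sqrt(meas$cd4)
  }

  if (method %in% c("two_point", "ols")) {
    p <- cohort$patients
    res <- lapply(split(meas, meas$patient_id), function(mi) {
      est <- if (method == "two_point") {
        slope_two_point(mi, min_gap_years = min_gap_years)
      } else slope_ols(mi)
      if (is.null(est)) return(NULL)
      slope <- est$slope
      if (scale == "sqrt") {
        # delta method back to cells/ul/year at the patient's mean level
        mlev <- mean(sqrt(mi$cd4_raw))
        slope <- 2 * mlev * slope
      }
      data.frame(patient_id = mi$patient_id[1], slope = slope,
                 n_points_used = est$n_points_used, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  } else {
    fit <- if (method == "blup") fit_lmm(meas, scale = scale)
           else fit_joint(cohort, scale = scale)
    blups <- fit$blups
    npts <- table(meas$patient_id)
    slope <- blups$slope
    if (scale == "sqrt") {
      # fitted sqrt-level at the midpoint of each patient's observation span
      tmid <- tapply(meas$time, meas$patient_id, function(t) mean(range(t)))
      tmid <- as.numeric(tmid[blups$patient_id])
      mlev <- fit$beta0 + blups$b0 + blups$slope * tmid
      slope <- 2 * pmax(mlev, 1e-6) * blups$slope
    }
    out <- data.frame(patient_id = blups$patient_id, slope = slope,
                      n_points_used = as.integer(npts[blups$patient_id]),
                      stringsAsFactors = FALSE)
  }
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(patient_id = character(0), slope = numeric(0),
                      n_points_used = integer(0))
  }
  out$method <- method
  out$scale <- scale
  rownames(out) <- NULL
  out[, c("patient_id", "method", "slope", "n_points_used", "scale")]
}

#' Summarise a set of slope estimates
#'
#' Median, interquartile range, and the fraction of "rapid decliners" —
#' patients whose CD4 decline exceeds `threshold` cells/ul per year (slope
#' below `-threshold`).
#'
#' @param estimates data.frame from [estimate_slopes()] (needs `slope`).
#' @param threshold rapid-decline threshold (cells/ul/year, positive).
#' @return list: `method`, `n`, `median`, `iqr` (q1, q3), `prop_rapid`,
#'   `threshold`.
#' @export
summarize_slopes <- function(estimates, threshold = 100) {
  if (nrow(estimates) == 0) stop("no slope estimates to summarise")
  s <- estimates$slope
  q <- unname(quantile(s, c(0.25, 0.5, 0.75)))
  list(method = estimates$method[1] %||% NA_character_, n = length(s),
       median = q[2], iqr = c(q1 = q[1], q3 = q[3]),
       prop_rapid = mean(s < -threshold), threshold = threshold)
}
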