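# Outcome models: stratified Cox proportional hazards with the ART Cohort
# Collaboration predictor set, hazard ratios per +10 cells/ul/year of CD4
# slope, person-year event rates, Harrell c index of 5-year risk
# predictions, and the slope-quartile event table.

CD4_STRATA <- c("<100", "100-<200", "200-<350", ">=350")

cd4_stratum <- function(cd4) {
  cut(cd4, breaks = c(-Inf, 100, 200, 350, Inf), right = FALSE,
      labels = CD4_STRATA)
}

#' Event rate per 100 person-years with a normal-approximation CI
#'
#' `rate = 100 * n_events / person_years`; the 95% CI treats the event count
#' as Poisson and uses the normal approximation
#' `100 * (n +/- 1.96 * sqrt(n)) / person_years`, floored at 0.
#'
#' @param n_events event count.
#' @param person_years total follow-up (years), positive.
#' @return list: `n_events`, `person_years`, `rate_per_100py`, `ci`.
#' @export
event_rate <- function(n_events, person_years) {
  if (person_years <= 0) stop("person_years must be positive")
  if (n_events < 0) stop("n_events must be non-negative")
  rate <- 100 * n_events / person_years
  half <- 1.96 * sqrt(n_events)
  ci <- c(lower = max(0, 100 * (n_events - half) / person_years),
          upper = 100 * (n_events + half) / person_years)
  list(n_events = n_events, person_years = person_years,
       rate_per_100py = rate, ci = ci)
}

#' Assemble per-patient survival records
#'
#' Joins the endpoint, slope estimates and baseline covariates into the flat
#' table the Cox models consume.  Baseline CD4 (and its stratum) is the
#' window value chosen by [apply_eligibility()] for the cART era, or the
#' 1993 baseline CD4 for the pre-cART era.  Age is updated from age at
#' seroconversion to age at the survival baseline.
#'
#' @param cohort an eligible `cd4_cohort`.
#' @param slopes data.frame from [estimate_slopes()].
#' @param endpoint `"aids_or_death"` or `"death"`.
#' @return data.frame with columns `patient_id`, `time`, `event`, `slope`,
#'   `cd4_baseline`, `cd4_stratum`, `idu`, `log10_vl`, `age`, `prior_aids`.
#' @export
make_survival_records <- function(cohort, slopes,
                                  endpoint = c("aids_or_death", "death")) {
  endpoint <- match.arg(endpoint)
  ep <- build_endpoint(cohort, endpoint)
  p <- cohort$patients
  i <- match(ep$patient_id, p$patient_id)
  baseline_date <- if (cohort$era == "cart") p$cart_date[i] else p$baseline_date[i]
  rec <- data.frame(
    patient_id = ep$patient_id, time = ep$time, event = ep$event,
    slope = slopes$slope[match(ep$patient_id, slopes$patient_id)],
    cd4_baseline = p$baseline_cd4[i],
    idu = p$transmission_group[i] == "idu",
    log10_vl = if (cohort$era == "cart") p$log10_vl_at_cart[i] else NA_real_,
    age = p$age_at_baseline[i] + years_between(p$seroconversion_date[i],
                                               baseline_date),
    prior_aids = p$prior_aids[i], stringsAsFactors = FALSE)
  rec$cd4_stratum <- cd4_stratum(rec$cd4_baseline)
  rec[!is.na(rec$slope), , drop = FALSE]
}

#' Stratified Cox model for the effect of CD4 slope on outcome
#'
#' Partial-likelihood fit (Efron ties) with baseline CD4 category and
#' injection-drug-use transmission as strata.  The slope enters per +10
#' cells/ul/year so the reported hazard ratio matches the "per 10 cells/ul
#' per year reduction in decline" convention; covariate adjustment uses the
#' ART-CC predictors measured at baseline.  Monotone-likelihood separation
#' is flagged rather than silently reported.
#'
#' @param records data.frame from [make_survival_records()].
#' @param covariates subset of `c("log10_vl", "age", "prior_aids")` to
#'   adjust for (age enters per 10 years).
#' @param strata `"cd4_idu"` (the primary design) or `"none"`.
#' @param slope_term `"per10"` (continuous, default), `"binary"` (rapid
#'   decline vs not, see [rapid_decline_binary_cox()]) or `"none"`.
#' @param threshold rapid-decline threshold for the binary term.
#' @return class `cd4_cox_fit`: `coefficients` table, `hr_slope_per10`
#'   (point, CI, p; named `hr_slope_binary` meaningfully only for the binary
#'   term), `n`, `n_events`, `n_strata`, `loglik`, `flagged`, and the
#'   underlying `survival::coxph` object.
#' @export
cox_fit_stratified <- function(records,
                               covariates = c("log10_vl", "age", "prior_aids"),
                               strata = c("cd4_idu", "none"),
                               slope_term = c("per10", "binary", "none"),
                               threshold = 100) {
  strata <- match.arg(strata)
  slope_term <- match.arg(slope_term)
  df <- records
  df$slope10 <- df$slope / 10
  df$rapid <- df$slope < -threshold
  df$age10 <- df$age / 10
  rhs <- c(switch(slope_term, per10 = "slope10", binary = "rapid", none = NULL),
           vapply(covariates, function(v) switch(v, age = "age10", v), ""))
  if (length(rhs) == 0) rhs <- "1"  # null model: baseline hazard only
  if (strata == "cd4_idu") rhs <- c(rhs, "strata(cd4_stratum, idu)")
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(rhs, collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron", x = TRUE)
  cf <- summary(fit)$coefficients
  cf_b <- coef(fit)
  flagged <- !is.null(cf_b) &&
    (any(is.na(cf_b)) || any(abs(cf_b) > 10, na.rm = TRUE) ||
       any(cf[, "se(coef)"] > 100, na.rm = TRUE))
  slope_row <- switch(slope_term, per10 = "slope10", binary = "rapidTRUE",
                      none = NA_character_)
  hr <- if (!is.na(slope_row) && slope_row %in% rownames(cf) &&
            !is.na(cf[slope_row, "coef"])) {
    b <- cf[slope_row, "coef"]; se <- cf[slope_row, "se(coef)"]
    c(hr = exp(b), lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se),
      p = 2 * pnorm(-abs(b / se)))
  } else c(hr = NA_real_, lower = NA_real_, upper = NA_real_, p = NA_real_)
  structure(list(coefficients = cf, hr_slope_per10 = hr,
                 slope_term = slope_term,
                 n = nrow(df), n_events = sum(df$event),
                 n_strata = if (strata == "cd4_idu")
                   length(unique(interaction(df$cd4_stratum, df$idu, drop = TRUE)))
                 else 1L,
                 loglik = fit$loglik[length(fit$loglik)],
                 flagged = flagged, strata = strata, model = fit,
                 data = df),
            class = "cd4_cox_fit")
}

#' @export
print.cd4_cox_fit <- function(x, ...) {
  cat(sprintf("stratified Cox model: n = %d, events = %d, strata = %d\n",
              x$n, x$n_events, x$n_strata))
  if (!is.na(x$hr_slope_per10["hr"])) {
    lab <- if (x$slope_term == "binary") "rapid decline (binary)"
           else "+10 cells/ul/yr slope"
    cat(sprintf("  HR for %s: %.3f (95%% CI %.3f-%.3f), p = %.3f\n", lab,
                x$hr_slope_per10["hr"], x$hr_slope_per10["lower"],
                x$hr_slope_per10["upper"], x$hr_slope_per10["p"]))
  }
  if (x$flagged) cat("  [flagged: separation or degenerate covariate]\n")
  invisible(x)
}

#' Rapid-decline binary Cox model
#'
#' The slope dichotomised at `threshold` cells/ul/year of decline (slope
#' below `-threshold` = rapid) replacing the continuous term; otherwise as
#' [cox_fit_stratified()].
#' @inheritParams cox_fit_stratified
#' @return a `cd4_cox_fit` (degenerate dichotomies are flagged).
#' @export
rapid_decline_binary_cox <- function(records,
                                     covariates = c("log10_vl", "age", "prior_aids"),
                                     strata = "cd4_idu", threshold = 100) {
  rapid <- records$slope < -threshold
  if (length(unique(rapid)) < 2) {
    return(structure(list(coefficients = NULL,
                          hr_slope_per10 = c(hr = NA_real_, lower = NA_real_,
                                             upper = NA_real_, p = NA_real_),
                          slope_term = "binary", n = nrow(records),
                          n_events = sum(records$event), n_strata = NA_integer_,
                          loglik = NA_real_, flagged = TRUE, strata = strata,
                          model = NULL, data = records),
                     class = "cd4_cox_fit"))
  }
  cox_fit_stratified(records, covariates, strata, slope_term = "binary",
                     threshold = threshold)
}

#' Harrell c index of risk scores truncated at a horizon
#'
#' A pair (i, j) is comparable if `t_i < t_j`, `t_i <= horizon` and subject i
#' had the event; it is concordant if the score of i (higher = worse)
#' exceeds the score of j.  Score ties count 1/2.
#'
#' @param records data.frame with `time` and `event`.
#' @param risk_scores one score per record, higher = worse prognosis.
#' @param horizon truncation horizon (years).
#' @return list: `c`, `horizon`, `n_comparable_pairs`.
#' @export
concordance_5y <- function(records, risk_scores, horizon = 5) {
  stopifnot(length(risk_scores) == nrow(records), horizon > 0)
  t <- records$time; ev <- records$event; s <- risk_scores
  num <- 0; npairs <- 0
  idx <- which(ev & t <= horizon)
  for (i in idx) {
    j <- t > t[i]
    npairs <- npairs + sum(j)
    num <- num + sum(s[i] > s[j]) + 0.5 * sum(s[i] == s[j])
  }
  if (npairs == 0) stop("no comparable pairs at this horizon")
  list(c = num / npairs, horizon = horizon, n_comparable_pairs = npairs)
}

# Breslow per-stratum baseline cumulative hazard evaluated at `horizon`,
# using uncentred linear predictors
breslow_H0 <- function(time, event, lp, strata_id, horizon) {
  H <- setNames(numeric(0), character(0))
  for (s in unique(strata_id)) {
    in_s <- strata_id == s
    ts <- time[in_s]; es <- event[in_s]; rs <- exp(lp[in_s])
    dtimes <- sort(unique(ts[es & ts <= horizon]))
    h <- 0
    for (d in dtimes) {
      h <- h + sum(es & ts == d) / sum(rs[ts >= d])
    }
    H[as.character(s)] <- h
  }
  H
}

#' Predicted 5-year event probabilities from a stratified Cox fit
#'
#' `1 - exp(-H0_s(horizon) * exp(lp_i))` with `H0_s` the Breslow estimator of
#' the subject's stratum and `lp` the uncentred linear predictor.
#'
#' @param fit a `cd4_cox_fit`.
#' @param records data.frame of subjects to score (defaults to the fitting
#'   data); every subject's stratum must occur in the fitting data.
#' @param horizon prediction horizon (years).
#' @return numeric vector of event probabilities (the c-index risk scores).
#' @export
risk_scores_5y <- function(fit, records = NULL, horizon = 5) {
  stopifnot(inherits(fit, "cd4_cox_fit"))
  if (is.null(fit$model)) stop("degenerate fit carries no predictions")
  train <- fit$data
  if (is.null(records)) records <- train
  df <- records
  df$slope10 <- df$slope / 10
  df$age10 <- df$age / 10
  df$rapid <- df$slope < -100
  sid_train <- if (fit$strata == "cd4_idu")
    as.character(interaction(train$cd4_stratum, train$idu, drop = TRUE))
  else rep("all", nrow(train))
  sid_new <- if (fit$strata == "cd4_idu")
    as.character(interaction(df$cd4_stratum, df$idu))
  else rep("all", nrow(df))
  if (!all(sid_new %in% sid_train)) {
    stop("subject in a stratum absent from the fitting data")
  }
  X_train <- fit$model$x
  beta <- coef(fit$model)
  if (is.null(beta) || ncol(X_train) == 0) {
    lp_train <- rep(0, nrow(train))
    lp_new <- rep(0, nrow(df))
  } else {
    beta[is.na(beta)] <- 0
    lp_train <- drop(X_train %*% beta)
    # rebuild the design for new subjects on the same terms
    mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$model)),
                              data = df)
    keep <- colnames(X_train)
    lp_new <- drop(mm[, keep, drop = FALSE] %*% beta[keep])
  }
  H0 <- breslow_H0(train$time, train$event, lp_train, sid_train, horizon)
  1 - exp(-H0[sid_new] * exp(lp_new))
}

#' Events cross-classified by quartiles of the CD4 slope
#'
#' Quartile cut points are the 25/50/75 empirical percentiles of the slopes
#' of all analysed patients; a slope exactly at a cut point goes to the
#' lower quartile.
#'
#' @param records data.frame with `event` and `slope` (or pass `slopes`).
#' @param slopes optional slope vector overriding `records$slope`.
#' @return list: `events` (length-4 counts summing to the total), `n`
#'   (patients per quartile), `cuts`.
#' @export
quartile_event_table <- function(records, slopes = NULL) {
  s <- slopes %||% records$slope
  if (length(unique(s)) < 4) stop("need at least 4 distinct slope values")
  cuts <- unname(quantile(s, c(0.25, 0.5, 0.75)))
  q <- 1L + (s > cuts[1]) + (s > cuts[2]) + (s > cuts[3])
  ev <- vapply(1:4, function(k) sum(records$event[q == k]), 0L)
  n <- vapply(1:4, function(k) sum(q == k), 0L)
  stopifnot(sum(ev) == sum(records$event))
  list(events = ev, n = n, cuts = cuts)
}
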