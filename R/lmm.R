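# Linear mixed model for CD4 trajectories: patient-specific random intercept
# and random slope for time since seroconversion.  Fitting is delegated to
# lme4; this module fixes the model surface used throughout the pipeline and
# extracts variance components and BLUPs in the units the analysis reports.

#' Fit the random-intercept/random-slope linear mixed model
#'
#' `cd4 ~ time + (time | patient)` on the raw or square-root scale.  When the
#' correlated random-effects fit lands on a singular boundary (|correlation|
#' = 1 or a zero variance), the model is refitted with independent random
#' effects and flagged.
#'
#' @param cohort a `cd4_cohort` or a measurement table (`patient_id`, `time`,
#'   `cd4`).
#' @param scale `"raw"` or `"sqrt"`.
#' @param reml REML (default) or ML; model comparisons need ML.
#' @param correlated allow intercept-slope correlation (default TRUE).
#' @return an object of class `cd4_lmm_fit`: `beta0`, `beta1`, `sd_b0`,
#'   `sd_b1`, `corr_b0b1`, `sd_eps`, `loglik`, `n_params`, and `blups`
#'   (data.frame `patient_id`, `b0`, `b1`, `slope` = beta1 + b1 on the
#'   modelling scale).
#' @export
fit_lmm <- function(cohort, scale = c("raw", "sqrt"), reml = TRUE,
                    correlated = TRUE) {
  scale <- match.arg(scale)
  meas <- if (inherits(cohort, "cd4_cohort")) cohort$measurements else cohort
  if (nrow(meas) < 3 || length(unique(meas$patient_id)) < 2) {
    stop("LMM needs at least two patients with measurements")
  }
  df <- data.frame(id = factor(meas$patient_id), time = meas$time,
                   y = if (scale == "sqrt") sqrt(meas$cd4) else meas$cd4)
  form_corr <- y ~ time + (time | id)
  form_indep <- y ~ time + ((1 | id) + (0 + time | id))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fitted_indep <- !correlated
  mod <- suppressWarnings(suppressMessages(
    lme4::lmer(if (correlated) form_corr else form_indep, data = df,
               REML = reml, control = ctrl)))
  if (correlated && lme4::isSingular(mod, tol = 1e-5)) {
    vc <- as.data.frame(lme4::VarCorr(mod))
    cc <- vc$sdcor[!is.na(vc$var2)]
    if (length(cc) == 1 && abs(cc) > 0.999) {
      mod <- suppressWarnings(suppressMessages(
        lme4::lmer(form_indep, data = df, REML = reml, control = ctrl)))
      fitted_indep <- TRUE
    }
  }
  fe <- lme4::fixef(mod)
  vc <- as.data.frame(lme4::VarCorr(mod))
  sd_b0 <- vc$sdcor[vc$grp != "Residual" & vc$var1 == "(Intercept)" &
                      is.na(vc$var2)][1]
  sd_b1 <- vc$sdcor[vc$grp != "Residual" & vc$var1 == "time" &
                      is.na(vc$var2)][1]
  cc <- vc$sdcor[!is.na(vc$var2)]
  corr <- if (fitted_indep || length(cc) == 0) 0 else cc[1]
  sd_eps <- vc$sdcor[vc$grp == "Residual"][1]
  re <- lme4::ranef(mod)$id
  # independence fit returns two terms; merge them
  if (is.null(re)) {
    res <- lme4::ranef(mod)
    re <- data.frame(`(Intercept)` = res[[1]][, 1], time = res[[2]][, 1],
                     check.names = FALSE, row.names = rownames(res[[1]]))
  }
  if (!"time" %in% names(re)) re$time <- 0
  blups <- data.frame(patient_id = rownames(re),
                      b0 = re[["(Intercept)"]], b1 = re[["time"]],
                      stringsAsFactors = FALSE)
  blups$slope <- unname(fe["time"]) + blups$b1
  structure(list(beta0 = unname(fe["(Intercept)"]), beta1 = unname(fe["time"]),
                 sd_b0 = sd_b0, sd_b1 = sd_b1,
                 corr_b0b1 = if (is.na(corr)) 0 else corr,
                 sd_eps = sd_eps,
                 loglik = as.numeric(logLik(mod)), n_params = if (fitted_indep) 5L else 6L,
                 reml = reml, independent_re = fitted_indep,
                 blups = blups, scale = scale, model = mod,
                 fingerprint = data_fingerprint(df$time, df$y)),
            class = "cd4_lmm_fit")
}

#' @export
print.cd4_lmm_fit <- function(x, ...) {
  cat(sprintf(paste0("linear mixed model (%s scale, %s)\n",
                     "  beta0 = %.2f, beta1 = %.2f\n",
                     "  sd_b0 = %.2f, sd_b1 = %.2f, corr = %.2f, ",
                     "sd_eps = %.2f\n  loglik = %.2f (%d patients)\n"),
              x$scale, if (x$reml) "REML" else "ML", x$beta0, x$beta1,
              x$sd_b0, x$sd_b1, x$corr_b0b1, x$sd_eps, x$loglik,
              nrow(x$blups)))
  invisible(x)
}

#' Compare the linear mixed model and the IOU model by AIC
#'
#' Both fits must be maximum-likelihood fits of the same data on the same
#' (square-root) scale; data fingerprints are checked.  `AIC = 2 k - 2
#' loglik`; the smaller wins.  The models are non-nested in general and the
#' random-slope model sits on the `alpha -> 0` boundary of the IOU family, so
#' AIC rather than a likelihood-ratio test is used.
#'
#' @param lmm_fit a `cd4_lmm_fit` fitted with `reml = FALSE`.
#' @param iou_fit a `cd4_iou_fit` on the same data and scale.
#' @return list: `aic_lmm`, `aic_iou`, `delta_aic` (lmm - iou), `preferred`.
#' @export
compare_models <- function(lmm_fit, iou_fit) {
  stopifnot(inherits(lmm_fit, "cd4_lmm_fit"), inherits(iou_fit, "cd4_iou_fit"))
  if (lmm_fit$reml) stop("model comparison requires an ML (reml = FALSE) LMM fit")
  if (lmm_fit$scale != iou_fit$scale) stop("fits are on different scales")
  if (!isTRUE(all.equal(lmm_fit$fingerprint, iou_fit$fingerprint,
                        tolerance = 1e-6))) {
    stop("fits were computed on different data (fingerprint mismatch)")
  }
  aic_lmm <- 2 * lmm_fit$n_params - 2 * lmm_fit$loglik
  aic_iou <- 2 * iou_fit$n_params - 2 * iou_fit$loglik
  list(aic_lmm = aic_lmm, aic_iou = aic_iou,
       delta_aic = aic_lmm - aic_iou,
       preferred = if (aic_iou < aic_lmm) "iou" else "lmm")
}
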