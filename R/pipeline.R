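# Orchestration: end-to-end reproduction of the analysis on a cohort —
# eligibility, slope estimation, longitudinal fits, stratified outcome
# models with discrimination, and the sensitivity suite.

#' Analysis configuration
#'
#' @param era `"cart"` or `"pre_cart"`.
#' @param endpoint `"aids_or_death"` or `"death"`.
#' @param subgroup `"all"` or `"cd4_gt_350"` (baseline CD4 > 350 cells/ul).
#' @param slope_method,slope_filter,slope_scale passed to
#'   [estimate_slopes()].
#' @param compare_trajectories also fit the IOU model on the square-root
#'   scale and compare it with the linear mixed model by AIC (slower).
#' @param seed integer; expanded into per-stage seeds by a fixed schedule so
#'   stages are individually reproducible.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return a list of class `cd4_analysis_config`.
#' @export
analysis_config <- function(era = c("cart", "pre_cart"),
                            endpoint = c("aids_or_death", "death"),
                            subgroup = c("all", "cd4_gt_350"),
                            slope_method = "blup", slope_filter = "none",
                            slope_scale = "raw",
                            compare_trajectories = FALSE,
                            seed = 1, out_dir = NULL) {
  structure(list(era = match.arg(era), endpoint = match.arg(endpoint),
                 subgroup = match.arg(subgroup),
                 slope_method = slope_method, slope_filter = slope_filter,
                 slope_scale = slope_scale,
                 compare_trajectories = compare_trajectories,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cd4_analysis_config")
}

# fixed hash schedule expanding a global seed into per-stage seeds
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483647)
}

subgroup_filter <- function(cohort, subgroup) {
  if (subgroup == "all") return(cohort)
  p <- cohort$patients
  keep <- !is.na(p$baseline_cd4) & p$baseline_cd4 > 350
  m <- cohort$measurements
  out <- new_cohort(p[keep, , drop = FALSE],
                    m[m$patient_id %in% p$patient_id[keep], , drop = FALSE],
                    era = cohort$era)
  attr(out, "censor_date") <- attr(cohort, "censor_date")
  out
}

# one outcome block: event count/rate, unadjusted + adjusted HR, c indices
outcome_block <- function(records, covariates, endpoint_label) {
  py <- sum(records$time)
  er <- event_rate(sum(records$event), py)
  unadj <- cox_fit_stratified(records, covariates = character(0),
                              strata = "none", slope_term = "per10")
  c_unadj <- concordance_5y(records, -records$slope)$c
  adj <- cox_fit_stratified(records, covariates = covariates,
                            strata = "cd4_idu", slope_term = "per10")
  base <- cox_fit_stratified(records, covariates = covariates,
                             strata = "cd4_idu", slope_term = "none")
  c_with <- concordance_5y(records, risk_scores_5y(adj))$c
  c_without <- concordance_5y(records, risk_scores_5y(base))$c
  list(endpoint = endpoint_label, n = nrow(records),
       n_events = sum(records$event), pct_events = 100 * mean(records$event),
       event_rate = er,
       hr_unadjusted = unadj$hr_slope_per10, c_slope_alone = c_unadj,
       hr_adjusted = adj$hr_slope_per10,
       c_without_slope = c_without, c_with_slope = c_with,
       fits = list(unadjusted = unadj, adjusted = adj, base = base))
}

block_to_row <- function(b) {
  data.frame(endpoint = b$endpoint, n = b$n, n_events = b$n_events,
             pct_events = b$pct_events,
             event_rate = b$event_rate$rate_per_100py,
             rate_lower = b$event_rate$ci["lower"],
             rate_upper = b$event_rate$ci["upper"],
             hr_unadj = b$hr_unadjusted["hr"],
             hr_unadj_lower = b$hr_unadjusted["lower"],
             hr_unadj_upper = b$hr_unadjusted["upper"],
             p_unadj = b$hr_unadjusted["p"],
             c_slope_alone = b$c_slope_alone,
             hr_adj = b$hr_adjusted["hr"],
             hr_adj_lower = b$hr_adjusted["lower"],
             hr_adj_upper = b$hr_adjusted["upper"],
             p_adj = b$hr_adjusted["p"],
             c_without_slope = b$c_without_slope,
             c_with_slope = b$c_with_slope, row.names = NULL)
}

write_manifest <- function(config, counts, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- c(sprintf("package_version\t%s",
                   as.character(utils::packageVersion("cd4slope"))),
           sprintf("seed\t%d", config$seed),
           vapply(names(config), function(k)
             sprintf("config_%s\t%s", k, paste(format(config[[k]]), collapse = ",")),
             ""),
           vapply(names(counts), function(k)
             sprintf("n_%s\t%s", k, counts[[k]]), ""))
  writeLines(man, file.path(out_dir, "manifest.tsv"))
}

#' Run the main cART-era analysis end to end
#'
#' Stages: eligibility filter, slope estimation by all three (or four)
#' methods, the linear mixed model (and optionally the IOU comparison on the
#' square-root scale), and the stratified outcome models for both endpoints
#' with discrimination of 5-year predictions.  Deterministic given the
#' cohort and config.
#'
#' @param cohort a raw `cd4_cohort` (`era = "cart"`), e.g. from
#'   [simulate_cohort()] or [read_cohort()].
#' @param config an [analysis_config()].
#' @return result bundle: `eligibility`, `slope_summaries`, `slopes`,
#'   `lmm`, `trajectory_comparison` (or NULL), `outcomes` (one block per
#'   endpoint), `quartile_events`, `table2` (data.frame analogue of the
#'   outcome table), `counts`.
#' @export
run_main_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  counts <- list(input = nrow(cohort$patients))
  el <- apply_eligibility(cohort)
  elig <- subgroup_filter(el$cohort, config$subgroup)
  counts$eligible <- nrow(el$cohort$patients)
  counts$analysed <- nrow(elig$patients)
  if (counts$analysed == 0) stop("stage eligibility: no patients retained")

  methods <- c("two_point", "ols", "blup")
  slopes <- lapply(setNames(methods, methods), function(m)
    estimate_slopes(elig, method = m, filter = config$slope_filter,
                    scale = config$slope_scale))
  summaries <- lapply(slopes, summarize_slopes)
  counts$with_slope <- nrow(slopes[[config$slope_method]])

  meas <- pre_cart_measurements(elig)
  lmm <- fit_lmm(meas, scale = "sqrt", reml = FALSE)
  comparison <- NULL
  if (isTRUE(config$compare_trajectories)) {
    iou <- fit_iou(meas, scale = "sqrt")
    comparison <- compare_models(lmm, iou)
    comparison$iou_fit <- iou
  }

  use_slopes <- slopes[[config$slope_method]] %||%
    estimate_slopes(elig, method = config$slope_method,
                    filter = config$slope_filter, scale = config$slope_scale)
  blocks <- lapply(c("aids_or_death", "death"), function(epp) {
    rec <- make_survival_records(elig, use_slopes, endpoint = epp)
    outcome_block(rec, covariates = c("log10_vl", "age", "prior_aids"),
                  endpoint_label = epp)
  })
  rec_primary <- make_survival_records(elig, use_slopes, "aids_or_death")
  # slope quartiles are undefined when the mixed model estimates no slope
  # heterogeneity and every BLUP collapses onto the population slope
  qt <- tryCatch(quartile_event_table(rec_primary), error = function(e) NULL)
  table2 <- do.call(rbind, lapply(blocks, block_to_row))
  counts$events_primary <- blocks[[1]]$n_events

  if (!is.null(config$out_dir)) {
    write_manifest(config, counts, config$out_dir)
    write.table(table2, file.path(config$out_dir, "table2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_eligibility_report(el$report, file.path(config$out_dir,
                                                  "eligibility.tsv"))
  }
  list(eligibility = el$report, slope_summaries = summaries, slopes = slopes,
       lmm = lmm, trajectory_comparison = comparison, outcomes = blocks,
       quartile_events = qt, table2 = table2, counts = counts)
}

#' Run the pre-cART-era supplementary analysis
#'
#' 1993 baseline rule, administrative censoring at 1995-12-31, slope from
#' the mixed model on 1989-1993 measurements, Cox adjustment for age with
#' CD4-category and injection-drug-use strata (no viral load: seldom
#' measured in that era), plus the ART-naive sensitivity rerun.
#'
#' @param cohort a `cd4_cohort` with `era = "pre_cart"`.
#' @param config an [analysis_config()] (era `"pre_cart"`).
#' @return bundle: `main` and `sensitivity_art_naive`, each with `records`,
#'   `slope_summary`, `outcomes` (both endpoints), `table` rows.
#' @export
run_pre_cart_analysis <- function(cohort, config = analysis_config(era = "pre_cart")) {
  run_one <- function(exclude_any_art) {
    base <- build_pre_cart_baseline(cohort, exclude_any_art = exclude_any_art)
    base <- subgroup_filter(base, config$subgroup)
    if (nrow(base$patients) == 0) stop("stage pre_cart_baseline: no patients")
    slopes <- estimate_slopes(base, method = config$slope_method,
                              scale = config$slope_scale)
    blocks <- lapply(c("aids_or_death", "death"), function(epp) {
      rec <- make_survival_records(base, slopes, endpoint = epp)
      outcome_block(rec, covariates = c("age", "prior_aids"),
                    endpoint_label = epp)
    })
    list(n = nrow(base$patients), slopes = slopes,
         slope_summary = summarize_slopes(slopes), outcomes = blocks,
         table = do.call(rbind, lapply(blocks, block_to_row)))
  }
  main <- run_one(FALSE)
  sens <- run_one(TRUE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(main$table, file.path(config$out_dir, "table4.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(main = main, sensitivity_art_naive = sens)
}

#' Sensitivity suite over slope-estimation variants
#'
#' Reruns the adjusted primary-endpoint Cox model with slopes from each
#' variant: the three measurement filters, per-patient least squares, and
#' the joint model.  Variant-specific failures are recorded and the suite
#' continues.
#'
#' @param cohort a raw cART-era `cd4_cohort`.
#' @param config an [analysis_config()].
#' @param include_joint include the (slow) joint-model variant.
#' @return data.frame: one row per variant with `variant`, `n`, `hr`,
#'   `lower`, `upper`, `p`, `error`.
#' @export
run_sensitivity_suite <- function(cohort, config = analysis_config(),
                                  include_joint = TRUE) {
  el <- apply_eligibility(cohort)
  elig <- subgroup_filter(el$cohort, config$subgroup)
  variants <- list(
    drop_first_6mo = list(method = "blup", filter = "drop_first_6mo"),
    last_2y_window = list(method = "blup", filter = "last_2y_window"),
    seroconversion_1996_plus = list(method = "blup",
                                    filter = "seroconversion_1996_plus"),
    ols = list(method = "ols", filter = "none"))
  if (include_joint) variants$joint <- list(method = "joint", filter = "none")
  rows <- lapply(names(variants), function(vn) {
    v <- variants[[vn]]
    out <- tryCatch({
      sl <- estimate_slopes(elig, method = v$method, filter = v$filter,
                            scale = config$slope_scale)
      rec <- make_survival_records(elig, sl, endpoint = config$endpoint)
      fit <- cox_fit_stratified(rec, covariates = c("log10_vl", "age",
                                                    "prior_aids"))
      data.frame(variant = vn, n = nrow(rec),
                 hr = fit$hr_slope_per10["hr"],
                 lower = fit$hr_slope_per10["lower"],
                 upper = fit$hr_slope_per10["upper"],
                 p = fit$hr_slope_per10["p"], error = NA_character_,
                 row.names = NULL)
    }, error = function(e) {
      data.frame(variant = vn, n = NA_integer_, hr = NA_real_,
                 lower = NA_real_, upper = NA_real_, p = NA_real_,
                 error = conditionMessage(e), row.names = NULL)
    })
    out
  })
  do.call(rbind, rows)
}
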