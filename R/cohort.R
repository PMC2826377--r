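# Cohort container, CSV readers/writers, seroconversion-date derivation and
# the eligibility / endpoint rules of the cART-era and pre-cART-era analyses.

PATIENT_COLS <- c("patient_id", "sex", "age_at_baseline", "transmission_group",
                  "prior_aids", "last_negative_date", "first_positive_date",
                  "seroconversion_date", "cart_date", "log10_vl_at_cart",
                  "aids_date", "death_date", "last_visit_date")
# optional extra column: art_start_date (any mono/dual/cART start, used by the
# pre-cART-era sensitivity analysis)
MEASUREMENT_COLS <- c("patient_id", "date", "cd4", "log10_vl")

EXCLUSION_REASONS <- c("fewer_than_two_cd4", "missing_cd4_window",
                       "missing_vl_window", "missing_both",
                       "interval_below_3mo")

#' Construct a seroconverter cohort object
#'
#' Bundles a patient table and a long-format CD4 measurement table.  Every
#' measurement must refer to a known patient; measurements are sorted by
#' patient and time.
#'
#' @param patients data.frame with (at least) the columns listed for
#'   `patients.csv` in the package README.
#' @param measurements data.frame with columns `patient_id`, `date` (or
#'   `time`, years since seroconversion), `cd4`, `log10_vl`.
#' @param era `"cart"` (patients initiating combination therapy) or
#'   `"pre_cart"` (untreated-era supplementary design).
#' @return An object of class `cd4_cohort`: a list with elements `patients`,
#'   `measurements`, `era`.
#' @export
new_cohort <- function(patients, measurements, era = c("cart", "pre_cart")) {
  era <- match.arg(era)
  stopifnot(is.data.frame(patients), is.data.frame(measurements))
  if (nrow(measurements) > 0) {
    unknown <- setdiff(unique(measurements$patient_id), patients$patient_id)
    if (length(unknown) > 0) {
      stop("measurements refer to unknown patient_id(s): ",
           paste(head(unknown, 5), collapse = ", "))
    }
    if (is.null(measurements$time)) {
      sc <- patients$seroconversion_date[match(measurements$patient_id,
                                               patients$patient_id)]
      measurements$time <- years_between(sc, measurements$date)
    }
    measurements <- measurements[order(measurements$patient_id,
                                       measurements$time), , drop = FALSE]
    rownames(measurements) <- NULL
  } else if (is.null(measurements$time)) {
    measurements$time <- numeric(0)
  }
  structure(list(patients = patients, measurements = measurements, era = era),
            class = "cd4_cohort")
}

#' @export
print.cd4_cohort <- function(x, ...) {
  cat(sprintf("<cd4_cohort> era=%s: %d patients, %d CD4 measurements\n",
              x$era, nrow(x$patients), nrow(x$measurements)))
  invisible(x)
}

#' Midpoint seroconversion date
#'
#' The seroconversion date of a documented seroconverter is estimated as the
#' midpoint between the last negative and the first positive HIV antibody
#' test.  Test intervals wider than 3 years are rejected: such patients do
#' not qualify as seroconverters.
#'
#' @param last_negative,first_positive Date vectors (or coercible).
#' @param max_interval_years widest admissible test interval (years).
#' @return Date vector of midpoints.
#' @export
derive_seroconversion <- function(last_negative, first_positive,
                                  max_interval_years = 3) {
  ln <- as.Date(last_negative)
  fp <- as.Date(first_positive)
  if (anyNA(ln) || anyNA(fp)) stop("invalid input: missing or unparseable test dates")
  gap <- as.numeric(fp - ln)
  if (any(gap < 0)) stop("invalid input: last negative test after first positive test")
  if (any(gap > max_interval_years * DAYS_PER_YEAR)) {
    stop("interval too wide: last-negative/first-positive interval exceeds ",
         max_interval_years, " years")
  }
  ln + gap / 2
}

# value (CD4 or VL) in [cart - window, cart] closest to cart; ties -> later date
window_value <- function(dates, values, cart_date, window_days) {
  ok <- !is.na(values) & dates >= cart_date - window_days & dates <= cart_date
  if (!any(ok)) return(NULL)
  d <- dates[ok]; v <- values[ok]
  pick <- which(d == max(d))
  pick <- pick[length(pick)]
  list(date = d[pick], value = v[pick])
}

#' Apply the cART-era eligibility rules
#'
#' Retains patients with (a) a CD4 count in the window `[cart - window_days,
#' cart]`, (b) a viral load in the same window, and (c) at least one earlier
#' CD4 count at least `min_gap_days` before the window CD4.  Patients with no
#' recorded cART date are dropped before any accounting.  Exclusion reasons
#' are assigned in a fixed order (fewer than two CD4 counts, then missing
#' window measurements, then insufficient interval) so that each excluded
#' patient is counted under exactly one reason.
#'
#' @param cohort a `cd4_cohort` with `era = "cart"`.
#' @param window_days baseline measurement window before cART (days).
#' @param min_gap_days minimum interval between the window CD4 and an earlier
#'   CD4 (days; 91 d encodes "at least 3 months").
#' @return list with elements `cohort` (eligible subset, with columns
#'   `baseline_cd4` and `baseline_cd4_date` added to the patient table) and
#'   `report` (an `EligibilityReport`: `n_input`, `n_eligible`, `exclusions`).
#' @export
apply_eligibility <- function(cohort, window_days = 91, min_gap_days = 91) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  if (cohort$era != "cart") stop("eligibility rules apply to era = 'cart' cohorts")
  pts <- cohort$patients
  pts <- pts[!is.na(pts$cart_date), , drop = FALSE]
  n_input <- nrow(pts)
  excl <- setNames(integer(length(EXCLUSION_REASONS)), EXCLUSION_REASONS)
  keep <- logical(n_input)
  baseline_cd4 <- rep(NA_real_, n_input)
  baseline_date <- rep(as.Date(NA), n_input)
  meas <- cohort$measurements
  split_meas <- split(seq_len(nrow(meas)), meas$patient_id)

  for (i in seq_len(n_input)) {
    p <- pts[i, ]
    idx <- split_meas[[as.character(p$patient_id)]]
    m <- meas[idx, , drop = FALSE]
    m <- m[!is.na(m$cd4) & m$date <= p$cart_date, , drop = FALSE]
    if (nrow(m) < 2) { excl["fewer_than_two_cd4"] <- excl["fewer_than_two_cd4"] + 1L; next }
    wcd4 <- window_value(m$date, m$cd4, p$cart_date, window_days)
    # a VL reported with the patient record counts as measured at cART
    have_vl <- !is.na(p$log10_vl_at_cart) ||
      !is.null(window_value(meas$date[idx], meas$log10_vl[idx], p$cart_date, window_days))
    if (is.null(wcd4) && !have_vl) { excl["missing_both"] <- excl["missing_both"] + 1L; next }
    if (is.null(wcd4)) { excl["missing_cd4_window"] <- excl["missing_cd4_window"] + 1L; next }
    if (!have_vl) { excl["missing_vl_window"] <- excl["missing_vl_window"] + 1L; next }
    if (!any(m$date <= wcd4$date - min_gap_days)) {
      excl["interval_below_3mo"] <- excl["interval_below_3mo"] + 1L; next
    }
    keep[i] <- TRUE
    baseline_cd4[i] <- wcd4$value
    baseline_date[i] <- wcd4$date
  }

  pts$baseline_cd4 <- baseline_cd4
  pts$baseline_cd4_date <- baseline_date
  elig <- pts[keep, , drop = FALSE]
  meas_keep <- meas[meas$patient_id %in% elig$patient_id, , drop = FALSE]
  out <- new_cohort(elig, meas_keep, era = "cart")
  report <- structure(list(n_input = n_input, n_eligible = nrow(elig),
                           exclusions = excl),
                      class = "cd4_eligibility_report")
  stopifnot(report$n_input == report$n_eligible + sum(report$exclusions))
  list(cohort = out, report = report)
}

#' @export
print.cd4_eligibility_report <- function(x, ...) {
  cat(sprintf("eligibility: %d of %d patients retained\n", x$n_eligible, x$n_input))
  for (r in names(x$exclusions)) {
    if (x$exclusions[[r]] > 0) cat(sprintf("  excluded %-22s %d\n", r, x$exclusions[[r]]))
  }
  invisible(x)
}

#' Write an eligibility report as a two-column TSV
#' @param report an object from [apply_eligibility()].
#' @param path output file.
#' @export
write_eligibility_report <- function(report, path) {
  df <- data.frame(reason = c("n_input", "n_eligible", names(report$exclusions)),
                   count = c(report$n_input, report$n_eligible,
                             unname(report$exclusions)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the time-to-event endpoint
#'
#' For a cART-era cohort, time runs from cART initiation to the first new
#' AIDS event or death (`aids_or_death`) or to death only (`death`);
#' event-free patients are censored at their last clinic visit.  For a
#' pre-cART-era cohort (from [build_pre_cart_baseline()]), time runs from the
#' 1993 baseline with administrative censoring at the cohort's censor date.
#'
#' @param cohort a `cd4_cohort` (eligible subset for the cART era).
#' @param endpoint `"aids_or_death"` or `"death"`.
#' @return data.frame `patient_id`, `time` (years, strictly positive),
#'   `event` (logical).
#' @export
build_endpoint <- function(cohort, endpoint = c("aids_or_death", "death")) {
  endpoint <- match.arg(endpoint)
  p <- cohort$patients
  origin <- if (cohort$era == "cart") p$cart_date else p$baseline_date
  if (any(is.na(origin))) stop("endpoint origin date missing for some patients")
  event_date <- if (endpoint == "aids_or_death") {
    pmin(p$aids_date, p$death_date, na.rm = TRUE)
  } else {
    p$death_date
  }
  censor_date <- p$last_visit_date
  if (cohort$era == "pre_cart") {
    admin <- attr(cohort, "censor_date") %||% as.Date("1995-12-31")
    censor_date <- pmin(censor_date, admin)
    event_date[!is.na(event_date) & event_date > censor_date] <- NA
  }
  bad <- !is.na(event_date) & event_date <= origin
  if (any(bad)) {
    stop("invalid record: endpoint event on or before origin for patient(s) ",
         paste(head(p$patient_id[bad], 5), collapse = ", "))
  }
  end <- pmin(event_date, censor_date, na.rm = TRUE)
  event <- !is.na(event_date) & event_date <= censor_date
  time <- years_between(origin, end)
  if (any(time <= 0)) stop("invalid record: non-positive follow-up time")
  data.frame(patient_id = p$patient_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Construct the pre-cART-era supplementary study population
#'
#' Baseline is each patient's last recorded CD4 count in `baseline_year`;
#' retained patients must have at least one earlier CD4 count inside
#' `slope_window` and no AIDS event before baseline.  Follow-up is
#' administratively censored at `censor_date`.  With `exclude_any_art`,
#' patients on any antiretroviral therapy by the end of `baseline_year` are
#' dropped and follow-up is censored at therapy start if therapy began before
#' the censor date.
#'
#' @param cohort a `cd4_cohort` with `era = "pre_cart"`.
#' @param baseline_year calendar year whose last CD4 defines baseline.
#' @param slope_window two calendar years bounding the measurements used for
#'   slope estimation.
#' @param censor_date administrative censoring date.
#' @param exclude_any_art logical; the ART-naive sensitivity analysis.
#' @return a `cd4_cohort` restricted to the study population, whose patient
#'   table gains `baseline_date` and `baseline_cd4`, and whose measurements
#'   are restricted to the slope window up to baseline.  Patients without a
#'   qualifying baseline are silently excluded (by definition of the design).
#' @export
build_pre_cart_baseline <- function(cohort, baseline_year = 1993,
                                    slope_window = c(1989, 1993),
                                    censor_date = as.Date("1995-12-31"),
                                    exclude_any_art = FALSE) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  if (cohort$era != "pre_cart") stop("expected a pre_cart-era cohort")
  censor_date <- as.Date(censor_date)
  p <- cohort$patients
  meas <- cohort$measurements
  meas <- meas[!is.na(meas$cd4), , drop = FALSE]
  yr <- as.integer(format(meas$date, "%Y"))

  baseline_date <- rep(as.Date(NA), nrow(p))
  baseline_cd4 <- rep(NA_real_, nrow(p))
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    mi <- meas[meas$patient_id == p$patient_id[i], , drop = FALSE]
    yi <- as.integer(format(mi$date, "%Y"))
    in93 <- which(yi == baseline_year)
    if (length(in93) == 0) next
    bidx <- in93[which.max(mi$date[in93])]
    bdate <- mi$date[bidx]
    prior <- mi$date < bdate & yi >= slope_window[1] & yi <= slope_window[2]
    if (!any(prior)) next
    if (!is.na(p$aids_date[i]) && p$aids_date[i] <= bdate) next  # prior AIDS
    keep[i] <- TRUE
    baseline_date[i] <- bdate
    baseline_cd4[i] <- mi$cd4[bidx]
  }
  p$baseline_date <- baseline_date
  p$baseline_cd4 <- baseline_cd4
  p <- p[keep, , drop = FALSE]

  if (exclude_any_art) {
    art <- p$art_start_date %||% rep(as.Date(NA), nrow(p))
    on_art_by_baseline <- !is.na(art) &
      as.integer(format(art, "%Y")) <= baseline_year
    p <- p[!on_art_by_baseline, , drop = FALSE]
    art <- p$art_start_date %||% rep(as.Date(NA), nrow(p))
    # censor at later therapy start (1994-95)
    later <- !is.na(art) & art > p$baseline_date
    p$last_visit_date[later] <- pmin(p$last_visit_date[later], art[later])
    drop_ev <- function(d) { d[later & !is.na(d) & d > p$last_visit_date] <- NA; d }
    p$aids_date <- drop_ev(p$aids_date)
    p$death_date <- drop_ev(p$death_date)
  }

  keep_meas <- meas$patient_id %in% p$patient_id &
    yr >= slope_window[1] &
    meas$date <= p$baseline_date[match(meas$patient_id, p$patient_id)]
  keep_meas[is.na(keep_meas)] <- FALSE
  out <- new_cohort(p, meas[keep_meas, , drop = FALSE], era = "pre_cart")
  attr(out, "censor_date") <- censor_date
  out
}

parse_dates <- function(x, col, file) {
  x[x %in% c("", "NA")] <- NA
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad) > 0) {
    stop(sprintf("unparseable date in column '%s' of %s at row %d: '%s'",
                 col, file, bad[1], x[bad[1]]))
  }
  d
}

#' Read a cohort from CSV files
#'
#' `patients.csv` and `measurements.csv` follow the schemas documented in the
#' README (ISO-8601 dates; empty fields are absent values).  Unknown columns
#' raise a warning; missing mandatory columns, unparseable dates and negative
#' CD4 counts are hard errors that name the offending row.
#'
#' @param patient_path,measurement_path CSV file paths.
#' @param era cohort era, `"cart"` or `"pre_cart"`.
#' @return a `cd4_cohort`.
#' @export
read_cohort <- function(patient_path, measurement_path, era = "cart") {
  pat <- read.csv(patient_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  miss <- setdiff(PATIENT_COLS, names(pat))
  if (length(miss) > 0) stop("patients file missing mandatory column(s): ",
                             paste(miss, collapse = ", "))
  extra <- setdiff(names(pat), c(PATIENT_COLS, "art_start_date"))
  if (length(extra) > 0) warning("unknown patient column(s) ignored: ",
                                 paste(extra, collapse = ", "))
  for (col in grep("_date$", names(pat), value = TRUE)) {
    pat[[col]] <- parse_dates(pat[[col]], col, patient_path)
  }
  pat$age_at_baseline <- as.numeric(pat$age_at_baseline)
  pat$log10_vl_at_cart <- suppressWarnings(as.numeric(pat$log10_vl_at_cart))
  pat$prior_aids <- as.logical(pat$prior_aids)

  mea <- read.csv(measurement_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(mea) == 0) {
    mea <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                      cd4 = numeric(0), log10_vl = numeric(0))
  } else {
    miss <- setdiff(MEASUREMENT_COLS, names(mea))
    if (length(miss) > 0) stop("measurements file missing mandatory column(s): ",
                               paste(miss, collapse = ", "))
    extra <- setdiff(names(mea), MEASUREMENT_COLS)
    if (length(extra) > 0) warning("unknown measurement column(s) ignored: ",
                                   paste(extra, collapse = ", "))
    mea$date <- parse_dates(mea$date, "date", measurement_path)
    mea$cd4 <- suppressWarnings(as.numeric(mea$cd4))
    mea$log10_vl <- suppressWarnings(as.numeric(mea$log10_vl))
    neg <- which(!is.na(mea$cd4) & mea$cd4 < 0)
    if (length(neg) > 0) stop(sprintf("negative CD4 in %s at row %d",
                                      measurement_path, neg[1]))
  }
  new_cohort(pat, mea[, intersect(MEASUREMENT_COLS, names(mea))], era = era)
}

#' Write a cohort to a directory as patients.csv and measurements.csv
#' @param cohort a `cd4_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- intersect(c(PATIENT_COLS, "art_start_date"), names(cohort$patients))
  write.csv(cohort$patients[, keep],
            file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  write.csv(cohort$measurements[, MEASUREMENT_COLS],
            file.path(dir, "measurements.csv"), row.names = FALSE, na = "")
  invisible(dir)
}
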