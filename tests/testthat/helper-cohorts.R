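# Shared fixtures: tiny hand-built cohorts and exact-grid trajectory panels.

# a minimal patient row with sensible defaults, overridable per field
patient_row <- function(patient_id = "P1", sex = "male",
                        age_at_baseline = 35, transmission_group = "msm",
                        prior_aids = FALSE,
                        last_negative_date = as.Date("1999-01-01"),
                        first_positive_date = as.Date("1999-12-31"),
                        seroconversion_date = as.Date("1999-07-02"),
                        cart_date = as.Date(NA), log10_vl_at_cart = NA_real_,
                        aids_date = as.Date(NA), death_date = as.Date(NA),
                        last_visit_date = as.Date("2006-01-01"),
                        art_start_date = as.Date(NA)) {
  data.frame(patient_id = patient_id, sex = sex,
             age_at_baseline = age_at_baseline,
             transmission_group = transmission_group,
             prior_aids = prior_aids,
             last_negative_date = last_negative_date,
             first_positive_date = first_positive_date,
             seroconversion_date = seroconversion_date,
             cart_date = cart_date, log10_vl_at_cart = log10_vl_at_cart,
             aids_date = aids_date, death_date = death_date,
             last_visit_date = last_visit_date,
             art_start_date = art_start_date, stringsAsFactors = FALSE)
}

meas_rows <- function(patient_id, dates, cd4, log10_vl = NA_real_) {
  data.frame(patient_id = patient_id, date = as.Date(dates), cd4 = cd4,
             log10_vl = log10_vl, stringsAsFactors = FALSE)
}

# balanced panel on an exact shared time grid, drawn from the package's
# trajectory processes; returns a measurement table usable by the fitters
make_panel <- function(n, times, trajectory = c("linear", "iou"),
                       beta0 = 620, beta1 = -60, sd_b0 = 150, sd_b1 = 25,
                       alpha = 20, tau = 60, sd_eps = 80, seed = 1) {
  trajectory <- match.arg(trajectory)
  cfg <- cd4slope::simulation_config(
    n_patients = n, seed = seed, trajectory = trajectory,
    beta0 = beta0, beta1 = beta1, sd_b0 = sd_b0, sd_b1 = sd_b1,
    alpha = max(alpha, 1e-6), tau = tau, sd_eps = sd_eps)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b0 <- rnorm(1, 0, sd_b0)
    latent <- if (trajectory == "linear") {
      cd4slope::draw_trajectory_linear(times, b0, rnorm(1, 0, sd_b1), cfg)
    } else {
      cd4slope::draw_trajectory_iou(times, b0, cfg)
    }
    out[[i]] <- data.frame(patient_id = sprintf("S%04d", i), time = times,
                           cd4 = pmax(0, latent + rnorm(length(times), 0, sd_eps)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
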