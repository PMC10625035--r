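# Small hand-made parameter bundle for fast, exactly-checkable tests.
tiny_params <- function(discount_rate = 0, horizon = 5) {
  cost_parameters(
    tibble::tribble(
      ~event,             ~annual_rate, ~los_mean, ~los_sd, ~direct_mean, ~direct_sd, ~indirect_mean, ~indirect_sd,
      "ppm_implant",      NA_real_,     10,        2,       1000,         100,        100,            10,
      "generator_change", 0.5,          1,         0.5,     200,          20,         20,             2,
      "clinic_visit",     2,            0.125,     0,       50,           0,          10,             0
    ),
    discount_rate = discount_rate, horizon = horizon
  )
}

zero_rate_params <- function(implant_direct = 108052, horizon = 20) {
  p <- ppm_cost_parameters(horizon = horizon)
  p$annual_rate[p$kind != "implant"] <- 0
  p$direct_mean[p$event == "ppm_implant"] <- implant_direct
  p
}

# one event-table row
ev_row <- function(patient_id, event, day, age = 1, los = 0,
                   direct = 0, indirect = 0) {
  tibble::tibble(patient_id = patient_id, event = event,
                 age_at_event = age, days_since_implant = day,
                 los = los, direct_charge = direct,
                 indirect_cost = indirect)
}

# a minimal valid patient: surgery followed by implantation, plus a
# follow-up marker event fixing the observed follow-up length
basic_patient <- function(id, implant_age = 1, chs_delay = 10,
                          followup_days = 2 * 365.25, extra = NULL) {
  rows <- dplyr::bind_rows(
    ev_row(id, "chs", -chs_delay, age = implant_age - chs_delay / 365.25),
    ev_row(id, "ppm_implant", 0, age = implant_age, los = 5,
           direct = 1000, indirect = 100),
    ev_row(id, "clinic_visit", followup_days, age = implant_age +
             followup_days / 365.25, los = 0.125, direct = 50,
           indirect = 10)
  )
  if (!is.null(extra)) rows <- dplyr::bind_rows(rows, extra)
  rows
}
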