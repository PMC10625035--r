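#' Configure the synthetic event-history generator
#'
#' The generator emulates an institutional cardiology database: every
#' patient undergoes congenital heart surgery (CHS), receives a permanent
#' pacemaker within `chs_delay_max` days, and is then followed for up to
#' `horizon` years. In each follow-up year every major complication
#' occurs as an independent Bernoulli draw at its annual probability and
#' every minor monitoring event count is Poisson with its annual
#' frequency as mean; within-year event times are uniform. Lengths of
#' stay are drawn from moment-matched gamma distributions (deterministic
#' when the SD is zero, as for clinic-type events).
#'
#' Billing is modelled per event type as
#' `direct_charge = slope * LOS + noise`, with `slope` and the noise SD
#' calibrated so that (i) the expected charge equals the bundle's
#' `direct_mean`, (ii) the charge SD equals `direct_sd`, and (iii) the
#' population R-squared of charge on LOS equals the target in
#' `r2_targets`. The default noise family is a moment-matched gamma
#' (mean = regression intercept), which keeps charges non-negative and
#' right-skewed, as hospital charges are; `noise_family = "gaussian"`
#' uses additive normal noise clipped at zero (clips are counted and
#' more than 5% of them triggers a warning). Indirect (family
#' out-of-pocket) cost is deterministic per event:
#' `indirect_mean + per_day * (LOS - los_mean)`, i.e. a per-day cost
#' anchored so its expectation matches the bundle.
#'
#' @param params A [cost_parameters] bundle supplying rates, LOS and cost
#'   summaries. Defaults to [ppm_cost_parameters()].
#' @param n_patients Number of patients to simulate.
#' @param horizon Follow-up horizon in whole years.
#' @param r2_targets Named vector of target R-squared values of direct
#'   charge on LOS, per event type. Events not named get slope 0 (charge
#'   independent of LOS).
#' @param noise_family `"gamma"` (default) or `"gaussian"` charge noise.
#' @param indirect_per_day Indirect cost per hospital day (USD/day).
#' @param censoring `"none"` (all patients followed for the full horizon)
#'   or `"exponential"` follow-up censoring with mean `censor_mean`.
#' @param censor_mean Mean follow-up (years) under exponential censoring.
#' @param implant_age_max Implantation ages are uniform on
#'   `[0, implant_age_max)` years.
#' @param chs_delay_max Implantation occurs 0..`chs_delay_max` days
#'   (uniform integer) after the index surgery.
#' @param icd_fraction Fraction of patients given a cardioverter-
#'   defibrillator record (used to exercise cohort exclusion rules).
#' @param seed Integer seed; equal seeds give byte-identical output.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(params = ppm_cost_parameters(),
                             n_patients = 1000,
                             horizon = horizon_of(params),
                             r2_targets = c(ppm_implant = 0.838,
                                            malfunction_replacement = 0.23,
                                            generator_change = 0.007,
                                            infection = 0.864),
                             noise_family = c("gamma", "gaussian"),
                             indirect_per_day = (578 - 136) / 0.875,
                             censoring = c("none", "exponential"),
                             censor_mean = NULL,
                             implant_age_max = 4,
                             chs_delay_max = 30,
                             icd_fraction = 0,
                             seed = 1L) {
  stopifnot(inherits(params, "cost_parameters"))
  noise_family <- match.arg(noise_family)
  censoring <- match.arg(censoring)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("generator_config: n_patients must be a positive count")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1) {
    abort("generator_config: horizon must be >= 1 year")
  }
  if (censoring == "exponential" &&
      (is.null(censor_mean) || censor_mean <= 0)) {
    abort("generator_config: exponential censoring needs a positive censor_mean")
  }
  if (indirect_per_day < 0) abort("generator_config: indirect_per_day must be >= 0")

  billing <- tibble::as_tibble(params)
  r2 <- unname(r2_targets[billing$event])
  r2[is.na(r2)] <- 0
  r2[billing$los_sd == 0 | billing$direct_sd == 0] <- 0
  slope <- ifelse(r2 > 0, billing$direct_sd * sqrt(r2) / billing$los_sd, 0)
  intercept <- billing$direct_mean - slope * billing$los_mean
  noise_sd <- billing$direct_sd * sqrt(1 - r2)
  billing <- tibble::tibble(
    event = billing$event,
    los_mean = billing$los_mean,
    los_sd = billing$los_sd,
    slope = slope,
    intercept = intercept,
    noise_sd = noise_sd,
    ind_intercept = billing$indirect_mean - indirect_per_day * billing$los_mean
  )

  structure(
    list(params = params, n_patients = as.integer(n_patients),
         horizon = as.integer(horizon), r2_targets = r2_targets,
         noise_family = noise_family, indirect_per_day = indirect_per_day,
         billing = billing, censoring = censoring, censor_mean = censor_mean,
         implant_age_max = implant_age_max,
         chs_delay_max = as.integer(chs_delay_max),
         icd_fraction = icd_fraction, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# gamma draws with given mean/SD; degenerate at the mean when sd == 0
rgamma_ms <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Generate patient event histories
#'
#' Produces one row per hospital event: the index surgery (`chs`), the
#' pacemaker implantation at day 0, and per-year complication and
#' monitoring events through the horizon or the patient's censoring
#' time, whichever is earlier. Lengths of stay are filled; charges are
#' `NA` until [generate_billing()] is applied (or use
#' [generate_events()] for both in one call).
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `patient_id`, `event`, `age_at_event`
#'   (years), `days_since_implant`, `los` (days), `direct_charge`,
#'   `indirect_cost` (2018 USD).
#' @export
generate_patient_histories <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_histories_impl(config))
}

generate_histories_impl <- function(config) {
  n <- config$n_patients
  H <- config$horizon
  params <- config$params
  pid <- sprintf("P%06d", seq_len(n))

  implant_age <- runif(n, 0, config$implant_age_max)
  delay <- sample.int(config$chs_delay_max + 1L, n, replace = TRUE) - 1L
  imp <- param_row(params, "ppm_implant")
  implant_los <- rgamma_ms(n, imp$los_mean, imp$los_sd)
  censor <- switch(config$censoring,
                   none = rep(Inf, n),
                   exponential = rexp(n, rate = 1 / config$censor_mean))
  icd <- if (config$icd_fraction > 0) runif(n) < config$icd_fraction else rep(FALSE, n)
  icd_day <- if (any(icd)) runif(n, 0, H) * DAYS_PER_YEAR else numeric(n)

  pieces <- list(
    tibble::tibble(idx = seq_len(n), event = "chs",
                   day = -as.numeric(delay), los = 0),
    tibble::tibble(idx = seq_len(n), event = "ppm_implant",
                   day = 0, los = implant_los)
  )
  if (any(icd)) {
    w <- which(icd)
    pieces <- c(pieces, list(tibble::tibble(idx = w, event = "icd_implant",
                                            day = icd_day[w], los = 1)))
  }

  rated <- rated_rows(params)
  for (j in seq_len(nrow(rated))) {
    ev <- rated$event[j]
    rate <- rated$annual_rate[j]
    if (is.na(rate) || rate == 0) next
    if (rated$kind[j] == "major") {
      occ <- rbinom(n * H, 1L, rate)
      hit <- which(occ == 1L)
      i <- ((hit - 1L) %% n) + 1L
      t <- ((hit - 1L) %/% n) + 1L
    } else {
      cnt <- rpois(n * H, rate)
      hit <- rep(seq_along(cnt), cnt)
      i <- ((hit - 1L) %% n) + 1L
      t <- ((hit - 1L) %/% n) + 1L
    }
    k <- length(i)
    if (k == 0) next
    day <- (t - 1 + runif(k)) * DAYS_PER_YEAR
    los <- rgamma_ms(k, rated$los_mean[j], rated$los_sd[j])
    pieces <- c(pieces, list(tibble::tibble(idx = i, event = ev,
                                            day = day, los = los)))
  }

  out <- dplyr::bind_rows(pieces)
  keep <- out$event %in% c("chs", "ppm_implant", "icd_implant") |
    out$day / DAYS_PER_YEAR <= censor[out$idx]
  out <- out[keep, , drop = FALSE]

  out |>
    dplyr::mutate(
      patient_id = pid[.data$idx],
      age_at_event = implant_age[.data$idx] + .data$day / DAYS_PER_YEAR,
      days_since_implant = .data$day,
      direct_charge = NA_real_,
      indirect_cost = NA_real_
    ) |>
    dplyr::arrange(.data$patient_id, .data$days_since_implant, .data$event) |>
    dplyr::select("patient_id", "event", "age_at_event",
                  "days_since_implant", "los", "direct_charge",
                  "indirect_cost")
}

#' Fill billing charges on an event table
#'
#' Applies the charge model in `config` (see [generator_config()]) to
#' every pacemaker-related event row: direct charge as a linear function
#' of LOS plus calibrated noise, indirect cost as a deterministic
#' per-day model anchored at the event's mean. `chs` and `icd_implant`
#' rows are carried at zero cost (they are outside the pacing cost
#' perspective). Under the Gaussian noise family, negative charges are
#' clipped to zero; the clipped fraction is attached as attribute
#' `clipped_fraction` and a warning is raised when it exceeds 5%.
#'
#' @param events Event table from [generate_patient_histories()].
#' @param config A [generator_config()].
#' @return The event table with `direct_charge` and `indirect_cost`
#'   filled.
#' @export
generate_billing <- function(events, config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(is.na(events$los))) abort("generate_billing: events must have LOS assigned")
  withr::with_seed(config$seed + 7919L, generate_billing_impl(events, config))
}

generate_billing_impl <- function(events, config) {
  events <- tibble::as_tibble(events)
  direct <- numeric(nrow(events))
  indirect <- numeric(nrow(events))
  n_clipped <- 0L
  n_priced <- 0L

  for (j in seq_len(nrow(config$billing))) {
    b <- config$billing[j, ]
    idx <- which(events$event == b$event)
    if (length(idx) == 0) next
    los <- events$los[idx]
    k <- length(idx)
    n_priced <- n_priced + k
    if (b$noise_sd == 0) {
      charge <- b$intercept + b$slope * los
    } else if (config$noise_family == "gamma" && b$intercept > 0) {
      charge <- b$slope * los + rgamma_ms(k, b$intercept, b$noise_sd)
    } else {
      charge <- b$intercept + b$slope * los + rnorm(k, 0, b$noise_sd)
    }
    clip <- charge < 0
    n_clipped <- n_clipped + sum(clip)
    charge[clip] <- 0
    direct[idx] <- charge
    indirect[idx] <- pmax(0, b$ind_intercept + config$indirect_per_day * los)
  }

  if (n_priced > 0 && n_clipped / n_priced > 0.05) {
    warn(sprintf("generate_billing: %.1f%% of charges clipped at zero",
                 100 * n_clipped / n_priced))
  }
  events$direct_charge <- direct
  events$indirect_cost <- indirect
  attr(events, "clipped_fraction") <- if (n_priced > 0) n_clipped / n_priced else 0
  events
}

#' Generate a complete synthetic event table
#'
#' Convenience wrapper: [generate_patient_histories()] followed by
#' [generate_billing()].
#'
#' @inheritParams generate_patient_histories
#' @return A fully priced event tibble.
#' @export
generate_events <- function(config) {
  generate_billing(generate_patient_histories(config), config)
}

#' Generate a yearly surgical-volume series
#'
#' Counts grow geometrically: the expected count in year `t` (0-based)
#' is `start_count * (1 + cagr)^t`, with optional mean-one multiplicative
#' log-normal noise of the given log-scale SD.
#'
#' @param start_count Expected count in the first year (> 0).
#' @param cagr Compound annual growth rate (fraction per year, > -1).
#' @param years Number of years in the series (>= 2).
#' @param noise_sd Log-scale SD of the multiplicative noise (0 = exact).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param start_year First calendar year.
#' @return A tibble with columns `year` and `count` (real-valued; exact
#'   geometric when `noise_sd = 0`).
#' @export
generate_surgery_volume <- function(start_count, cagr, years,
                                    noise_sd = 0, seed = 1L,
                                    start_year = 1960L) {
  if (start_count <= 0) abort("generate_surgery_volume: start_count must be > 0")
  if (years < 2) abort("generate_surgery_volume: years must be >= 2")
  if (cagr <= -1) abort("generate_surgery_volume: cagr must be > -1")
  t <- 0:(years - 1)
  mu <- start_count * (1 + cagr)^t
  count <- if (noise_sd > 0) {
    withr::with_seed(seed, mu * exp(rnorm(years, -noise_sd^2 / 2, noise_sd)))
  } else {
    mu
  }
  tibble::tibble(year = start_year + t, count = count)
}

#' Generate a full surgical-volume table
#'
#' Emulates the volume history of a single pediatric cardiac surgery
#' center over 1960-2018: congenital heart surgeries split by patient
#' age (under 4 vs 4 and older, log-linear yearly growth 0.027 and
#' 0.015), postoperative pacemaker implantations from 1963 at 7.2%
#' compound growth, and a surgeon roster growing from 1 to 10. Start
#' levels are set so the period totals are on the order of 4e4
#' surgeries and 1e3 postoperative implantations. Counts are rounded to
#' integers.
#'
#' @param start_year,end_year Calendar span of the series.
#' @param u4_start,f4_start Expected first-year surgery counts for the
#'   under-4 and 4-plus groups.
#' @param u4_growth,f4_growth Yearly log-linear growth rates (the GLM
#'   slope scale, i.e. expected counts grow by `exp(growth)` per year).
#' @param ppm_start_year,ppm_start,ppm_cagr Pacemaker series start year,
#'   level, and compound annual growth rate.
#' @param surgeons_start,surgeons_end Roster size at the endpoints
#'   (deterministic geometric interpolation).
#' @param noise_sd Log-scale SD of multiplicative count noise.
#' @param seed Integer seed.
#' @return A tibble with columns `year`, `n_chs_under4`, `n_chs_4plus`,
#'   `n_ppm_postop`, `n_surgeons`.
#' @export
generate_volume_series <- function(start_year = 1960L, end_year = 2018L,
                                   u4_start = 190, f4_start = 120,
                                   u4_growth = 0.027, f4_growth = 0.015,
                                   ppm_start_year = 1963L, ppm_start = 1.5,
                                   ppm_cagr = 0.072,
                                   surgeons_start = 1, surgeons_end = 10,
                                   noise_sd = 0.05, seed = 1L) {
  if (end_year <= start_year) abort("generate_volume_series: end_year must be after start_year")
  years <- end_year - start_year + 1L
  u4 <- generate_surgery_volume(u4_start, exp(u4_growth) - 1, years,
                                noise_sd, seed, start_year)
  f4 <- generate_surgery_volume(f4_start, exp(f4_growth) - 1, years,
                                noise_sd, seed + 1L, start_year)
  ppm_years <- end_year - ppm_start_year + 1L
  ppm <- generate_surgery_volume(ppm_start, ppm_cagr, ppm_years,
                                 noise_sd, seed + 2L, ppm_start_year)
  ppm_full <- rep(0, years)
  ppm_full[match(ppm$year, u4$year)] <- ppm$count
  t <- 0:(years - 1)
  surgeons <- surgeons_start * (surgeons_end / surgeons_start)^(t / (years - 1))
  tibble::tibble(
    year = u4$year,
    n_chs_under4 = round(u4$count),
    n_chs_4plus = round(f4$count),
    n_ppm_postop = round(ppm_full),
    n_surgeons = round(surgeons)
  )
}
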