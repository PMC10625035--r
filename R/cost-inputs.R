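#' Select the study cohort from an event table
#'
#' Applies the inclusion rules for the postoperative-pacemaker costing
#' cohort: the pacemaker implantation must fall within `window` days
#' after a congenital heart surgery (inclusive), the patient must be
#' younger than `max_age` years at implantation (strict), the last
#' recorded event must be at least `min_followup` years after the
#' implant, and patients with any cardioverter-defibrillator record are
#' removed entirely. Patients with a `ppm_implant` but no `chs` record
#' are excluded with a message rather than an error. The operation is
#' idempotent.
#'
#' @param events Event table (see [generate_patient_histories()] for the
#'   schema).
#' @param window Maximum days between surgery and implantation (default
#'   30, inclusive).
#' @param max_age Maximum implantation age in years (strict, default 4).
#' @param min_followup Minimum follow-up in years (default 0.5).
#' @return The rows of `events` belonging to retained patients.
#' @export
select_study_cohort <- function(events, window = 30, max_age = 4,
                                min_followup = 0.5) {
  events <- tibble::as_tibble(events)
  per_patient <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_implant = any(.data$event == "ppm_implant"),
      implant_age = .data$age_at_event[.data$event == "ppm_implant"][1],
      has_icd = any(.data$event == "icd_implant"),
      # chs rows sit at negative days_since_implant: delay = -days
      chs_delay = if (any(.data$event == "chs")) {
        min(-.data$days_since_implant[.data$event == "chs"])
      } else {
        NA_real_
      },
      last_day = max(.data$days_since_implant),
      .groups = "drop"
    )

  orphans <- per_patient |>
    dplyr::filter(.data$has_implant, is.na(.data$chs_delay))
  if (nrow(orphans) > 0) {
    inform(sprintf(
      "select_study_cohort: %d patient(s) with an implant but no surgery record excluded",
      nrow(orphans)))
  }

  keep <- per_patient |>
    dplyr::filter(
      .data$has_implant,
      !.data$has_icd,
      !is.na(.data$chs_delay),
      .data$chs_delay >= 0,
      .data$chs_delay <= window,
      .data$implant_age < max_age,
      .data$last_day >= min_followup * DAYS_PER_YEAR
    ) |>
    dplyr::pull("patient_id")

  events |> dplyr::filter(.data$patient_id %in% keep)
}

#' Person-years of follow-up per patient
#'
#' Follow-up is measured from implantation to the last observed event.
#' With annual-cycle data the default `"cycles"` convention counts whole
#' at-risk years, `ceiling(last event time in years)`: a patient whose
#' last event falls in year 7 was at risk for 7 complete annual draws.
#' `"exact"` uses the raw last-event time.
#'
#' @param events Event table.
#' @param exposure `"cycles"` (default) or `"exact"`.
#' @return A tibble with `patient_id` and `person_years`.
#' @export
person_years <- function(events, exposure = c("cycles", "exact")) {
  exposure <- match.arg(exposure)
  events |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      person_years = max(.data$days_since_implant) / DAYS_PER_YEAR,
      .groups = "drop"
    ) |>
    dplyr::mutate(person_years = pmax(0, .data$person_years)) |>
    dplyr::mutate(person_years = if (exposure == "cycles") {
      ceiling(.data$person_years)
    } else {
      .data$person_years
    })
}

#' Estimate an annual event rate with a 95% confidence interval
#'
#' The point estimate is total events of the given type divided by total
#' person-years of follow-up. For major complications the rate is
#' interpreted as an annual probability and the interval is a Wilson
#' score interval on person-year trials; for minor monitoring events it
#' is a frequency with an exact Poisson interval.
#'
#' @inheritParams person_years
#' @param type An event code from [major_events()] or [minor_events()].
#' @return A one-row tibble: `event`, `rate`, `conf.low`, `conf.high`,
#'   `n_events`, `person_years`.
#' @export
estimate_annual_rate <- function(events, type,
                                 exposure = c("cycles", "exact")) {
  exposure <- match.arg(exposure)
  if (!type %in% c(major_events(), minor_events())) {
    abort(paste0("estimate_annual_rate: '", type, "' is not a rated event type"))
  }
  py <- sum(person_years(events, exposure)$person_years)
  if (py <= 0) abort("estimate_annual_rate: zero person-years of follow-up")
  x <- sum(events$event == type)
  rate <- x / py

  if (type %in% major_events()) {
    n_trials <- max(1L, round(py))
    # Wilson score interval; only conf.int is used, so the chi-squared
    # approximation note is irrelevant here
    ci <- suppressWarnings(
      stats::prop.test(min(x, n_trials), n_trials,
                       correct = FALSE)$conf.int)
  } else {
    ci <- stats::poisson.test(x, T = py)$conf.int
  }
  tibble::tibble(event = type, rate = rate,
                 conf.low = ci[1], conf.high = ci[2],
                 n_events = x, person_years = py)
}

#' Summarise LOS and costs for one event type
#'
#' Sample mean and SD (n-1 denominator) of length of stay, direct
#' charge, and indirect cost over all events of the given type. With a
#' single event the SDs are reported as 0 with a message.
#'
#' @param events Event table with charges filled.
#' @param type An event code.
#' @return A one-row tibble: `event`, `n`, `los_mean`, `los_sd`,
#'   `direct_mean`, `direct_sd`, `indirect_mean`, `indirect_sd`.
#' @export
summarize_event <- function(events, type) {
  rows <- events |> dplyr::filter(.data$event == type)
  if (nrow(rows) == 0) abort(paste0("summarize_event: no '", type, "' events"))
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  if (nrow(rows) == 1) {
    inform(paste0("summarize_event: single '", type,
                  "' event; SDs reported as 0"))
  }
  tibble::tibble(
    event = type, n = nrow(rows),
    los_mean = mean(rows$los), los_sd = sd0(rows$los),
    direct_mean = mean(rows$direct_charge), direct_sd = sd0(rows$direct_charge),
    indirect_mean = mean(rows$indirect_cost), indirect_sd = sd0(rows$indirect_cost)
  )
}

#' Regress direct charge on length of stay
#'
#' Ordinary least squares of `direct_charge` on `los` for one event
#' type, with the two-sided t-test p-value for the slope. This is the
#' fit that establishes how strongly an event's billing depends on
#' hospitalization time.
#'
#' @param events Event table with charges filled.
#' @param type An event code.
#' @return An object of class `los_cost_fit` wrapping the `lm` fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_los_cost_regression <- function(events, type) {
  rows <- events |> dplyr::filter(.data$event == type)
  if (nrow(rows) < 3) abort("fit_los_cost_regression: need >= 3 events")
  if (length(unique(rows$los)) < 2) {
    abort("fit_los_cost_regression: degenerate design (all LOS identical)")
  }
  fit <- lm(direct_charge ~ los, data = rows)
  # exact lines are a legitimate input (noiseless billing); silence the
  # perfect-fit note
  sm <- suppressWarnings(summary(fit))
  structure(
    list(fit = fit, event = type,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         n = nrow(rows)),
    class = "los_cost_fit"
  )
}

#' @export
print.los_cost_fit <- function(x, ...) {
  cat(sprintf(
    "<los_cost_fit> %s: charge = %.1f + %.1f * LOS  (R^2 = %.3f, p = %.3g, n = %d)\n",
    x$event, x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Fit the indirect-cost model
#'
#' Least-squares fit of `indirect = per_visit + per_day * LOS` over a
#' set of (LOS, indirect cost) points, typically the per-event-type
#' means of the parameter bundle. A negative fitted per-visit intercept
#' is clipped to zero with a warning.
#'
#' @param los Vector of lengths of stay (days), or a two-column data
#'   frame with columns `los` and `indirect`.
#' @param indirect Vector of indirect costs (USD); omit when `los` is a
#'   data frame.
#' @return A list of class `indirect_cost_model` with elements
#'   `per_visit` (USD) and `per_day` (USD/day) plus fit diagnostics.
#' @export
fit_indirect_model <- function(los, indirect = NULL) {
  if (is.data.frame(los)) {
    indirect <- los$indirect
    los <- los$los
  }
  if (length(los) < 2 || length(unique(los)) < 2) {
    abort("fit_indirect_model: need >= 2 points with distinct LOS")
  }
  fit <- lm(indirect ~ los)
  per_visit <- unname(coef(fit)[1])
  per_day <- unname(coef(fit)[2])
  if (per_visit < 0) {
    warn(sprintf("fit_indirect_model: negative per-visit intercept (%.2f) clipped to 0",
                 per_visit))
    per_visit <- 0
  }
  sm <- suppressWarnings(summary(fit))
  structure(
    list(per_visit = per_visit, per_day = per_day,
         r_squared = sm$r.squared, n = length(los)),
    class = "indirect_cost_model"
  )
}

#' @export
print.indirect_cost_model <- function(x, ...) {
  cat(sprintf("<indirect_cost_model> indirect = %.2f + %.2f * LOS (R^2 = %.3f, n = %d)\n",
              x$per_visit, x$per_day, x$r_squared, x$n))
  invisible(x)
}

#' Predict indirect cost from LOS
#'
#' @param object An [fit_indirect_model()] result.
#' @param los Lengths of stay (days).
#' @param ... Unused.
#' @return Predicted indirect costs (USD).
#' @export
predict.indirect_cost_model <- function(object, los, ...) {
  object$per_visit + object$per_day * los
}

#' Estimate the full cost-parameter bundle from an event table
#'
#' Runs the whole estimation stage: annual probabilities for major
#' complications and annual frequencies for minor events (events per
#' person-year), LOS and cost summaries per event type, and the
#' implantation cost summary. Event types absent from the table are
#' dropped from the bundle.
#'
#' @param events Event table with charges filled (typically the output
#'   of [select_study_cohort()]).
#' @param discount_rate,horizon Carried into the returned bundle.
#' @inheritParams person_years
#' @return A [cost_parameters] object.
#' @export
estimate_cost_parameters <- function(events, discount_rate = 0.03,
                                     horizon = 20,
                                     exposure = c("cycles", "exact")) {
  exposure <- match.arg(exposure)
  present <- intersect(c(major_events(), minor_events()),
                       unique(events$event))
  rate_tbl <- purrr::map_dfr(present, function(e) {
    estimate_annual_rate(events, e, exposure)[, c("event", "rate")]
  })
  sum_tbl <- purrr::map_dfr(c("ppm_implant", present),
                            function(e) summarize_event(events, e))
  bundle <- sum_tbl |>
    dplyr::left_join(rate_tbl, by = "event") |>
    dplyr::rename(annual_rate = "rate") |>
    dplyr::select("event", "annual_rate", "los_mean", "los_sd",
                  "direct_mean", "direct_sd", "indirect_mean", "indirect_sd")
  cost_parameters(bundle, discount_rate = discount_rate, horizon = horizon)
}
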