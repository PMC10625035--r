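#' Classify each patient's clinical course
#'
#' A patient's course is `complication` if they experienced one or more
#' device malfunctions requiring lead-and-generator replacement and/or
#' infections; routine generator replacement at battery depletion does
#' not count as a complication, nor do monitoring events.
#'
#' @param events Event table; every patient must have a `ppm_implant`
#'   row.
#' @return A tibble with `patient_id` and `course`
#'   (`"complication"`/`"no_complication"`).
#' @export
classify_course <- function(events) {
  events <- tibble::as_tibble(events)
  no_implant <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = any(.data$event == "ppm_implant"), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(no_implant) > 0) {
    abort(paste0("classify_course: patient(s) without an implant record: ",
                 paste(head(no_implant$patient_id, 5), collapse = ", ")))
  }
  events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      course = ifelse(
        any(.data$event %in% c("malfunction_replacement", "infection")),
        "complication", "no_complication"),
      .groups = "drop"
    )
}

#' Build cumulative cost curves by clinical course
#'
#' For each patient, cumulative direct cost at year `y` is the sum of
#' charges for all pacing-related events in years `0..y` (year binning
#' is `floor(days / 365.25)`; the implantation sits in year 0). Indirect
#' cost is computed from LOS through the supplied indirect-cost model,
#' or taken from the `indirect_cost` column when no model is given. A
#' patient contributes to year `y` only while still under follow-up
#' (last observed event at year `y` or later), so the per-year sample
#' size shrinks with `y`; the group mean at each year is over the
#' patients still observed, not carried forward.
#'
#' @param events Event table with charges filled.
#' @param indirect_model Optional [fit_indirect_model()] result.
#' @param horizon Last year of the curve (default 20).
#' @return A tibble of class `cost_curves`: `group`, `year`, `n`,
#'   `direct_mean`, `direct_sd`, `indirect_mean`, `indirect_sd`.
#' @export
build_cost_curves <- function(events, indirect_model = NULL, horizon = 20) {
  events <- tibble::as_tibble(events) |>
    dplyr::filter(!.data$event %in% c("chs", "icd_implant"))
  courses <- classify_course(events)

  per_event <- events |>
    dplyr::mutate(
      year = floor(.data$days_since_implant / DAYS_PER_YEAR),
      ind = if (is.null(indirect_model)) {
        .data$indirect_cost
      } else {
        predict(indirect_model, .data$los)
      }
    )

  followup <- per_event |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_year = max(.data$year), .groups = "drop")

  grid <- followup |>
    dplyr::mutate(last_year = pmin(.data$last_year, horizon)) |>
    dplyr::reframe(year = 0:.data$last_year, .by = "patient_id")

  cum <- per_event |>
    dplyr::group_by(.data$patient_id, .data$year) |>
    dplyr::summarise(direct = sum(.data$direct_charge),
                     indirect = sum(.data$ind), .groups = "drop")

  patient_curves <- grid |>
    dplyr::left_join(cum, by = c("patient_id", "year")) |>
    dplyr::mutate(dplyr::across(c("direct", "indirect"),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::arrange(.data$patient_id, .data$year) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(direct = cumsum(.data$direct),
                  indirect = cumsum(.data$indirect)) |>
    dplyr::ungroup() |>
    dplyr::left_join(courses, by = "patient_id")

  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  curves <- patient_curves |>
    dplyr::group_by(group = .data$course, .data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      direct_mean = mean(.data$direct), direct_sd = sd0(.data$direct),
      indirect_mean = mean(.data$indirect), indirect_sd = sd0(.data$indirect),
      .groups = "drop"
    )

  for (g in c("complication", "no_complication")) {
    if (!g %in% curves$group) {
      warn(paste0("build_cost_curves: no patients in group '", g, "'"))
    }
  }
  structure(curves,
            class = c("cost_curves", class(curves)),
            patient_curves = patient_curves)
}

#' Extrapolate a cumulative cost curve to 20 years
#'
#' Ordinary least squares of the mean cumulative cost on year over an
#' observation window (default years 10-19), evaluated at the target
#' year. Intended for follow-up cohorts whose observation ends short of
#' the full horizon.
#'
#' @param curves A [build_cost_curves()] result (or any tibble with
#'   `group`, `year`, and a `<stream>_mean` column).
#' @param group Which course group to extrapolate (default
#'   `"no_complication"`).
#' @param stream `"direct"` or `"indirect"`.
#' @param window Years used for the fit.
#' @param at Year at which to evaluate the fitted line (default 20).
#' @return A list of class `cost_extrapolation`: `value` (USD at `at`),
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`, plus the inputs.
#' @export
extrapolate_20y <- function(curves, group = "no_complication",
                            stream = c("direct", "indirect"),
                            window = 10:19, at = 20) {
  stream <- match.arg(stream)
  col <- paste0(stream, "_mean")
  rows <- tibble::as_tibble(curves) |>
    dplyr::filter(.data$group == !!group, .data$year %in% window,
                  .data$n > 0)
  if (nrow(rows) < 3) {
    abort(sprintf(
      "extrapolate_20y: only %d observed year(s) in the window; need >= 3",
      nrow(rows)))
  }
  fit <- lm(rows[[col]] ~ rows$year)
  # an exactly linear observed curve is a valid case; silence the
  # perfect-fit note
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- sm$r.squared
  p <- if (nrow(sm$coefficients) >= 2) unname(sm$coefficients[2, 4]) else NA_real_
  structure(
    list(value = intercept + slope * at, at = at,
         slope = slope, intercept = intercept,
         r_squared = r2, p_value = p, n = nrow(rows),
         group = group, stream = stream, window = window),
    class = "cost_extrapolation"
  )
}

#' @export
print.cost_extrapolation <- function(x, ...) {
  cat(sprintf(
    "<cost_extrapolation> %s %s cost at year %d: $%.0f (R^2 = %.3f over %d window years)\n",
    x$group, x$stream, x$at, x$value,
    ifelse(is.na(x$r_squared), NA, x$r_squared), x$n))
  invisible(x)
}
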