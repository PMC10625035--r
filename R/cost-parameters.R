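#' Markov model input bundle
#'
#' A `cost_parameters` object collects everything the cost model needs:
#' one row per event type with its annual rate (a probability for major
#' complications, a mean count per patient-year for minor monitoring
#' events), length-of-stay mean/SD in days, and direct and indirect cost
#' mean/SD in 2018 USD, together with the annual discount rate and the
#' simulation horizon. The implantation row carries costs but no rate:
#' every modelled patient is implanted exactly once, at time zero.
#'
#' @param events A data frame with columns `event`, `annual_rate`,
#'   `los_mean`, `los_sd`, `direct_mean`, `direct_sd`, `indirect_mean`,
#'   `indirect_sd`. Must contain a `ppm_implant` row; other rows must be
#'   recognised major or minor event codes.
#' @param discount_rate Annual discount rate (fraction per year, >= 0).
#' @param horizon Time horizon in years (>= 1).
#'
#' @return A tibble of class `cost_parameters` with a `kind` column
#'   (`implant`/`major`/`minor`) and `discount_rate`, `horizon`
#'   attributes.
#' @export
cost_parameters <- function(events, discount_rate = 0.03, horizon = 20) {
  events <- tibble::as_tibble(events)
  needed <- c("event", "annual_rate", "los_mean", "los_sd",
              "direct_mean", "direct_sd", "indirect_mean", "indirect_sd")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(paste0("cost_parameters: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(events$event, c("ppm_implant", major_events(), minor_events()))
  if (length(bad) > 0) {
    abort(paste0("cost_parameters: unknown event code(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!"ppm_implant" %in% events$event) {
    abort("cost_parameters: a ppm_implant row is required")
  }
  if (anyDuplicated(events$event)) {
    abort("cost_parameters: duplicated event rows")
  }
  if (!is.numeric(discount_rate) || length(discount_rate) != 1 || discount_rate < 0) {
    abort("cost_parameters: discount_rate must be a single non-negative number")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1) {
    abort("cost_parameters: horizon must be >= 1 year")
  }

  events <- events |>
    dplyr::mutate(kind = dplyr::case_when(
      .data$event == "ppm_implant" ~ "implant",
      .data$event %in% major_events() ~ "major",
      TRUE ~ "minor"
    )) |>
    dplyr::relocate("event", "kind")

  num <- events |> dplyr::select(-"event", -"kind")
  if (any(num < 0, na.rm = TRUE)) {
    abort("cost_parameters: rates, LOS, and costs must be non-negative")
  }
  rates <- events$annual_rate[events$kind == "major"]
  if (any(rates > 1, na.rm = TRUE)) {
    abort("cost_parameters: major-event annual probabilities must lie in [0, 1]")
  }

  structure(events,
            class = c("cost_parameters", class(events)),
            discount_rate = discount_rate,
            horizon = horizon)
}

#' Reference parameter bundle for postoperative pacemaker pacing
#'
#' Point estimates for the cost model of pediatric permanent-pacemaker
#' care: annual probabilities of the three major complications
#' (malfunction requiring lead-and-generator replacement 2.0%, generator
#' replacement 11.2%, infection 0.6%), annual frequencies of the five
#' monitoring event types (clinic visit 1.5, device check 0.9, ECG 1.8,
#' Holter 0.1, EP catheterization 0.1 per patient-year), and the
#' associated length-of-stay and direct/indirect cost summaries in 2018
#' USD, discounted at 3% per year over a 20-year horizon. Cardiac
#' rehabilitation is kept in the taxonomy with rate zero; no cost
#' estimate is available for it. Minor events have deterministic LOS and
#' charges (SD 0).
#'
#' @inheritParams cost_parameters
#' @return A [cost_parameters] object.
#' @export
ppm_cost_parameters <- function(discount_rate = 0.03, horizon = 20) {
  tbl <- tibble::tribble(
    ~event,                    ~annual_rate, ~los_mean, ~los_sd, ~direct_mean, ~direct_sd, ~indirect_mean, ~indirect_sd,
    "ppm_implant",             NA_real_,     13.005,    13.166,  108052,       109053,     7338,           7429,
    "malfunction_replacement", 0.020,        3.156,     3.586,   52720,        52720,      1792,           2035,
    "generator_change",        0.112,        0.322,     1.039,   41797,        11050,      355,            600,
    "infection",               0.006,        12.679,    15.573,  91653,        112100,     7154,           8784,
    "clinic_visit",            1.5,          0.125,     0,       219,          0,          136,            0,
    "device_check",            0.9,          0.125,     0,       463,          0,          136,            0,
    "ecg",                     1.8,          0.125,     0,       289,          0,          136,            0,
    "holter",                  0.1,          0.125,     0,       963,          0,          136,            0,
    "ep_cath",                 0.1,          1.000,     0,       5894,         0,          578,            0,
    "rehab",                   0,            0.125,     0,       0,            0,          0,              0
  )
  cost_parameters(tbl, discount_rate = discount_rate, horizon = horizon)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat(sprintf("<cost_parameters> horizon %d y, discount %.1f%%/y\n",
              attr(x, "horizon"), 100 * attr(x, "discount_rate")))
  NextMethod()
}

discount_rate_of <- function(params) attr(params, "discount_rate")
horizon_of <- function(params) attr(params, "horizon")

param_row <- function(params, event) {
  row <- params[params$event == event, , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("no parameter row for event '", event, "'"))
  row
}

# rate-bearing rows (major + minor), in canonical order
rated_rows <- function(params) {
  params |>
    dplyr::filter(.data$kind %in% c("major", "minor")) |>
    dplyr::arrange(match(.data$event, c(major_events(), minor_events())))
}
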