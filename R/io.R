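EVENTS_COLS <- c("patient_id", "event", "age_at_event",
                 "days_since_implant", "los", "direct_charge",
                 "indirect_cost")
VOLUME_COLS <- c("year", "n_chs_under4", "n_chs_4plus", "n_ppm_postop",
                 "n_surgeons")

#' Read and write event tables
#'
#' Canonical CSV schema: header
#' `patient_id,event,age_at_event,days_since_implant,los,direct_charge,indirect_cost`,
#' comma-separated, UTF-8, currency in plain decimal 2018 USD, LOS in
#' days. `read_events()` validates the header and every event code
#' (unknown codes are reported with their line numbers); an empty file
#' with a valid header yields an empty table with a warning.
#'
#' @param path File path.
#' @param events Event tibble to write.
#' @return `read_events()` returns the typed event tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(paste0("read_events: no such file: ", path))
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      event = readr::col_character(),
      age_at_event = readr::col_double(),
      days_since_implant = readr::col_double(),
      los = readr::col_double(),
      direct_charge = readr::col_double(),
      indirect_cost = readr::col_double()
    )
  )
  missing <- setdiff(EVENTS_COLS, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("read_events: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl[, EVENTS_COLS]
  bad <- which(!tbl$event %in% event_types())
  if (length(bad) > 0) {
    # +1 for the header line
    abort(paste0(
      "read_events: unknown event code(s): ",
      paste(sprintf("'%s' (line %d)", tbl$event[head(bad, 5)],
                    head(bad, 5) + 1L), collapse = ", ")))
  }
  if (nrow(tbl) == 0) warn("read_events: file contains no event rows")
  tbl
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  missing <- setdiff(EVENTS_COLS, names(events))
  if (length(missing) > 0) {
    abort(paste0("write_events: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(events[, EVENTS_COLS], path)
  invisible(path)
}

#' Read and write surgical-volume tables
#'
#' CSV schema: header
#' `year,n_chs_under4,n_chs_4plus,n_ppm_postop,n_surgeons`, one row per
#' calendar year.
#'
#' @param path File path.
#' @param volumes Volume tibble to write.
#' @return `read_volumes()` returns the typed tibble; `write_volumes()`
#'   returns `path` invisibly.
#' @export
read_volumes <- function(path) {
  if (!file.exists(path)) abort(paste0("read_volumes: no such file: ", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  missing <- setdiff(VOLUME_COLS, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("read_volumes: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.unsorted(tbl$year, strictly = TRUE)) {
    abort("read_volumes: years must be strictly increasing")
  }
  tbl[, VOLUME_COLS]
}

#' @rdname read_volumes
#' @export
write_volumes <- function(volumes, path) {
  missing <- setdiff(VOLUME_COLS, names(volumes))
  if (length(missing) > 0) {
    abort(paste0("write_volumes: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(volumes[, VOLUME_COLS], path)
  invisible(path)
}

#' Read and write cost-parameter bundles as JSON
#'
#' One block per event type mirroring the bundle's columns, plus the
#' discount rate and horizon.
#'
#' @param params A [cost_parameters] object.
#' @param path File path.
#' @return `read_cost_parameters()` returns a [cost_parameters] object;
#'   `write_cost_parameters()` returns `path` invisibly.
#' @export
write_cost_parameters <- function(params, path) {
  stopifnot(inherits(params, "cost_parameters"))
  payload <- list(
    discount_rate = discount_rate_of(params),
    horizon = horizon_of(params),
    events = tibble::as_tibble(params) |> dplyr::select(-"kind")
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_cost_parameters
#' @export
read_cost_parameters <- function(path) {
  if (!file.exists(path)) abort(paste0("read_cost_parameters: no such file: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cost_parameters(tibble::as_tibble(payload$events),
                  discount_rate = payload$discount_rate,
                  horizon = payload$horizon)
}
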