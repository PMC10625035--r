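#' Compound annual growth rate
#'
#' Geometric annual growth rate between two endpoint counts:
#' `(last / first)^(1 / n_years) - 1`. `n_years` is the elapsed span,
#' i.e. `last_year - first_year` (58 for a 1960-2018 series).
#'
#' @param first,last Endpoint counts (> 0).
#' @param n_years Elapsed years between the endpoints (>= 1).
#' @return Growth rate as a fraction per year.
#' @export
compute_cagr <- function(first, last, n_years) {
  if (any(first <= 0) || any(last <= 0)) {
    abort("compute_cagr: endpoint counts must be > 0")
  }
  if (any(n_years < 1)) abort("compute_cagr: n_years must be >= 1")
  (last / first)^(1 / n_years) - 1
}

#' CAGR of a yearly series
#'
#' Endpoint-based [compute_cagr()] on a `(year, count)` table, with an
#' optional 3-year endpoint average for noisy series.
#'
#' @param data A data frame.
#' @param year,count Columns holding calendar year and count
#'   (tidy-evaluated).
#' @param smooth_endpoints If `TRUE`, each endpoint is the mean of the
#'   first/last 3 observations (the elapsed span is unchanged).
#' @return Growth rate as a fraction per year.
#' @export
series_cagr <- function(data, year, count, smooth_endpoints = FALSE) {
  yr <- dplyr::pull(data, {{ year }})
  ct <- dplyr::pull(data, {{ count }})
  o <- order(yr)
  yr <- yr[o]
  ct <- ct[o]
  if (smooth_endpoints && length(ct) >= 6) {
    first <- mean(head(ct, 3))
    last <- mean(utils::tail(ct, 3))
  } else {
    first <- ct[1]
    last <- ct[length(ct)]
  }
  compute_cagr(first, last, yr[length(yr)] - yr[1])
}

#' Fit a yearly count trend
#'
#' Poisson log-linear regression of counts on calendar year (the
#' default), or an ordinary linear fit. The slope `beta` is the yearly
#' log-rate change under the Poisson model (expected counts grow by
#' `exp(beta)` per year); the p-value is the Wald test of zero slope.
#' Non-integer counts (e.g. noiseless geometric series) are accepted;
#' the Poisson fit is then a quasi-likelihood fit of the same mean
#' model.
#'
#' @param data A data frame.
#' @param year,count Columns (tidy-evaluated).
#' @param model `"poisson"` or `"linear"`.
#' @return A list of class `trend_fit`: `beta`, `intercept` (at the
#'   first year of the series), `p_value`, `model`, `n`, and the
#'   underlying fit.
#' @export
fit_count_trend <- function(data, year, count,
                            model = c("poisson", "linear")) {
  model <- match.arg(model)
  yr <- dplyr::pull(data, {{ year }})
  ct <- dplyr::pull(data, {{ count }})
  if (length(yr) < 3) abort("fit_count_trend: need >= 3 observations")
  if (any(ct < 0)) abort("fit_count_trend: counts must be non-negative")
  if (all(ct == 0)) abort("fit_count_trend: all counts are zero")
  x <- yr - min(yr)
  fit <- if (model == "poisson") {
    suppressWarnings(glm(ct ~ x, family = stats::poisson()))
  } else {
    lm(ct ~ x)
  }
  sm <- summary(fit)
  structure(
    list(beta = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         p_value = unname(sm$coefficients[2, 4]),
         model = if (model == "poisson") "poisson_glm" else "linear",
         n = length(yr), fit = fit),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: beta = %.4f per year (p = %.3g, n = %d)\n",
              x$model, x$beta, x$p_value, x$n))
  invisible(x)
}

#' Pacemaker implantations per surgery
#'
#' Normalises yearly postoperative pacemaker implantations by the total
#' number of congenital heart surgeries performed that year. Years with
#' zero surgeries are emitted as `NA` with a message.
#'
#' @param volumes A surgical-volume table with columns `year`,
#'   `n_chs_under4`, `n_chs_4plus`, `n_ppm_postop`.
#' @return A tibble with `year`, `n_chs`, `n_ppm_postop`, `rate`.
#' @export
normalize_ppm_rate <- function(volumes) {
  out <- volumes |>
    tibble::as_tibble() |>
    dplyr::mutate(
      n_chs = .data$n_chs_under4 + .data$n_chs_4plus,
      rate = dplyr::if_else(.data$n_chs > 0,
                            .data$n_ppm_postop / .data$n_chs, NA_real_)
    ) |>
    dplyr::select("year", "n_chs", "n_ppm_postop", "rate")
  if (any(is.na(out$rate))) {
    inform(sprintf("normalize_ppm_rate: %d year(s) with zero surgeries emitted as NA",
                   sum(is.na(out$rate))))
  }
  out
}
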