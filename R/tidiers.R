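#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods
#'
#' broom-style accessors: `tidy()` returns the object's main table,
#' `glance()` a one-row summary.
#'
#' @param x A pedipace result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pedipace-tidiers
NULL

#' @rdname pedipace-tidiers
#' @method tidy cost_parameters
#' @export
tidy.cost_parameters <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname pedipace-tidiers
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$summary
}

#' @rdname pedipace-tidiers
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    direct_mean = s$mean[s$stream == "direct"],
    direct_sd = s$sd[s$stream == "direct"],
    direct_se = s$se[s$stream == "direct"],
    indirect_mean = s$mean[s$stream == "indirect"],
    indirect_sd = s$sd[s$stream == "indirect"],
    indirect_se = s$se[s$stream == "indirect"],
    n = x$config$n_patients,
    horizon = x$config$horizon,
    discount_rate = x$config$discount_rate,
    attrition = x$config$attrition
  )
}

#' @rdname pedipace-tidiers
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) {
  x$summary
}

#' @rdname pedipace-tidiers
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    direct_mean = s$mean[s$stream == "direct"],
    direct_sd = s$sd[s$stream == "direct"],
    indirect_mean = s$mean[s$stream == "indirect"],
    indirect_sd = s$sd[s$stream == "indirect"],
    n_draws = x$spec$n_draws,
    inner = x$inner
  )
}

#' @rdname pedipace-tidiers
#' @method tidy los_cost_fit
#' @export
tidy.los_cost_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "los"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname pedipace-tidiers
#' @method glance los_cost_fit
#' @export
glance.los_cost_fit <- function(x, ...) {
  tibble::tibble(event = x$event, r.squared = x$r_squared,
                 p.value = x$p_value, nobs = x$n)
}

#' @rdname pedipace-tidiers
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "year"),
    estimate = c(x$intercept, x$beta)
  )
}

#' @rdname pedipace-tidiers
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, p.value = x$p_value,
                 model = x$model, nobs = x$n)
}

#' @rdname pedipace-tidiers
#' @method tidy indirect_cost_model
#' @export
tidy.indirect_cost_model <- function(x, ...) {
  tibble::tibble(term = c("per_visit", "per_day"),
                 estimate = c(x$per_visit, x$per_day))
}

#' @rdname pedipace-tidiers
#' @method glance indirect_cost_model
#' @export
glance.indirect_cost_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n)
}

#' @rdname pedipace-tidiers
#' @method tidy cost_extrapolation
#' @export
tidy.cost_extrapolation <- function(x, ...) {
  tibble::tibble(group = x$group, stream = x$stream, at = x$at,
                 value = x$value, slope = x$slope,
                 intercept = x$intercept, r.squared = x$r_squared,
                 p.value = x$p_value, nobs = x$n)
}
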