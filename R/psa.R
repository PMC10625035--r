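#' Moment-match a parameter distribution
#'
#' Standard health-economics conventions: gamma for positive quantities
#' (costs, lengths of stay), matched by `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`; beta for probabilities. A probability with a
#' known SD is moment-matched exactly; one without an SD uses an
#' effective sample size `m`, giving `alpha = mean * m`,
#' `beta = (1 - mean) * m`. An SD of zero (or family `"point"`) yields a
#' point mass.
#'
#' @param family `"gamma"`, `"beta"`, or `"point"`.
#' @param mean Target mean (> 0; in (0,1) for beta).
#' @param sd Target SD (>= 0), or `NULL` for beta with `effective_n`.
#' @param effective_n Effective sample size for beta concentration when
#'   no SD is available.
#' @return A list of class `psa_dist`: `family`, `mean`, `sd`, and the
#'   family's hyperparameters.
#' @export
moment_match <- function(family = c("gamma", "beta", "point"), mean,
                         sd = NULL, effective_n = NULL) {
  family <- match.arg(family)
  if (family == "point" || (!is.null(sd) && sd == 0)) {
    return(structure(list(family = "point", mean = mean, sd = 0),
                     class = "psa_dist"))
  }
  if (family == "gamma") {
    if (mean <= 0) abort("moment_match: gamma requires mean > 0")
    if (is.null(sd) || sd < 0) abort("moment_match: gamma requires sd >= 0")
    return(structure(
      list(family = "gamma", mean = mean, sd = sd,
           shape = (mean / sd)^2, scale = sd^2 / mean),
      class = "psa_dist"))
  }
  # beta
  if (mean <= 0 || mean >= 1) {
    abort("moment_match: beta requires mean in (0, 1)")
  }
  if (!is.null(sd)) {
    v <- sd^2
    if (v >= mean * (1 - mean)) {
      abort("moment_match: beta SD too large for the given mean")
    }
    m <- mean * (1 - mean) / v - 1
  } else {
    if (is.null(effective_n) || effective_n <= 0) {
      abort("moment_match: beta without sd needs a positive effective_n")
    }
    m <- effective_n
  }
  structure(
    list(family = "beta", mean = mean,
         sd = sqrt(mean * (1 - mean) / (m + 1)),
         alpha = mean * m, beta = (1 - mean) * m),
    class = "psa_dist")
}

draw_psa_dist <- function(dist, n) {
  switch(dist$family,
         point = rep(dist$mean, n),
         gamma = rgamma(n, shape = dist$shape, scale = dist$scale),
         beta = rbeta(n, dist$alpha, dist$beta))
}

#' Specify a probabilistic sensitivity analysis
#'
#' Beta distributions for the major-complication annual probabilities
#' (concentration set by `effective_n`, the follow-up cohort size, since
#' no SD is reported for them), gamma distributions for every cost with
#' a reported SD, and point masses for parameters without uncertainty
#' information (the minor-event frequencies and their deterministic
#' charges). Lengths of stay are not varied: unit costs, not LOS, enter
#' the cost expectation.
#'
#' @param n_draws Number of parameter draws (>= 2).
#' @param effective_n Effective sample size for probability parameters
#'   lacking an SD (default 255, the follow-up cohort size the default
#'   rates come from).
#' @param point_mass_all If `TRUE`, every parameter is a point mass (the
#'   PSA then reproduces the base case exactly; mainly for testing).
#' @param seed Integer seed.
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_draws = 10000, effective_n = 255,
                     point_mass_all = FALSE, seed = 1L) {
  if (n_draws < 2) abort("psa_spec: n_draws must be >= 2")
  structure(
    list(n_draws = as.integer(n_draws), effective_n = effective_n,
         point_mass_all = isTRUE(point_mass_all), seed = as.integer(seed)),
    class = "psa_spec"
  )
}

psa_distributions <- function(params, spec) {
  mk <- function(family, mean, sd = NULL) {
    if (spec$point_mass_all || (!is.null(sd) && (is.na(sd) || sd == 0)) ||
        (is.null(sd) && family != "beta")) {
      moment_match("point", mean)
    } else if (family == "beta") {
      moment_match("beta", mean, sd = NULL, effective_n = spec$effective_n)
    } else {
      moment_match("gamma", mean, sd)
    }
  }
  imp <- param_row(params, "ppm_implant")
  rated <- rated_rows(params)
  dists <- list(
    implant_direct = mk("gamma", imp$direct_mean, imp$direct_sd),
    implant_indirect = mk("gamma", imp$indirect_mean, imp$indirect_sd)
  )
  for (j in seq_len(nrow(rated))) {
    ev <- rated$event[j]
    rate <- rated$annual_rate[j]
    if (is.na(rate)) next
    dists[[paste0(ev, "_rate")]] <-
      if (rated$kind[j] == "major" && rate > 0 && rate < 1 &&
          !spec$point_mass_all) {
        mk("beta", rate)
      } else {
        moment_match("point", rate)
      }
    dists[[paste0(ev, "_direct")]] <- if (rated$direct_mean[j] > 0) {
      mk("gamma", rated$direct_mean[j], rated$direct_sd[j])
    } else {
      moment_match("point", rated$direct_mean[j])
    }
    dists[[paste0(ev, "_indirect")]] <- if (rated$indirect_mean[j] > 0) {
      mk("gamma", rated$indirect_mean[j], rated$indirect_sd[j])
    } else {
      moment_match("point", rated$indirect_mean[j])
    }
  }
  dists
}

#' Run a probabilistic sensitivity analysis
#'
#' Samples a full parameter bundle per draw from the distributions in
#' `spec` and re-evaluates the model, by default through the exact
#' closed form ([expected_costs_closed_form()]), so the reported spread
#' reflects parameter uncertainty only, not Monte-Carlo noise. An inner
#' simulation (`inner = "simulate"`, with `inner_n` patients per draw)
#' is available for checking that the two routes agree.
#'
#' @param params Base-case [cost_parameters] bundle.
#' @param spec A [psa_spec()].
#' @param config A [simulation_config()]; supplies horizon, discount
#'   rate, and attrition.
#' @param inner `"closed_form"` (default) or `"simulate"`.
#' @param inner_n Patients per draw under the inner simulation.
#' @return An object of class `psa_result`: `draws` (tibble with one row
#'   per draw: sampled parameters and resulting expected costs) and
#'   `summary` (mean and SD per cost stream).
#' @export
run_psa <- function(params, spec = psa_spec(), config = simulation_config(),
                    inner = c("closed_form", "simulate"), inner_n = 500) {
  inner <- match.arg(inner)
  stopifnot(inherits(params, "cost_parameters"),
            inherits(spec, "psa_spec"),
            inherits(config, "simulation_config"))
  dists <- psa_distributions(params, spec)
  nd <- spec$n_draws

  draws <- withr::with_seed(spec$seed, {
    cols <- lapply(dists, draw_psa_dist, n = nd)
    tibble::as_tibble(cols)
  })

  rated <- rated_rows(params)
  H <- config$horizon
  w <- sum((1 - config$attrition)^(1:H) *
             discount_factor(config$discount_rate, 1:H))

  if (inner == "closed_form") {
    per_year_direct <- rep(0, nd)
    per_year_indirect <- rep(0, nd)
    for (j in seq_len(nrow(rated))) {
      ev <- rated$event[j]
      if (is.na(rated$annual_rate[j])) next
      per_year_direct <- per_year_direct +
        draws[[paste0(ev, "_rate")]] * draws[[paste0(ev, "_direct")]]
      per_year_indirect <- per_year_indirect +
        draws[[paste0(ev, "_rate")]] * draws[[paste0(ev, "_indirect")]]
    }
    draws$direct <- draws$implant_direct + w * per_year_direct
    draws$indirect <- draws$implant_indirect + w * per_year_indirect
  } else {
    res <- purrr::map(seq_len(nd), function(i) {
      p <- params
      imp <- p$event == "ppm_implant"
      p$direct_mean[imp] <- draws$implant_direct[i]
      p$indirect_mean[imp] <- draws$implant_indirect[i]
      for (j in seq_len(nrow(rated))) {
        ev <- rated$event[j]
        if (is.na(rated$annual_rate[j])) next
        k <- p$event == ev
        p$annual_rate[k] <- draws[[paste0(ev, "_rate")]][i]
        p$direct_mean[k] <- draws[[paste0(ev, "_direct")]][i]
        p$indirect_mean[k] <- draws[[paste0(ev, "_indirect")]][i]
      }
      cfg <- config
      cfg$n_patients <- as.integer(inner_n)
      cfg$seed <- (config$seed + i) %% .Machine$integer.max
      s <- simulate_cohort(p, cfg)$summary
      c(direct = s$mean[s$stream == "direct"],
        indirect = s$mean[s$stream == "indirect"])
    })
    draws$direct <- purrr::map_dbl(res, "direct")
    draws$indirect <- purrr::map_dbl(res, "indirect")
  }

  summary_tbl <- tibble::tibble(
    stream = c("direct", "indirect"),
    mean = c(mean(draws$direct), mean(draws$indirect)),
    sd = c(sd(draws$direct), sd(draws$indirect)),
    n_draws = nd
  )
  structure(list(draws = draws, summary = summary_tbl, spec = spec,
                 inner = inner, config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%s inner evaluation)\n",
              x$spec$n_draws, x$inner))
  print(x$summary)
  invisible(x)
}
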