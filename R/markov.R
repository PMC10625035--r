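#' Configure the Markov cost simulation
#'
#' One alive "with pacemaker" health state with independent per-cycle
#' event draws, an optional absorbing exit state entered with annual
#' probability `attrition`, cycle length one year, costs accrued at
#' cycle end, no half-cycle correction. Implantation cost accrues at
#' time zero, undiscounted; follow-up cycles `t = 1..horizon` are
#' discounted by `(1 + discount_rate)^-t`.
#'
#' @param n_patients Cohort size (default 10 000).
#' @param horizon Years simulated (default 20).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param attrition Annual probability of leaving the model (default 0).
#' @param sample_implant_cost If `TRUE`, each patient's implantation
#'   cost is drawn from a zero-truncated normal with the bundle's
#'   implantation mean/SD; by default it is the deterministic mean.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 10000, horizon = 20,
                              discount_rate = 0.03, attrition = 0,
                              sample_implant_cost = FALSE, seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("simulation_config: n_patients must be >= 1")
  }
  if (!is.numeric(horizon) || horizon < 1) {
    abort("simulation_config: horizon must be >= 1")
  }
  if (discount_rate < 0) abort("simulation_config: discount_rate must be >= 0")
  if (attrition < 0 || attrition >= 1) {
    abort("simulation_config: attrition must lie in [0, 1)")
  }
  structure(
    list(n_patients = as.integer(n_patients), horizon = as.integer(horizon),
         discount_rate = discount_rate, attrition = attrition,
         sample_implant_cost = isTRUE(sample_implant_cost),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Discount factor
#'
#' Present-value factor `(1 + rate)^-t` for a cost accrued at the end of
#' cycle `t`; `t = 0` (the implantation year) is undiscounted.
#'
#' @param rate Annual discount rate (>= 0).
#' @param t Cycle index (>= 0); vectorised.
#' @return Dimensionless discount factor(s).
#' @export
discount_factor <- function(rate, t) {
  if (any(rate < 0)) abort("discount_factor: rate must be >= 0")
  if (any(t < 0)) abort("discount_factor: t must be >= 0")
  (1 + rate)^(-t)
}

#' Closed-form expected discounted costs
#'
#' Exact expectation of the simulated cohort mean, with no sampling:
#' implantation cost plus, for each cycle `t = 1..H`, the survival
#' weight `(1 - attrition)^t`, the discount factor, and the sum over
#' event types of annual rate times mean unit cost. Serves as the
#' analytic oracle for [simulate_cohort()] and the objective for
#' [calibrate_attrition()].
#'
#' @param params A [cost_parameters] bundle.
#' @param config A [simulation_config()]. Its `discount_rate` overrides
#'   the bundle's.
#' @return A list with elements `direct` and `indirect` (2018 USD).
#' @export
expected_costs_closed_form <- function(params, config = simulation_config()) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(config, "simulation_config"))
  H <- config$horizon
  t <- seq_len(H)
  w <- (1 - config$attrition)^t * discount_factor(config$discount_rate, t)
  rated <- rated_rows(params)
  per_year_direct <- sum(rated$annual_rate * rated$direct_mean, na.rm = TRUE)
  per_year_indirect <- sum(rated$annual_rate * rated$indirect_mean, na.rm = TRUE)
  imp <- param_row(params, "ppm_implant")
  list(direct = imp$direct_mean + sum(w) * per_year_direct,
       indirect = imp$indirect_mean + sum(w) * per_year_indirect)
}

# zero-truncated normal via inverse CDF
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Simulate a cohort of pacemaker patients
#'
#' Patient-level Monte-Carlo evaluation of the cost model: each of
#' `n_patients` hypothetical patients accrues the implantation cost at
#' time zero and then, for each annual cycle while still in the model,
#' draws an exit with probability `attrition`, each major complication
#' as a Bernoulli trial at its annual probability, and each minor event
#' count as a Poisson draw at its annual frequency, accruing
#' `count * unit cost * discount factor`. Draws use one seeded stream
#' in a fixed order (survival, then each event type as a
#' patients-by-cycles block), so results are reproducible and invariant
#' to patient labelling.
#'
#' @param params A [cost_parameters] bundle.
#' @param config A [simulation_config()].
#' @param trajectories If `TRUE`, attach per-patient-by-cycle event
#'   counts and discounted cost increments.
#' @return An object of class `cohort_summary`: a list with `summary`
#'   (tibble: stream, mean, sd, se, n), `patients` (per-patient
#'   discounted totals), and optionally `trajectories`.
#' @export
simulate_cohort <- function(params, config = simulation_config(),
                            trajectories = FALSE) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(config, "simulation_config"))
  withr::with_seed(config$seed,
                   simulate_cohort_impl(params, config, trajectories))
}

simulate_cohort_impl <- function(params, config, trajectories) {
  n <- config$n_patients
  H <- config$horizon
  d <- discount_factor(config$discount_rate, seq_len(H))
  imp <- param_row(params, "ppm_implant")

  implant_direct <- if (config$sample_implant_cost) {
    rnorm_trunc0(n, imp$direct_mean, imp$direct_sd)
  } else {
    rep(imp$direct_mean, n)
  }
  implant_indirect <- rep(imp$indirect_mean, n)

  # alive[i, t]: still in the model during cycle t
  alive <- matrix(1, n, H)
  if (config$attrition > 0) {
    stay <- matrix(runif(n * H) >= config$attrition, n, H)
    acc <- rep(TRUE, n)
    for (tt in seq_len(H)) {
      acc <- acc & stay[, tt]
      alive[, tt] <- as.numeric(acc)
    }
  }

  direct_cycle <- matrix(0, n, H)
  indirect_cycle <- matrix(0, n, H)
  rated <- rated_rows(params)
  counts_list <- if (trajectories) vector("list", nrow(rated)) else NULL
  for (j in seq_len(nrow(rated))) {
    rate <- rated$annual_rate[j]
    if (is.na(rate) || rate == 0) next
    cnt <- if (rated$kind[j] == "major") {
      matrix(rbinom(n * H, 1L, rate), n, H)
    } else {
      matrix(rpois(n * H, rate), n, H)
    }
    cnt <- cnt * alive
    direct_cycle <- direct_cycle + cnt * rated$direct_mean[j]
    indirect_cycle <- indirect_cycle + cnt * rated$indirect_mean[j]
    if (trajectories) counts_list[[j]] <- cnt
  }

  disc_direct <- sweep(direct_cycle, 2, d, `*`)
  disc_indirect <- sweep(indirect_cycle, 2, d, `*`)
  total_direct <- implant_direct + rowSums(disc_direct)
  total_indirect <- implant_indirect + rowSums(disc_indirect)

  summary_tbl <- tibble::tibble(
    stream = c("direct", "indirect"),
    mean = c(mean(total_direct), mean(total_indirect)),
    sd = c(sd(total_direct), sd(total_indirect)),
    n = n
  ) |>
    dplyr::mutate(se = .data$sd / sqrt(.data$n)) |>
    dplyr::relocate("stream", "mean", "sd", "se", "n")

  out <- list(
    summary = summary_tbl,
    patients = tibble::tibble(patient = seq_len(n),
                              direct = total_direct,
                              indirect = total_indirect),
    config = config
  )
  if (trajectories) {
    traj <- tidyr::expand_grid(patient = seq_len(n), cycle = seq_len(H)) |>
      dplyr::arrange(.data$cycle, .data$patient)
    for (j in seq_len(nrow(rated))) {
      traj[[rated$event[j]]] <- if (is.null(counts_list[[j]])) {
        0
      } else {
        as.vector(counts_list[[j]])
      }
    }
    traj$alive <- as.vector(alive) > 0
    traj$direct_increment <- as.vector(disc_direct)
    traj$indirect_increment <- as.vector(disc_indirect)
    out$trajectories <- traj |> dplyr::arrange(.data$patient, .data$cycle)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> N = %d, horizon %d y, discount %.1f%%, attrition %.3f\n",
              x$config$n_patients, x$config$horizon,
              100 * x$config$discount_rate, x$config$attrition))
  print(x$summary)
  invisible(x)
}

#' Calibrate the attrition probability to a target mean cost
#'
#' Finds the annual exit probability at which the closed-form expected
#' 20-year direct cost equals a target, by root finding on
#' `[0, 1)` to within $1. Useful for reconciling the minimal
#' single-state model with an externally reported mean that implies an
#' unmodelled exit mechanism.
#'
#' @param params A [cost_parameters] bundle.
#' @param config A [simulation_config()]; its attrition entry is the
#'   quantity solved for.
#' @param target_mean_direct Target expected direct cost (USD). Must lie
#'   between the implantation cost and the zero-attrition expectation.
#' @return The calibrated annual exit probability.
#' @export
calibrate_attrition <- function(params, config = simulation_config(),
                                target_mean_direct) {
  at_q <- function(q) {
    cfg <- config
    cfg$attrition <- q
    expected_costs_closed_form(params, cfg)$direct
  }
  hi <- at_q(0)
  lo <- param_row(params, "ppm_implant")$direct_mean
  if (target_mean_direct > hi + 1 || target_mean_direct < lo - 1) {
    abort(sprintf(
      "calibrate_attrition: target %.0f outside attainable range [%.0f, %.0f]",
      target_mean_direct, lo, hi))
  }
  if (abs(target_mean_direct - hi) <= 1) return(0)
  uniroot(function(q) at_q(q) - target_mean_direct,
          interval = c(0, 1 - 1e-12), tol = 1e-12)$root
}
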