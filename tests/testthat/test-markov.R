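test_that("discount factors follow (1 + r)^-t with an undiscounted year zero", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_identical(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 5), 1.03^-5)
  expect_error(discount_factor(-0.01, 1), "rate")
  expect_error(discount_factor(0.03, -1), "t must")
})

test_that("the closed form reduces to the implantation cost when no events occur", {
  p <- zero_rate_params(implant_direct = 108052)
  cf <- expected_costs_closed_form(p, simulation_config())
  expect_identical(cf$direct, 108052)
})

test_that("the closed form equals a term-by-term summation oracle", {
  oracle <- function(params, config) {
    rated <- tidy(params)[tidy(params)$kind != "implant", ]
    imp <- tidy(params)[tidy(params)$kind == "implant", ]
    direct <- imp$direct_mean
    indirect <- imp$indirect_mean
    for (t in seq_len(config$horizon)) {
      w <- (1 - config$attrition)^t / (1 + config$discount_rate)^t
      for (j in seq_len(nrow(rated))) {
        r <- rated$annual_rate[j]
        if (is.na(r)) next
        direct <- direct + w * r * rated$direct_mean[j]
        indirect <- indirect + w * r * rated$indirect_mean[j]
      }
    }
    list(direct = direct, indirect = indirect)
  }
  cases <- list(
    list(p = ppm_cost_parameters(), cfg = simulation_config()),
    list(p = ppm_cost_parameters(),
         cfg = simulation_config(discount_rate = 0)),
    list(p = ppm_cost_parameters(),
         cfg = simulation_config(attrition = 0.07)),
    list(p = tiny_params(),
         cfg = simulation_config(horizon = 5, discount_rate = 0.1,
                                 attrition = 0.25))
  )
  for (case in cases) {
    got <- expected_costs_closed_form(case$p, case$cfg)
    want <- oracle(case$p, case$cfg)
    expect_equal(got$direct, want$direct, tolerance = 1e-12)
    expect_equal(got$indirect, want$indirect, tolerance = 1e-12)
  }
})

test_that("undiscounted, attrition-free expectation is implant cost plus H times the yearly event cost", {
  p <- ppm_cost_parameters()
  r <- tidy(p)[tidy(p)$kind != "implant", ]
  per_year <- sum(r$annual_rate * r$direct_mean)
  cf <- expected_costs_closed_form(
    p, simulation_config(discount_rate = 0, horizon = 20))
  expect_equal(cf$direct, 108052 + 20 * per_year, tolerance = 1e-12)
})

test_that("near-total attrition leaves only the implantation cost", {
  p <- ppm_cost_parameters()
  cf <- expected_costs_closed_form(
    p, simulation_config(attrition = 1 - 1e-12))
  expect_equal(cf$direct, 108052, tolerance = 1e-6)
})

test_that("with all rates zero every simulated patient costs exactly the implant", {
  p <- zero_rate_params(implant_direct = 108052)
  s <- simulate_cohort(p, simulation_config(n_patients = 500, seed = 1))
  expect_true(all(s$patients$direct == 108052))
  expect_identical(s$summary$sd[s$summary$stream == "direct"], 0)
})

test_that("the simulated mean agrees with the closed form within Monte-Carlo error", {
  p <- ppm_cost_parameters()
  cfg <- simulation_config(n_patients = 20000, seed = 11)
  s <- simulate_cohort(p, cfg)
  cf <- expected_costs_closed_form(p, cfg)
  for (stream in c("direct", "indirect")) {
    row <- s$summary[s$summary$stream == stream, ]
    expect_lt(abs(row$mean - cf[[stream]]), 3 * row$se)
  }
})

test_that("oracle equivalence holds across randomized parameter bundles", {
  set.seed(42)
  for (i in 1:3) {
    tbl <- tibble::tibble(
      event = c("ppm_implant", "malfunction_replacement", "infection",
                "clinic_visit", "ep_cath"),
      annual_rate = c(NA, runif(2, 0, 0.3), runif(2, 0, 3)),
      los_mean = runif(5, 0.1, 15), los_sd = runif(5, 0, 10),
      direct_mean = runif(5, 100, 1e5), direct_sd = runif(5, 0, 5e4),
      indirect_mean = runif(5, 10, 1e4), indirect_sd = runif(5, 0, 5e3)
    )
    p <- cost_parameters(tbl, discount_rate = runif(1, 0, 0.06),
                         horizon = 10)
    cfg <- simulation_config(n_patients = 5000, horizon = 10,
                             discount_rate = attr(p, "discount_rate"),
                             attrition = runif(1, 0, 0.15), seed = i)
    s <- simulate_cohort(p, cfg)
    cf <- expected_costs_closed_form(p, cfg)
    row <- s$summary[s$summary$stream == "direct", ]
    expect_lt(abs(row$mean - cf$direct), 3 * row$se)
  }
})

test_that("simulation is reproducible by seed and sensitive to it", {
  p <- tiny_params()
  cfg <- simulation_config(n_patients = 300, horizon = 5, seed = 5,
                           discount_rate = 0)
  a <- simulate_cohort(p, cfg)
  b <- simulate_cohort(p, cfg)
  expect_identical(a$summary, b$summary)
  cfg2 <- simulation_config(n_patients = 300, horizon = 5, seed = 6,
                            discount_rate = 0)
  expect_false(identical(a$summary, simulate_cohort(p, cfg2)$summary))
})

test_that("scaling all unit costs scales simulated moments exactly", {
  p <- ppm_cost_parameters()
  p10 <- p
  for (col in c("direct_mean", "indirect_mean")) {
    p10[[col]] <- 10 * p10[[col]]
  }
  cfg <- simulation_config(n_patients = 2000, seed = 3)
  a <- simulate_cohort(p, cfg)$summary
  b <- simulate_cohort(p10, cfg)$summary
  expect_equal(b$mean, 10 * a$mean, tolerance = 1e-12)
  expect_equal(b$sd, 10 * a$sd, tolerance = 1e-12)
})

test_that("mean cost is monotone in discount rate, attrition, rates, and unit costs", {
  p <- ppm_cost_parameters()
  base <- expected_costs_closed_form(p, simulation_config())$direct
  expect_lt(expected_costs_closed_form(
    p, simulation_config(discount_rate = 0.06))$direct, base)
  expect_lt(expected_costs_closed_form(
    p, simulation_config(attrition = 0.05))$direct, base)
  up <- p
  up$annual_rate[up$event == "infection"] <- 0.05
  expect_gt(expected_costs_closed_form(up, simulation_config())$direct, base)
  up2 <- p
  up2$direct_mean[up2$event == "ecg"] <- 1000
  expect_gt(expected_costs_closed_form(up2, simulation_config())$direct, base)
  # and in simulation with a shared seed for the discount comparison
  cfg0 <- simulation_config(n_patients = 1000, seed = 4)
  cfg6 <- simulation_config(n_patients = 1000, discount_rate = 0.06, seed = 4)
  m0 <- simulate_cohort(p, cfg0)$summary$mean[1]
  m6 <- simulate_cohort(p, cfg6)$summary$mean[1]
  expect_lt(m6, m0)
})

test_that("implant-cost sampling with zero SD matches the deterministic default", {
  p <- ppm_cost_parameters()
  p$direct_sd[p$event == "ppm_implant"] <- 0
  p$indirect_sd[p$event == "ppm_implant"] <- 0
  cfg_off <- simulation_config(n_patients = 400, seed = 2)
  cfg_on <- simulation_config(n_patients = 400, seed = 2,
                              sample_implant_cost = TRUE)
  expect_identical(simulate_cohort(p, cfg_off)$summary,
                   simulate_cohort(p, cfg_on)$summary)
})

test_that("implant-cost sampling adds dispersion when the SD is positive", {
  p <- zero_rate_params()
  s <- simulate_cohort(
    p, simulation_config(n_patients = 2000, seed = 2,
                         sample_implant_cost = TRUE))
  expect_gt(s$summary$sd[1], 0)
  expect_true(all(s$patients$direct >= 0))
})

test_that("trajectories carry per-cycle counts and increments that add up", {
  p <- tiny_params()
  s <- simulate_cohort(p, simulation_config(n_patients = 50, horizon = 5,
                                            discount_rate = 0, seed = 7),
                       trajectories = TRUE)
  tr <- s$trajectories
  expect_equal(nrow(tr), 50 * 5)
  imp <- tidy(p)$direct_mean[tidy(p)$event == "ppm_implant"]
  totals <- tr |>
    dplyr::group_by(patient) |>
    dplyr::summarise(direct = sum(direct_increment) + imp)
  expect_equal(totals$direct, s$patients$direct)
})

test_that("attrition calibration inverts the closed form", {
  p <- ppm_cost_parameters()
  cfg <- simulation_config()
  cf0 <- expected_costs_closed_form(p, cfg)$direct
  expect_equal(calibrate_attrition(p, cfg, cf0), 0)

  implant <- tidy(p)$direct_mean[tidy(p)$event == "ppm_implant"]
  target <- implant + (cf0 - implant) / 2
  q <- calibrate_attrition(p, cfg, target)
  # independent fine-grid search oracle, written out from first principles
  r <- tidy(p)[tidy(p)$kind != "implant", ]
  per_year <- sum(r$annual_rate * r$direct_mean, na.rm = TRUE)
  grid <- seq(0, 0.9, by = 1e-5)
  annuity <- colSums(outer(1:20, grid, function(t, g) ((1 - g) / 1.03)^t))
  err <- abs(implant + per_year * annuity - target)
  expect_lt(abs(q - grid[which.min(err)]), 1e-4)
  # matched to within a dollar
  cfg_q <- cfg
  cfg_q$attrition <- q
  expect_lt(abs(expected_costs_closed_form(p, cfg_q)$direct - target), 1)
})

test_that("attrition calibration is monotone and range-checked", {
  p <- ppm_cost_parameters()
  cfg <- simulation_config()
  q_low <- calibrate_attrition(p, cfg, 150000)
  q_high <- calibrate_attrition(p, cfg, 200000)
  expect_gt(q_low, q_high)
  expect_error(calibrate_attrition(p, cfg, 1e7), "range")
  expect_error(calibrate_attrition(p, cfg, 1000), "range")
})
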