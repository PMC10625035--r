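test_that("cohort selection applies the postoperative window inclusively", {
  ev <- dplyr::bind_rows(
    basic_patient("in30", chs_delay = 30),
    basic_patient("out31", chs_delay = 31)
  )
  kept <- select_study_cohort(ev)
  expect_setequal(unique(kept$patient_id), "in30")
})

test_that("cohort selection removes ICD patients and orphan implants", {
  icd <- basic_patient("withicd",
                       extra = ev_row("withicd", "icd_implant", 400))
  orphan <- basic_patient("orphan")[-1, ]  # drop the chs row
  ev <- dplyr::bind_rows(basic_patient("ok"), icd, orphan)
  expect_message(kept <- select_study_cohort(ev), "no surgery record")
  expect_setequal(unique(kept$patient_id), "ok")
})

test_that("cohort selection enforces strict age and minimum follow-up", {
  ev <- dplyr::bind_rows(
    basic_patient("young", implant_age = 3.99),
    basic_patient("age4", implant_age = 4.0),
    basic_patient("short", followup_days = 0.4 * 365.25)
  )
  kept <- select_study_cohort(ev)
  expect_setequal(unique(kept$patient_id), "young")
})

test_that("cohort selection is idempotent", {
  cfg <- generator_config(n_patients = 300, horizon = 5, seed = 3,
                          icd_fraction = 0.1, implant_age_max = 6,
                          chs_delay_max = 60)
  ev <- generate_events(cfg)
  once <- select_study_cohort(ev)
  expect_identical(select_study_cohort(once), once)
  # and it strictly filtered something in this config
  expect_lt(dplyr::n_distinct(once$patient_id), 300)
})

test_that("annual rates are events per person-year", {
  # 100 patients followed 28 whole years each; 56 malfunction events
  ev <- purrr::map_dfr(1:100, function(i) {
    basic_patient(sprintf("P%03d", i), followup_days = 28 * 365.25)
  })
  extra <- purrr::map_dfr(1:56, function(i) {
    ev_row(sprintf("P%03d", i), "malfunction_replacement", 500, los = 3,
           direct = 50000, indirect = 1800)
  })
  ev <- dplyr::bind_rows(ev, extra)
  r <- estimate_annual_rate(ev, "malfunction_replacement")
  expect_equal(r$person_years, 2800)
  expect_equal(r$rate, 0.02)
  expect_true(r$conf.low < 0.02 && r$conf.high > 0.02)
})

test_that("zero events give rate zero with a zero lower bound", {
  ev <- basic_patient("a")
  r <- estimate_annual_rate(ev, "infection")
  expect_equal(r$rate, 0)
  expect_equal(r$conf.low, 0)
  r2 <- estimate_annual_rate(ev, "ecg")
  expect_equal(r2$rate, 0)
  expect_equal(r2$conf.low, 0)
})

test_that("zero person-years is an error", {
  ev <- dplyr::bind_rows(
    ev_row("a", "chs", -10),
    ev_row("a", "ppm_implant", 0)
  )
  expect_error(estimate_annual_rate(ev, "infection"), "person-years")
})

test_that("rate estimation ignores patient labels and row order", {
  cfg <- generator_config(n_patients = 400, horizon = 10, seed = 5)
  ev <- generate_events(cfg)
  base <- estimate_annual_rate(ev, "generator_change")
  shuffled <- ev[sample.int(nrow(ev)), ]
  relabeled <- dplyr::mutate(
    shuffled, patient_id = paste0("X", patient_id))
  again <- estimate_annual_rate(relabeled, "generator_change")
  expect_equal(again$rate, base$rate)
  expect_equal(again$person_years, base$person_years)
})

test_that("event summaries use sample SD with the n-1 denominator", {
  two <- dplyr::bind_rows(
    ev_row("a", "infection", 100, los = 2, direct = 10, indirect = 1),
    ev_row("b", "infection", 200, los = 4, direct = 30, indirect = 3)
  )
  s <- summarize_event(two, "infection")
  expect_equal(s$los_mean, 3)
  expect_equal(s$los_sd, sqrt(2))
  expect_equal(s$direct_mean, 20)
  expect_equal(s$direct_sd, sqrt(200))
  one <- ev_row("a", "holter", 10, los = 5, direct = 963, indirect = 136)
  expect_message(s1 <- summarize_event(one, "holter"), "single")
  expect_equal(s1$los_mean, 5)
  expect_equal(s1$los_sd, 0)
  expect_error(summarize_event(two, "ecg"), "no 'ecg' events")
})

test_that("the charge-on-LOS regression recovers an exact line", {
  ev <- purrr::map_dfr(1:5, function(i) {
    ev_row(paste0("p", i), "infection", i * 100, los = i,
           direct = 1000 + 500 * i)
  })
  fit <- fit_los_cost_regression(ev, "infection")
  expect_equal(fit$slope, 500, tolerance = 1e-10)
  expect_equal(fit$intercept, 1000, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(tidy(fit)$estimate, c(1000, 500), tolerance = 1e-10)
  expect_equal(glance(fit)$nobs, 5)
})

test_that("degenerate regression designs are rejected", {
  same_los <- purrr::map_dfr(1:5, function(i) {
    ev_row(paste0("p", i), "ecg", i, los = 0.125, direct = 100 + i)
  })
  expect_error(fit_los_cost_regression(same_los, "ecg"), "degenerate")
  expect_error(fit_los_cost_regression(same_los[1:2, ], "ecg"), ">= 3")
})

test_that("the indirect model interpolates two points exactly", {
  m <- fit_indirect_model(c(0, 1), c(100, 700))
  expect_equal(m$per_visit, 100, tolerance = 1e-12)
  expect_equal(m$per_day, 600, tolerance = 1e-12)
  expect_equal(predict(m, 2), 1300)
})

test_that("the indirect model matches a normal-equations oracle on the reference rows", {
  los <- c(13.005, 3.156, 0.322, 12.679, 0.125, 1.0)
  ind <- c(7338, 1792, 355, 7154, 136, 578)
  X <- cbind(1, los)
  oracle <- solve(t(X) %*% X, t(X) %*% ind)
  m <- fit_indirect_model(los, ind)
  expect_equal(m$per_visit, oracle[1], tolerance = 1e-10)
  expect_equal(m$per_day, oracle[2], tolerance = 1e-10)
})

test_that("flat indirect costs give a zero per-day rate", {
  m <- fit_indirect_model(c(0.125, 1, 5), c(136, 136, 136))
  expect_equal(m$per_day, 0, tolerance = 1e-12)
  expect_equal(m$per_visit, 136, tolerance = 1e-12)
})

test_that("a negative per-visit intercept is clipped with a warning", {
  expect_warning(m <- fit_indirect_model(c(1, 2, 3), c(0, 600, 1200)),
                 "clipped")
  expect_equal(m$per_visit, 0)
  expect_error(fit_indirect_model(c(1, 1), c(1, 2)), "distinct LOS")
})

test_that("estimation recovers generating rates on a moderate synthetic cohort", {
  cfg <- generator_config(n_patients = 2000, horizon = 10, seed = 8)
  ev <- generate_events(cfg)
  est <- estimate_cost_parameters(select_study_cohort(ev),
                                  discount_rate = 0.03, horizon = 10)
  p <- ppm_cost_parameters()
  py <- sum(person_years(ev)$person_years)
  for (e in c("generator_change", "clinic_visit", "ecg")) {
    want <- p$annual_rate[p$event == e]
    got <- est$annual_rate[est$event == e]
    se <- sqrt(want / py)
    expect_lt(abs(got - want), 3 * se)
  }
  expect_s3_class(est, "cost_parameters")
  expect_equal(attr(est, "horizon"), 10)
})
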