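test_that("same seed gives bit-identical cohorts", {
  cfg <- scenario_config(n_subjects = 6, n_visits = 5, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(scenario_config(n_subjects = 6, n_visits = 5,
                                       seed = 124))
  expect_false(identical(a$samples$hb, c$samples$hb))
})

test_that("with all variance sources off, [Hb] is constant within subject", {
  cfg <- scenario_config(n_subjects = 5, n_visits = 6, seed = 2,
                         pv_cv = 0, analytic_cv = 0, ret_bio_cv = 0,
                         pv_measured_cv = 0)
  co <- generate_cohort(cfg)
  spread <- tapply(co$samples$hb, co$samples$subject_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("mass conservation holds exactly pre-noise", {
  co <- generate_cohort(scenario_config(n_subjects = 10, n_visits = 6,
                                        seed = 3))
  bv <- co$truth$pv_true + co$truth$rcv_true
  expect_lt(max(abs(co$truth$hb_prenoise - 100 * co$truth$hbmass_true / bv)),
            1e-9)
})

test_that("derived CBC indices are mutually consistent", {
  co <- generate_cohort(scenario_config(n_subjects = 10, n_visits = 6,
                                        seed = 4))
  s <- co$samples
  # the analyzer derives HCT and MCHC, so these identities are exact even
  # with analytic noise on the measured channels
  expect_equal(s$hct, s$rbc * s$mcv / 10, tolerance = 1e-12)
  expect_equal(s$mchc, 100 * s$hb / s$hct, tolerance = 1e-12)
})

test_that("a single pure-PV event dilutes [Hb] by the mass-balance factor", {
  cfg <- scenario_config(
    n_subjects = 4, n_visits = 4, seed = 5,
    pv_cv = 0, analytic_cv = 0, ret_bio_cv = 0, pv_measured_cv = 0,
    events = data.frame(visit = 3, kind = "hyperhydration",
                        magnitude = 0.10)
  )
  co <- generate_cohort(cfg)
  for (sid in unique(co$truth$subject_id)) {
    tr <- co$truth[co$truth$subject_id == sid, ]
    s <- co$samples[co$samples$subject_id == sid, ]
    pv0 <- tr$pv_true[2]
    expect_equal(tr$pv_true[3], 1.1 * pv0, tolerance = 1e-12)
    expect_identical(tr$hbmass_true[3], tr$hbmass_true[2]) # Hbmass constant
    bv0 <- pv0 + tr$rcv_true[2]
    drop_expected <- 1 - bv0 / (bv0 + 0.1 * pv0)
    expect_equal(1 - s$hb[3] / s$hb[2], drop_expected, tolerance = 1e-10)
  }
})

test_that("event templates follow their definitions", {
  truth <- tibble::tibble(
    subject_id = "x", visit_index = 1:6,
    pv_true = rep(3000, 6), hbmass_true = rep(800, 6),
    ret_mult = rep(1, 6), mchc0 = 34
  )
  hyper <- inject_event(truth, 3, "hyperhydration", 0.10)
  expect_equal(hyper$pv_true, c(3000, 3000, 3300, 3000, 3000, 3000))
  expect_identical(hyper$hbmass_true, truth$hbmass_true)

  trans <- inject_event(truth, 4, "transfusion", 0.10)
  expect_equal(trans$hbmass_true, c(800, 800, 800, 880, 880, 880))
  expect_identical(trans$pv_true, truth$pv_true)
  expect_true(all(trans$ret_mult[4:6] < 1)) # post-transfusion RET% dip

  exercise <- inject_event(truth, 2, "exercise_hemoconcentration", 0.08)
  expect_equal(exercise$pv_true[2], 3000 * 0.92)
  expect_equal(exercise$pv_true[3], 3000)

  alt <- inject_event(truth, 2, "altitude", 0.05, altitude_ramp = 0.03,
                      ramp_visits = 3)
  expect_equal(alt$pv_true[2:6], rep(3000 * 0.95, 5))
  expect_equal(alt$hbmass_true[2], 800)               # ramp starts at 0
  expect_equal(alt$hbmass_true[5], 800 * 1.03)        # plateau reached
  expect_true(all(diff(alt$hbmass_true[2:5]) > 0))

  epo <- inject_event(truth, 2, "rhEPO", 0.06, rhepo_ret_multiplier = 2,
                      rhepo_duration = 2, ramp_visits = 3)
  expect_equal(epo$ret_mult[2:3], c(2, 2))
  expect_equal(epo$ret_mult[4], 1)
  expect_equal(epo$hbmass_true[5], 800 * 1.06)

  expect_identical(inject_event(truth, 3, "transfusion", 0), truth)
  expect_error(inject_event(truth, 3, "sauna", 0.1), "arg")
  expect_error(inject_event(truth, 99, "altitude", 0.1), "not in truth")
})

test_that("scenario validation rejects out-of-range events", {
  ev <- data.frame(visit = 20, kind = "altitude", magnitude = 0.1)
  expect_error(scenario_config(n_visits = 12, events = ev), "visit index")
  ev2 <- data.frame(visit = 3, kind = "hyperhydration", magnitude = 0.4)
  expect_error(scenario_config(events = ev2), "capped at 0.25")
  ev3 <- data.frame(visit = 3, kind = "hot_yoga", magnitude = 0.1)
  expect_error(scenario_config(events = ev3), "unknown event kind")
})

test_that("per-sex [Hb] means land on the configured baselines", {
  co <- generate_cohort(scenario_config(n_subjects = 1000, n_visits = 1,
                                        seed = 42))
  s <- co$samples
  for (cfg in list(list(sex = "male", mu = 15.2),
                   list(sex = "female", mu = 13.4))) {
    x <- s$hb[s$sex == cfg$sex]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$mu), 2 * se + 0.05)
  }
})

test_that("generated cohorts satisfy the CBC contract", {
  co <- generate_cohort(scenario_config(n_subjects = 30, n_visits = 12,
                                        seed = 77))
  expect_silent(validate_cbc(co$samples))
  expect_equal(nrow(co$samples), 30 * 12)
  expect_identical(co$samples[c("subject_id", "visit_index")],
                   co$truth[c("subject_id", "visit_index")])
})
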