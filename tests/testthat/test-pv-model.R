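test_that("a realizable linear law is recovered exactly from noise-free data", {
  samples <- linear_world_samples()
  fit <- train_pv_model(samples, regressor = "linear")
  pred <- estimate_pv(fit, samples)
  expect_lt(max(abs(pred - samples$pv_measured)), 1e-6) # well under 1 mL

  # weight is uninformative by construction: weight-free fit is identical
  fit_wf <- train_pv_model(samples, regressor = "linear",
                           weight_free = TRUE)
  expect_false("weight" %in% fit_wf$features)
  expect_equal(estimate_pv(fit_wf, samples), pred, tolerance = 1e-8)
})

test_that("estimation is a hand-computable dot product for a linear stub", {
  stub <- linear_pv_model(
    intercept = 500,
    coefficients = c(hb = -100, hct = -20, sex_male = 300, weight = 40)
  )
  s <- tibble::tibble(hb = 15, hct = 44, sex = "male", weight = 70)
  expect_equal(estimate_pv(stub, s), 500 - 1500 - 880 + 300 + 2800)
  # duplicated input row gives the identical estimate
  expect_equal(estimate_pv(stub, dplyr::bind_rows(s, s)),
               rep(estimate_pv(stub, s), 2))
})

test_that("contract errors name the offending input", {
  samples <- linear_world_samples()
  fit <- train_pv_model(samples, regressor = "linear")
  expect_error(estimate_pv(fit, samples[, setdiff(names(samples), "hct")]),
               "hct")
  na_samples <- samples
  na_samples$rbc[3] <- NA
  expect_error(estimate_pv(fit, na_samples), "rbc")
  expect_error(train_pv_model(samples[1:10, ], regressor = "linear"),
               "fewer than 30")
  no_pv <- samples
  no_pv$pv_measured <- NULL
  expect_error(train_pv_model(no_pv), "pv_measured")
  unfitted <- structure(list(regressor = "linear", coefs = NULL,
                             fit = NULL), class = "pv_model")
  expect_error(estimate_pv(unfitted, samples), "not fitted")
})

test_that("model artifacts round-trip through a file", {
  fit <- train_pv_model(linear_world_samples(), regressor = "linear")
  path <- withr::local_tempfile(fileext = ".rds")
  write_pv_model(fit, path)
  back <- read_pv_model(path)
  expect_equal(estimate_pv(back, linear_world_samples()),
               estimate_pv(fit, linear_world_samples()))
})

test_that("sensitivity grid has the closed form for a linear regressor", {
  stub <- linear_pv_model(intercept = 6000, coefficients = c(hb = -150))
  samples <- linear_world_samples()
  grid <- sensitivity_analysis(stub, samples,
                               levels = c(-0.1, 0, 0.1),
                               markers = "hb")
  # cell(hb, +0.1%) = beta * 0.001 * mean(hb)
  expect_equal(grid$hb[grid$level == 0.1], -150 * 0.001 * mean(samples$hb),
               tolerance = 1e-10)
  expect_equal(grid$hb[grid$level == -0.1], 150 * 0.001 * mean(samples$hb),
               tolerance = 1e-10)
  expect_identical(grid$hb[grid$level == 0], 0) # zero perturbation: exact 0

  # constant-output stub: no feature dependence, all cells 0
  const <- linear_pv_model(intercept = 3000, coefficients = c(hb = 0))
  g0 <- sensitivity_analysis(const, samples, markers = "hb")
  expect_true(all(g0$hb == 0))

  expect_error(sensitivity_analysis(stub, samples, markers = "albumin"),
               "unknown marker")
})

test_that("sensitivity cells scale linearly in the perturbation level", {
  co <- generate_cohort(scenario_config(n_subjects = 20, n_visits = 6,
                                        seed = 5))
  tr <- co$samples
  tr$pv_measured <- co$truth$pv_true
  fit <- train_pv_model(tr, regressor = "linear")
  grid <- sensitivity_analysis(fit, tr, levels = c(0.05, 0.2))
  for (m in setdiff(names(grid), "level")) {
    cells <- grid[[m]]
    expect_equal(cells[2] / cells[1], 4, tolerance = 1e-6)
  }
})

test_that("validation report covers the canonical agreement cases", {
  set.seed(8)
  measured <- rnorm(40, 3000, 300)
  sex <- rep(c("male", "female"), 20)

  identity <- validate_pv_model(measured, measured, sex)
  all_row <- identity[identity$group == "all", ]
  expect_equal(all_row$spearman_r, 1)
  expect_equal(all_row$bias_ml, 0)
  expect_equal(all_row$loa_lower_ml, 0)
  expect_true(all(c("male", "female") %in% identity$group))

  offset <- validate_pv_model(measured + 100, measured)
  expect_equal(offset$spearman_r[1], 1)
  expect_equal(offset$bias_ml[1], 100)

  reversed <- validate_pv_model(sort(measured), rev(sort(measured)))
  expect_equal(reversed$spearman_r[1], -1)

  flat <- validate_pv_model(rep(3000, 10), measured[1:10])
  expect_true(is.na(flat$spearman_r[1])) # constant series: r undefined

  expect_error(validate_pv_model(1:5, 1:4), "equal length")
  expect_error(validate_pv_model(1:2, 1:2), "at least 3")
})

test_that("weighting index is the squared Pearson correlation (R^2)", {
  set.seed(9)
  pv <- rnorm(50, 3000, 250)
  expect_equal(weighting_index(pv, 20 - 0.002 * pv), 1, tolerance = 1e-12)

  hb <- rnorm(50, 14, 1)
  # oracle: R^2 from an explicit simple linear regression, either way round
  expect_equal(weighting_index(pv, hb),
               summary(lm(pv ~ hb))$r.squared, tolerance = 1e-12)
  expect_equal(weighting_index(pv, hb),
               summary(lm(hb ~ pv))$r.squared, tolerance = 1e-12)

  # independent pairs: R^2 near 0
  pv_big <- rnorm(1e4, 3000, 250)
  hb_big <- rnorm(1e4, 14, 1)
  expect_lt(weighting_index(pv_big, hb_big), 0.01)

  expect_error(weighting_index(rep(3000, 10), rnorm(10)), "degenerate")
  expect_equal(default_weighting(), c(male = 0.28, female = 0.42))
})

test_that("ridge and gam regressors train and predict deterministically", {
  co <- generate_cohort(scenario_config(n_subjects = 15, n_visits = 4,
                                        seed = 6))
  tr <- co$samples
  tr$pv_measured <- co$truth$pv_true
  for (k in c("ridge", "gam")) {
    f1 <- train_pv_model(tr, regressor = k)
    f2 <- train_pv_model(tr, regressor = k)
    p1 <- estimate_pv(f1, tr)
    expect_identical(p1, estimate_pv(f2, tr))
    expect_true(all(p1 > 0))
    expect_lt(cor(p1, tr$pv_measured), 1 + 1e-9)
  }
})
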