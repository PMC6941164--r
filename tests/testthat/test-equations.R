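table3_means <- tibble::tibble(
  experiment_id = "E1", treatment_id = "T1", cow_id = "C1",
  acetate = 63.3, propionate = 20.2, butyrate = 9.9, methane_yield = 20.7)

test_that("stoichiometric fermentation balance matches hand arithmetic", {
  expect_equal(stoichiometric_methane(1, 1, 1), 0.75)
  expect_equal(stoichiometric_methane(0, 0, 0), 0)
  # at the development-data mean proportions: methane yield per 100 mol VFA
  expect_equal(stoichiometric_methane(63.3, 20.2, 9.9), 31.55)
  expect_error(stoichiometric_methane(-1, 0, 0), "non-negative")
  expect_warning(out <- stoichiometric_methane(1, 10, 0), "negative")
  expect_equal(out, -2)
})

test_that("design vectors follow the declared covariate transforms", {
  expect_equal(unname(design_matrix("M4", table3_means)[1, ]),
               c(3.6237624, 1), tolerance = 1e-7)
  expect_equal(unname(design_matrix("M7", table3_means)[1, ]),
               c(0.04950495, 1), tolerance = 1e-6)
  expect_equal(unname(design_matrix("M1c", table3_means)[1, ]),
               5.048, tolerance = 1e-9)
  # M2 carries minus-propionate so all printed coefficients are positive
  expect_equal(unname(design_matrix("M2", table3_means)[1, ]),
               c(63.3, -20.2, 9.9))
  expect_error(design_matrix("M6", table3_means), "propionate_conc")
  expect_error(model_form("M9"), "unknown model form")
})

test_that("published equations predict the frozen hand-oracle values", {
  expect_equal(predict(published_equation("M4"), table3_means),
               19.4859406, tolerance = 1e-6)
  expect_equal(predict(published_equation("M7"), table3_means),
               20.0435644, tolerance = 1e-6)
  expect_equal(predict(published_equation("M1c"), table3_means),
               20.09104, tolerance = 1e-6)
})

test_that("the registry returns the published estimates verbatim", {
  m3 <- published_equation("M3")
  expect_equal(unname(m3$coefficients), c(4.08, 7.05))
  expect_equal(unname(m3$standard_errors), c(0.36, 1.40))
  m1 <- published_equation("M1c")
  expect_equal(unname(m1$coefficients), 3.98)
  expect_equal(unname(m1$standard_errors), 0.15)
  m6 <- published_equation("M6")
  expect_equal(unname(m6$coefficients), c(-0.24, 26.1))
  # variance components are only reported for the three best forms
  for (id in c("M3", "M4", "M7")) {
    expect_equal(unname(published_equation(id)$variance_components),
                 c(1.7, 1.5, 6.9))
  }
  for (id in c("M1c", "M2", "M5", "M6")) {
    expect_true(all(is.na(published_equation(id)$variance_components)))
  }
  expect_identical(m3$source, "published")
})

test_that("predictions agree with explicit formulas on random profiles", {
  set.seed(19)
  prof <- random_profiles(1000)
  prof$experiment_id <- "E1"; prof$treatment_id <- "T1"
  prof$cow_id <- sprintf("C%04d", seq_len(nrow(prof)))
  for (id in model_forms()) {
    eq <- published_equation(id)
    coefs <- unname(eq$coefficients)
    # undo the structural minus sign for the M2 oracle formula
    oracle_coefs <- if (id == "M2") coefs * c(1, 1, 1) else coefs
    expect_equal(predict(eq, prof),
                 oracle_predict(id, prof, oracle_coefs),
                 tolerance = 1e-10, info = id)
  }
})

test_that("prediction is linear in the coefficients", {
  set.seed(7)
  prof <- random_profiles(50)
  prof$experiment_id <- "E1"; prof$treatment_id <- "T1"
  prof$cow_id <- sprintf("C%02d", 1:50)
  for (id in c("M1c", "M3", "M4")) {
    form <- model_form(id)
    n_par <- length(form$covariates) + form$has_intercept
    b1 <- runif(n_par, -2, 2); b2 <- runif(n_par, -2, 2)
    p1 <- predict(vfa_equation(form, b1), prof)
    p2 <- predict(vfa_equation(form, b2), prof)
    p12 <- predict(vfa_equation(form, 2 * b1 + 3 * b2), prof)
    expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-10)
  }
})

test_that("the proportion-based balance equals the quantity balance per 100 mol", {
  # dividing the mole-quantity balance by 100 mol total VFA gives the
  # yield form evaluated at the proportions; the stoichiometric design
  # column is that yield scaled by methane's molar mass over 100
  set.seed(3)
  prof <- random_profiles(100)
  ch4y <- stoichiometric_methane(prof$acetate, prof$propionate, prof$butyrate)
  prof$experiment_id <- "E1"; prof$treatment_id <- "T1"
  prof$cow_id <- sprintf("C%03d", 1:100)
  expect_equal(design_matrix("M1c", prof)[, "stoich"], 16 * ch4y / 100,
               tolerance = 1e-12)
})

test_that("ratio-form predictions decrease in propionate and floor at the intercept", {
  grid <- tibble::tibble(
    experiment_id = "E1", treatment_id = "T1",
    cow_id = sprintf("C%02d", 1:20),
    acetate = 60, butyrate = 10,
    propionate = seq(13, 29.9, length.out = 20),
    methane_yield = 20)
  for (id in c("M3", "M4", "M7")) {
    pred <- predict(published_equation(id), grid)
    expect_true(all(diff(pred) < 0), info = id)
    intercept <- unname(published_equation(id)$coefficients[2])
    expect_true(all(pred > intercept), info = id)
  }
  # the M7 prediction exceeds its intercept by exactly s/P, which vanishes
  # as propionate grows: the intercept is the smallest attainable yield
  m7 <- published_equation("M7")
  excess <- predict(m7, grid) - m7$coefficients[[2]]
  expect_equal(unname(excess), 316 / grid$propionate, tolerance = 1e-10)
})

test_that("equation containers enforce their shape", {
  expect_error(vfa_equation("M3", coefficients = 1), "2 coefficient")
  expect_error(vfa_equation("M3", c(1, 2),
                            variance_components = c(experiment = -1,
                                                    treatment = 0, cow = 1)),
               "non-negative")
})

test_that("broom methods and JSON serialisation expose the fit", {
  eq <- published_equation("M4")
  td <- tidy(eq)
  expect_equal(td$estimate, c(3.28, 7.60))
  gl <- glance(eq)
  expect_equal(gl$sigma2_cow, 6.9)
  aug <- augment(eq, table3_means)
  expect_equal(aug$.fitted, 19.4859406, tolerance = 1e-6)
  expect_equal(aug$.resid, 20.7 - 19.4859406, tolerance = 1e-6)

  parsed <- jsonlite::fromJSON(equation_to_json(eq))
  expect_equal(parsed$form_id, "M4")
  expect_equal(parsed$coefficients$`(Intercept)`, 7.60)
  expect_equal(parsed$variance_components$cow, 6.9)
})
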