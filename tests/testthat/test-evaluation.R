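test_that("rmsep matches hand arithmetic and a brute-force oracle", {
  expect_equal(rmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsep(c(1, 2, 3), c(2, 2, 2)), 0.8164966, tolerance = 1e-6)
  set.seed(4)
  obs <- rnorm(10, 20, 4); pred <- rnorm(10, 20, 4)
  expect_equal(rmsep(obs, pred), oracle_rmsep(obs, pred), tolerance = 1e-12)
  expect_error(rmsep(1:3, 1:2), "equal length")
  expect_error(rmsep(numeric(), numeric()), "at least 1")
})

test_that("Lin's concordance matches its definition and limits", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  # 2*(2/3) / (2/3 + 2/3 + 1) = 4/7
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-9)
  expect_error(lin_ccc(c(1, 1), c(2, 2)), "constant")
  set.seed(8)
  for (i in 1:20) {
    obs <- rnorm(25, 20, 5); pred <- obs * runif(1, 0.5, 1.5) + rnorm(25)
    expect_equal(lin_ccc(obs, pred), oracle_ccc(obs, pred),
                 tolerance = 1e-10)
    expect_gte(lin_ccc(obs, pred), -1)
    expect_lte(lin_ccc(obs, pred), 1)
  }
})

test_that("concordance is bounded by correlation and equals it when moments match", {
  set.seed(12)
  for (i in 1:20) {
    obs <- rnorm(30, 20, 5)
    pred <- 0.8 * obs + rnorm(30, sd = 2) + runif(1, -3, 3)
    expect_lte(abs(lin_ccc(obs, pred)), abs(pearson_r(obs, pred)) + 1e-12)
  }
  # equal means and variances: ccc collapses to r
  obs <- rnorm(100, 20, 5)
  pred <- rev(obs)  # same marginal moments by construction
  expect_equal(lin_ccc(obs, pred), pearson_r(obs, pred), tolerance = 1e-12)
})

test_that("pearson_r is the product-moment correlation", {
  x <- seq(1, 10)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(15)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
})

test_that("the MSEP decomposition matches hand arithmetic and sums exactly", {
  expect_equal(unname(msep_decomposition(c(0, 2), c(0, 1))),
               c(0.25, 0.25, 0))
  ident <- msep_decomposition(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ident), c(0, 0, 0))
  set.seed(23)
  for (i in 1:50) {
    obs <- rnorm(sample(5:40, 1), 20, 5)
    pred <- 0.7 * obs + rnorm(length(obs), sd = 3) + 1
    comp <- msep_decomposition(obs, pred)
    expect_true(all(comp >= 0))
    expect_equal(sum(comp), mean((obs - pred)^2), tolerance = 1e-9)
    expect_equal(comp, oracle_msep_components(obs, pred), tolerance = 1e-10)
  }
  expect_error(msep_decomposition(rep(2, 4), rnorm(4)), "constant")
})

test_that("published validation tables are internally consistent", {
  # individual-cow external validation: components recombine to the RMSEP
  expect_equal(round(rmsep_from_components(3.3, 0.47, 9.3), 2), 3.62)
  # treatment-mean external validation
  expect_equal(round(rmsep_from_components(0.62, 0.20, 8.1), 2), 2.99)
  # variance components: lack-of-fit and animal standard deviations
  sds <- variance_component_sds(published_equation("M4"))
  expect_equal(round(sds[["lack_of_fit_sd"]], 1), 1.8)
  expect_equal(round(sds[["animal_sd"]], 1), 2.6)
})

test_that("evaluate_predictions bundles the statistics coherently", {
  set.seed(2)
  obs <- rnorm(40, 20, 4); pred <- obs + rnorm(40, 1, 2)
  ev <- evaluate_predictions(obs, pred)
  expect_equal(ev$msep, ev$rmsep^2, tolerance = 1e-12)
  expect_equal(ev$ect + ev$er + ev$ed, ev$msep, tolerance = 1e-9)
  expect_equal(ev$n, 40L)
})

test_that("external validation isolates the error sources by construction", {
  # correctly specified: only cow-level noise, no mean or slope bias
  cfg <- simulation_config(
    n_experiments = 2, treatments_per_experiment = c(2, 2),
    cows_per_treatment = list(c(60, 60), c(60, 60)),
    variance_components = c(experiment = 0, treatment = 0, cow = 6.9),
    seed = 77)
  d <- simulate_dataset(cfg)
  ev <- external_validate(published_equation("M4"), d)
  expect_lt(ev$ect, 0.6)
  expect_lt(ev$er, 0.6)
  expect_gt(ev$ed, 4)
  # constant +1 shift in the observations: pure error of central tendency
  shifted <- make_fixture("shifted_bias")
  ev2 <- external_validate(published_equation("M4"), shifted)
  expect_equal(ev2$ect, 1, tolerance = 1e-9)
  expect_equal(ev2$er, 0, tolerance = 1e-9)
  expect_equal(ev2$ed, 0, tolerance = 1e-9)
})

test_that("model ranking uses rounded competition ranks", {
  m <- tibble::tibble(form_id = c("A", "B", "C"),
                      rmsep = c(3.24, 3.21, 3.17),
                      ccc = c(0.69, 0.70, 0.70))
  r <- rank_models(m)
  expect_equal(r$rank, c(1L, 1L, 1L))
  m2 <- tibble::tibble(form_id = letters[1:4],
                       rmsep = c(1, 2, 2, 3), ccc = rep(0.5, 4))
  expect_equal(rank_models(m2)$rank, c(1L, 2L, 2L, 4L))
  single <- rank_models(tibble::tibble(form_id = "A", rmsep = 3, ccc = 0.5))
  expect_equal(single$rank, 1L)
  expect_error(rank_models(m[0, ]), "no evaluated")
})

test_that("cross-validation of a noiseless truth is perfect", {
  d <- make_fixture("noiseless_m3")
  d2 <- d[d$experiment_id %in% c("E1", "E2"), ]
  cv <- loeo_crossval(d2, forms = "M3")
  expect_lt(cv$metrics$rmsep, 1e-8)
  expect_equal(cv$metrics$ccc, 1, tolerance = 1e-8)
  expect_equal(cv$n_folds, 2L)
})

test_that("out-of-fold predictions are per-record and order-invariant", {
  d <- toy_dataset(n_exp = 3, n_trt = 2, n_cow = 4, seed = 44)
  cv <- loeo_crossval(d, forms = c("M3", "M4"))
  expect_equal(nrow(cv$predictions), 2 * nrow(d))
  expect_true(all(table(cv$predictions$form_id) == nrow(d)))
  # each record is predicted by the fold that withheld its experiment
  expect_identical(cv$predictions$fold, cv$predictions$experiment_id)

  set.seed(1)
  cv2 <- loeo_crossval(d[sample(nrow(d)), ], forms = c("M3", "M4"))
  a <- dplyr::arrange(cv$predictions, form_id, experiment_id, treatment_id,
                      cow_id)
  b <- dplyr::arrange(cv2$predictions, form_id, experiment_id, treatment_id,
                      cow_id)
  expect_equal(a$predicted, b$predicted, tolerance = 1e-6)
})

test_that("a failing form does not abort the others", {
  d <- toy_dataset(n_exp = 3, n_trt = 2, n_cow = 4, seed = 3)
  suppressWarnings(cv <- loeo_crossval(d, forms = c("M4", "M6")))
  expect_identical(names(cv$failed), "M6")
  expect_identical(cv$metrics$form_id, "M4")
  expect_error(loeo_crossval(d[d$experiment_id == "E1", ], forms = "M4"),
               "at least 2 experiments")
})

test_that("reports serialise losslessly", {
  d <- toy_dataset(n_exp = 3, n_trt = 2, n_cow = 4, seed = 6)
  cv <- loeo_crossval(d, forms = c("M3", "M4", "M7"))
  json_path <- withr::local_tempfile(fileext = ".json")
  crossval_to_json(cv, json_path)
  parsed <- jsonlite::fromJSON(json_path)
  expect_equal(parsed$metrics$rmsep, cv$metrics$rmsep, tolerance = 1e-12)
  expect_equal(parsed$metrics$form_id, cv$metrics$form_id)

  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_crossval_predictions(cv, csv_path)
  back <- readr::read_csv(csv_path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cv$predictions))
  expect_equal(back$predicted, cv$predictions$predicted, tolerance = 1e-9)

  tbl_path <- withr::local_tempfile(fileext = ".csv")
  report_crossval(cv, tbl_path)
  tbl <- readr::read_csv(tbl_path, show_col_types = FALSE)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$rmsep, round(cv$metrics$rmsep, 1))
  expect_equal(tbl$ccc, round(cv$metrics$ccc, 2))
  expect_equal(tbl$rank, cv$metrics$rank)
})
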