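# Validation statistics and the leave-one-experiment-out cross-validation
# harness.

.check_pairs <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in observed/predicted", call. = FALSE)
  }
}

#' Root-mean-square error of prediction
#'
#' `sqrt(mean((observed - predicted)^2))`, interpretable as an average
#' standard deviation of prediction.
#'
#' @param observed,predicted Numeric vectors of equal, nonzero length.
#' @return A single number in the units of the observations.
#' @export
#' @examples
#' rmsep(c(1, 2, 3), c(2, 2, 2))
rmsep <- function(observed, predicted) {
  .check_pairs(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

#' Pearson product-moment correlation
#'
#' Thin, argument-checked wrapper over [stats::cor()]: errors (rather than
#' returning `NA`) when either series is constant.
#'
#' @param x,y Numeric vectors of equal length >= 2, both non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  .check_pairs(x, y, min_n = 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two series with respect to the 1:1 line:
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (divide-by-n) moments, per Lin's original definition; this guarantees a
#' value in \[-1, 1\] and exact consistency with the MSEP decomposition.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2; at least
#'   one non-constant.
#' @return Concordance in \[-1, 1\].
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))
lin_ccc <- function(observed, predicted) {
  .check_pairs(observed, predicted, min_n = 2)
  n <- length(observed)
  mo <- mean(observed); mp <- mean(predicted)
  so2 <- mean((observed - mo)^2)
  sp2 <- mean((predicted - mp)^2)
  if (so2 == 0 && sp2 == 0) {
    stop("concordance undefined: both series are constant", call. = FALSE)
  }
  sop <- mean((observed - mo) * (predicted - mp))
  2 * sop / (so2 + sp2 + (mo - mp)^2)
}

#' Decompose the mean squared error of prediction
#'
#' Partitions MSEP = mean((observed - predicted)^2) into three non-negative,
#' exactly additive components (population moments, r the Pearson
#' correlation, s the population standard deviations):
#'
#' * error of central tendency (squared mean bias): `(mean_p - mean_o)^2`;
#' * error due to regression (non-unity slope): `(s_p - r * s_o)^2`;
#' * error of disturbance (lack of correlation): `(1 - r^2) * s_o^2`.
#'
#' The orientation places the correlation factor on the predicted-series
#' standard deviation and expresses the disturbance in observed-variance
#' units; the sum identity holds algebraically either way.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2; the
#'   observed series must not be constant.
#' @return Named numeric vector `c(ect =, er =, ed =)` summing to MSEP.
#' @export
#' @examples
#' msep_decomposition(c(0, 2), c(0, 1))  # c(0.25, 0.25, 0)
msep_decomposition <- function(observed, predicted) {
  .check_pairs(observed, predicted, min_n = 2)
  mo <- mean(observed); mp <- mean(predicted)
  so <- sqrt(mean((observed - mo)^2))
  sp <- sqrt(mean((predicted - mp)^2))
  if (so == 0 || sp == 0) {
    stop("decomposition undefined for a constant series", call. = FALSE)
  }
  r <- stats::cor(observed, predicted)
  c(ect = (mp - mo)^2, er = (sp - r * so)^2, ed = (1 - r^2) * so^2)
}

#' RMSEP from published MSEP components
#'
#' Recombines an error-of-central-tendency / error-due-to-regression /
#' error-of-disturbance triple into the RMSEP they decompose:
#' `sqrt(ect + er + ed)`. Useful for checking the internal consistency of
#' reported validation tables.
#'
#' @param ect,er,ed Non-negative components of MSEP.
#' @return RMSEP, same units as the observations.
#' @export
rmsep_from_components <- function(ect, er, ed) {
  stopifnot(ect >= 0, er >= 0, ed >= 0)
  sqrt(ect + er + ed)
}

#' Standard deviations implied by the variance components
#'
#' From the three variance components of the mixed model, the lack-of-fit
#' standard deviation associated with feed type and context
#' (`sqrt(experiment + treatment)`) and the animal/measurement standard
#' deviation (`sqrt(cow)`).
#'
#' @param eq A `vfa_equation` carrying variance components, or a named
#'   numeric vector `c(experiment=, treatment=, cow=)`.
#' @return Named numeric `c(lack_of_fit_sd =, animal_sd =)`, g CH4/kg DMI.
#' @export
#' @examples
#' variance_component_sds(published_equation("M4"))
variance_component_sds <- function(eq) {
  vc <- if (inherits(eq, "vfa_equation")) eq$variance_components else eq
  c(lack_of_fit_sd = sqrt(vc[["experiment"]] + vc[["treatment"]]),
    animal_sd = sqrt(vc[["cow"]]))
}

#' Agreement statistics for a set of predictions
#'
#' Bundles the validation statistics for one (observed, predicted) set:
#' RMSEP, its square MSEP, Lin's concordance, the Pearson correlation and
#' the three MSEP components (which sum to MSEP exactly).
#'
#' @inheritParams msep_decomposition
#' @return One-row tibble with columns `n`, `rmsep`, `msep`, `ccc`, `r`,
#'   `ect`, `er`, `ed`.
#' @export
evaluate_predictions <- function(observed, predicted) {
  .check_pairs(observed, predicted, min_n = 2)
  comp <- msep_decomposition(observed, predicted)
  tibble::tibble(
    n = length(observed),
    rmsep = rmsep(observed, predicted),
    msep = rmsep(observed, predicted)^2,
    ccc = lin_ccc(observed, predicted),
    r = pearson_r(observed, predicted),
    ect = comp[["ect"]], er = comp[["er"]], ed = comp[["ed"]]
  )
}

#' Validate an equation on external data
#'
#' Predicts every record of `data` with the (fixed effects of the) equation
#' and returns the agreement statistics against the observed methane yield.
#'
#' @param eq A `vfa_equation` (fitted or published).
#' @param data A valid dataset with observed `methane_yield`.
#' @return One-row tibble as [evaluate_predictions()], plus `form_id`.
#' @export
#' @examples
#' d <- make_fixture("tiny_2exp")
#' external_validate(published_equation("M4"), d)
external_validate <- function(eq, data) {
  stopifnot(inherits(eq, "vfa_equation"))
  data <- validate_vfa_data(data)
  pred <- predict(eq, data)
  out <- evaluate_predictions(data$methane_yield, pred)
  dplyr::bind_cols(tibble::tibble(form_id = eq$form$form_id), out)
}

#' Rank models on rounded cross-validation statistics
#'
#' Competition ranking (ties share the minimum rank) on the key
#' (RMSEP rounded to 0.1 g/kg DMI, then -CCC rounded to 0.1): models whose
#' statistics agree at the precision of a results table share a rank, so
#' models differing by one concordance point in the second decimal are
#' treated as equally good. The unrounded statistics are kept alongside.
#'
#' @param metrics A tibble with columns `rmsep` and `ccc` (one row per
#'   model), e.g. the `metrics` element of [loeo_crossval()].
#' @return `metrics` with a `rank` integer column added (and rounded keys
#'   `rmsep_rounded`, `ccc_rounded`).
#' @export
rank_models <- function(metrics) {
  stopifnot(is.data.frame(metrics), all(c("rmsep", "ccc") %in% names(metrics)))
  if (nrow(metrics) == 0) stop("no evaluated models to rank", call. = FALSE)
  r1 <- round(metrics$rmsep, 1)
  c1 <- round(metrics$ccc, 1)
  key <- r1 * 100 - c1  # lexicographic: rmsep first, then larger ccc wins
  metrics$rmsep_rounded <- r1
  metrics$ccc_rounded <- c1
  metrics$rank <- as.integer(rank(key, ties.method = "min"))
  metrics
}

#' Leave-one-experiment-out cross-validation
#'
#' For each experiment in turn: withhold all its cows, fit every requested
#' model form on the remaining experiments by [fit_meta()], and predict the
#' withheld records from the fixed effects alone (random effects of an
#' unseen experiment have zero expectation). Out-of-fold predictions are
#' pooled over all experiments and summarised per form with
#' [evaluate_predictions()]; forms are then ranked with [rank_models()].
#' Each model is also refitted once to the pooled data, giving the
#' calibrated equation reported alongside the cross-validation statistics.
#'
#' @param data A valid dataset with records from >= 2 experiments.
#' @param forms Form identifiers to evaluate (default: all whose covariates
#'   the data supports).
#' @param options A [fit_options()] list.
#' @return An object of class `vfa_crossval`: a list with
#'   * `metrics` — tibble, one row per form (`form_id`, `n`, `rmsep`,
#'     `msep`, `ccc`, `r`, `ect`, `er`, `ed`, `rank`, rounded keys);
#'   * `predictions` — tibble of per-record out-of-fold predictions
#'     (identifiers, `fold`, `observed`, `predicted`, `form_id`);
#'   * `pooled` — named list of pooled-data `vfa_equation`s;
#'   * `failed` — named character of per-form failure messages;
#'   * `n_folds`, `options`.
#' @export
#' @examples
#' d <- make_fixture("tiny_2exp")
#' cv <- loeo_crossval(d, forms = c("M3", "M4"))
#' tidy(cv)
loeo_crossval <- function(data, forms = NULL, options = fit_options()) {
  data <- validate_vfa_data(data)
  counts <- .vfa_counts(data)
  if (counts$experiments < 2) {
    stop("cross-validation needs records from at least 2 experiments",
         call. = FALSE)
  }
  has_conc <- "propionate_conc" %in% names(data) &&
    !anyNA(data$propionate_conc)
  if (is.null(forms)) {
    forms <- model_forms()
    if (!has_conc) forms <- setdiff(forms, "M6")
  }
  forms <- vapply(forms, function(f) model_form(f)$form_id, character(1))

  exps <- sort(unique(as.character(data$experiment_id)))
  data$.row <- seq_len(nrow(data))

  failed <- character()
  pred_tbl <- list()
  metric_rows <- list()
  for (id in forms) {
    form <- model_form(id)
    preds <- rep(NA_real_, nrow(data))
    folds <- rep(NA_character_, nrow(data))
    err <- NULL
    for (ex in exps) {
      hold <- data$experiment_id == ex
      fit <- tryCatch(fit_meta(data[!hold, ], form, options),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        err <- sprintf("fold '%s': %s", ex, conditionMessage(fit))
        break
      }
      preds[hold] <- predict(fit, data[hold, ])
      folds[hold] <- ex
    }
    if (!is.null(err)) {
      failed[id] <- err
      next
    }
    pred_tbl[[id]] <- tibble::tibble(
      form_id = id,
      experiment_id = data$experiment_id,
      treatment_id = data$treatment_id,
      cow_id = data$cow_id,
      fold = folds,
      observed = data$methane_yield,
      predicted = preds
    )
    metric_rows[[id]] <- dplyr::bind_cols(
      tibble::tibble(form_id = id),
      evaluate_predictions(data$methane_yield, preds))
  }
  if (length(metric_rows) == 0) {
    stop("every requested form failed in cross-validation: ",
         paste(failed, collapse = " | "), call. = FALSE)
  }
  metrics <- rank_models(dplyr::bind_rows(metric_rows))
  pooled <- suppressWarnings(fit_all(data, forms = setdiff(forms, names(failed)),
                                     options = options))
  structure(
    list(metrics = metrics,
         predictions = dplyr::bind_rows(pred_tbl),
         pooled = pooled,
         failed = failed,
         n_folds = length(exps),
         options = options),
    class = "vfa_crossval"
  )
}

#' @export
print.vfa_crossval <- function(x, ...) {
  cat(sprintf("Leave-one-experiment-out cross-validation (%d folds)\n",
              x$n_folds))
  print(dplyr::select(x$metrics, dplyr::all_of(
    c("form_id", "n", "rmsep", "ccc", "rank"))))
  if (length(x$failed) > 0) {
    cat("failed forms:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.vfa_crossval <- function(x, ...) x$metrics

#' @export
glance.vfa_crossval <- function(x, ...) {
  tibble::tibble(
    n_forms = nrow(x$metrics),
    n_failed = length(x$failed),
    n_folds = x$n_folds,
    best_form = x$metrics$form_id[which.min(x$metrics$rank)],
    best_rmsep = min(x$metrics$rmsep)
  )
}

#' Serialise a cross-validation report
#'
#' `crossval_to_json()` writes the metrics, ranking and per-record
#' out-of-fold predictions as JSON; `write_crossval_predictions()` exports
#' the predictions as the canonical CSV (identifiers, observed, predicted,
#' fold).
#'
#' @param cv A `vfa_crossval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
crossval_to_json <- function(cv, path) {
  stopifnot(inherits(cv, "vfa_crossval"))
  payload <- list(
    schema = "vfamethane/crossval/1",
    n_folds = cv$n_folds,
    metrics = cv$metrics,
    failed = as.list(cv$failed),
    pooled = lapply(cv$pooled, function(eq)
      jsonlite::fromJSON(equation_to_json(eq))),
    predictions = cv$predictions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname crossval_to_json
#' @export
write_crossval_predictions <- function(cv, path) {
  stopifnot(inherits(cv, "vfa_crossval"))
  readr::write_csv(cv$predictions, path, progress = FALSE)
  invisible(path)
}

#' Render a results table for a cross-validation report
#'
#' Writes a CSV in the layout of a published model-comparison table: one row
#' per model with its symbolic form, pooled-data estimates with standard
#' errors, cross-validation RMSEP (1 decimal), concordance (2 decimals) and
#' rank. Forms that failed are rendered with a `failed` marker.
#'
#' @param cv A `vfa_crossval`.
#' @param path Output CSV path; `NULL` returns the tibble without writing.
#' @return The table as a tibble, invisibly when written.
#' @export
report_crossval <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "vfa_crossval"))
  rows <- purrr::map_dfr(cv$metrics$form_id, function(id) {
    eq <- cv$pooled[[id]]
    est <- if (is.null(eq)) NA_character_ else {
      paste(sprintf("%s = %.3g +/- %.2g", names(eq$coefficients),
                    eq$coefficients, eq$standard_errors), collapse = "; ")
    }
    m <- cv$metrics[cv$metrics$form_id == id, ]
    tibble::tibble(
      model = id,
      equation = model_form(id)$label,
      estimates = est,
      rmsep = round(m$rmsep, 1),
      ccc = round(m$ccc, 2),
      rank = m$rank,
      status = "ok"
    )
  })
  if (length(cv$failed) > 0) {
    rows <- dplyr::bind_rows(rows, purrr::map_dfr(names(cv$failed), function(id)
      tibble::tibble(model = id, equation = model_form(id)$label,
                     estimates = NA_character_, rmsep = NA_real_,
                     ccc = NA_real_, rank = NA_integer_, status = "failed")))
  }
  if (!is.null(path)) {
    readr::write_csv(rows, path, progress = FALSE)
    return(invisible(rows))
  }
  rows
}
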