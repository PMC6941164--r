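# The seven candidate prediction-equation structures and the registry of
# published calibrated coefficients.

.form_ids <- c("M1c", "M2", "M3", "M4", "M5", "M6", "M7")

.form_table <- list(
  M1c = list(
    label = "MY = 16 x (0.50A - 0.25P + 0.50B) x c/100",
    covariates = "stoich",
    has_intercept = FALSE,
    requires_conc = FALSE
  ),
  M2 = list(
    label = "MY = dA - eP + fB",
    covariates = c("acetate", "neg_propionate", "butyrate"),
    has_intercept = FALSE,
    requires_conc = FALSE
  ),
  M3 = list(
    label = "MY = g(A/P) + h",
    covariates = "acetate_propionate_ratio",
    has_intercept = TRUE,
    requires_conc = FALSE
  ),
  M4 = list(
    label = "MY = i(A+B)/P + j",
    covariates = "acetate_butyrate_propionate_ratio",
    has_intercept = TRUE,
    requires_conc = FALSE
  ),
  M5 = list(
    label = "MY = kP + m",
    covariates = "propionate",
    has_intercept = TRUE,
    requires_conc = FALSE
  ),
  M6 = list(
    label = "MY = n[P] + q",
    covariates = "propionate_conc",
    has_intercept = TRUE,
    requires_conc = TRUE
  ),
  M7 = list(
    label = "MY = s/P + t",
    covariates = "inv_propionate",
    has_intercept = TRUE,
    requires_conc = FALSE
  )
)

#' The seven methane-yield model forms
#'
#' `model_forms()` lists the identifiers of the seven candidate structures;
#' `model_form()` builds one of them. The forms map a ruminal VFA profile
#' (acetate A, propionate P, total butyrate B, mol/100 mol total VFA, and
#' optionally the propionate concentration \[P\] in mmol/L) to a design
#' vector for methane yield MY (g CH4/kg DMI):
#'
#' * `M1c` — stoichiometric, no intercept: MY = 16 x (0.50A - 0.25P + 0.50B) x c/100;
#'   the single free parameter c is the fermentation yield, mol total VFA/kg DMI.
#' * `M2` — MY = dA - eP + fB (no intercept). The design carries -P so that
#'   all three reported coefficients are positive.
#' * `M3` — MY = g(A/P) + h.
#' * `M4` — MY = i(A+B)/P + j.
#' * `M5` — MY = kP + m.
#' * `M6` — MY = n\[P\] + q (needs `propionate_conc`).
#' * `M7` — MY = s/P + t.
#'
#' @param form_id One of `"M1c"`, `"M2"`, ..., `"M7"` (case-insensitive).
#' @return `model_form()` returns a `vfa_model_form` object; `model_forms()`
#'   a character vector of the seven identifiers.
#' @export
#' @examples
#' model_form("M4")
model_form <- function(form_id) {
  if (inherits(form_id, "vfa_model_form")) return(form_id)
  if (!is.character(form_id) || length(form_id) != 1) {
    stop("`form_id` must be a single string", call. = FALSE)
  }
  id <- .form_ids[match(toupper(form_id), toupper(.form_ids))]
  if (is.na(id)) {
    stop("unknown model form '", form_id, "'; expected one of ",
         paste(.form_ids, collapse = ", "), call. = FALSE)
  }
  spec <- .form_table[[id]]
  structure(
    list(form_id = id, label = spec$label, covariates = spec$covariates,
         has_intercept = spec$has_intercept, requires_conc = spec$requires_conc),
    class = "vfa_model_form"
  )
}

#' @rdname model_form
#' @export
model_forms <- function() .form_ids

#' @export
print.vfa_model_form <- function(x, ...) {
  cat(sprintf("<model form %s>  %s\n", x$form_id, x$label))
  invisible(x)
}

#' Stoichiometric methane from fermented VFA
#'
#' Fermentation-balance prediction of methane (mol) from the quantities of
#' acetate (`c2`), propionate (`c3`) and total butyrate (`c4`) fermented,
#' each in moles: 0.50 c2 - 0.25 c3 + 0.50 c4. With proportions
#' (mol/100 mol total VFA) as inputs, the same expression gives the methane
#' yield per 100 mol of total VFA. A propionate-dominant input can make the
#' balance negative; the value is returned as-is with a warning, never
#' clipped.
#'
#' @param c2,c3,c4 Non-negative numeric vectors (moles), recycled to a
#'   common length.
#' @return Numeric vector of methane, mol.
#' @export
#' @examples
#' stoichiometric_methane(63.3, 20.2, 9.9)  # 31.55 mol/100 mol total VFA
stoichiometric_methane <- function(c2, c3, c4) {
  if (any(c2 < 0, na.rm = TRUE) || any(c3 < 0, na.rm = TRUE) ||
      any(c4 < 0, na.rm = TRUE)) {
    stop("VFA quantities must be non-negative", call. = FALSE)
  }
  out <- 0.50 * c2 - 0.25 * c3 + 0.50 * c4
  if (any(out < 0, na.rm = TRUE)) {
    warning("stoichiometric methane is negative for propionate-dominant input",
            call. = FALSE)
  }
  out
}

#' Design matrix of a model form
#'
#' Evaluates the covariate transforms of a model form on each record of a
#' dataset, in declared order, with the intercept column (all ones) appended
#' last when the form has one.
#'
#' @param form A `vfa_model_form` or a form identifier.
#' @param data A data frame with the VFA columns the form needs
#'   (`methane_yield` not required).
#' @return Numeric matrix, one row per record, with named columns.
#' @export
design_matrix <- function(form, data) {
  form <- model_form(form)
  data <- validate_vfa_data(data, require_methane = FALSE)
  if (form$requires_conc &&
      (!"propionate_conc" %in% names(data) || anyNA(data$propionate_conc))) {
    stop("model form ", form$form_id,
         " requires the 'propionate_conc' column (mmol/L)", call. = FALSE)
  }
  a <- data$acetate; p <- data$propionate; b <- data$butyrate
  cols <- lapply(form$covariates, function(cv) {
    switch(cv,
      stoich = 16 * stoichiometric_methane(a, p, b) / 100,
      acetate = a,
      neg_propionate = -p,
      butyrate = b,
      acetate_propionate_ratio = a / p,
      acetate_butyrate_propionate_ratio = (a + b) / p,
      propionate = p,
      propionate_conc = data$propionate_conc,
      inv_propionate = 1 / p,
      stop("unknown covariate transform: ", cv)
    )
  })
  x <- do.call(cbind, cols)
  colnames(x) <- form$covariates
  if (form$has_intercept) {
    x <- cbind(x, `(Intercept)` = rep(1, nrow(x)))
  }
  x
}

#' Construct a fitted/published methane-yield equation
#'
#' Low-level constructor for the container holding a model form together
#' with coefficient estimates, their standard errors and the variance
#' components (experiment, treatment within experiment, cow) in
#' (g CH4/kg DMI)^2. Most users obtain these from [fit_meta()] or
#' [published_equation()].
#'
#' @param form A `vfa_model_form` or identifier.
#' @param coefficients Numeric vector, one per design column (intercept last).
#' @param standard_errors Numeric vector of the same length, or `NA`.
#' @param variance_components Named numeric `c(experiment=, treatment=, cow=)`;
#'   `NA` where unknown. Must be non-negative where given.
#' @param source `"fitted"` or `"published"`.
#' @param metadata Optional list (estimation method, log-likelihood, ...).
#' @return A `vfa_equation` object.
#' @export
vfa_equation <- function(form, coefficients, standard_errors = NULL,
                         variance_components = c(experiment = NA_real_,
                                                 treatment = NA_real_,
                                                 cow = NA_real_),
                         source = c("fitted", "published"),
                         metadata = list()) {
  form <- model_form(form)
  n_par <- length(form$covariates) + form$has_intercept
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != n_par) {
    stop(sprintf("form %s expects %d coefficient(s), got %d",
                 form$form_id, n_par, length(coefficients)), call. = FALSE)
  }
  if (is.null(standard_errors)) standard_errors <- rep(NA_real_, n_par)
  if (length(standard_errors) != n_par) {
    stop("standard_errors must match the coefficient count", call. = FALSE)
  }
  vc <- variance_components[c("experiment", "treatment", "cow")]
  names(vc) <- c("experiment", "treatment", "cow")
  if (any(!is.na(vc) & vc < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  par_names <- c(form$covariates, if (form$has_intercept) "(Intercept)")
  names(coefficients) <- par_names
  names(standard_errors) <- par_names
  structure(
    list(form = form, coefficients = coefficients,
         standard_errors = as.numeric(standard_errors),
         variance_components = vc,
         source = match.arg(source), metadata = metadata),
    class = "vfa_equation"
  )
}

# Published calibrated coefficients (estimate, se), design order.
.published <- list(
  M1c = list(est = 3.98, se = 0.15),
  M2 = list(est = c(0.30, 0.22, 0.48), se = c(0.042, 0.055, 0.16)),
  M3 = list(est = c(4.08, 7.05), se = c(0.36, 1.40)),
  M4 = list(est = c(3.28, 7.60), se = c(0.29, 1.28)),
  M5 = list(est = c(-0.57, 32.3), se = c(0.057, 1.4)),
  M6 = list(est = c(-0.24, 26.1), se = c(0.035, 1.3)),
  M7 = list(est = c(316, 4.4), se = c(28, 1.5))
)

#' Published calibrated methane-yield equations
#'
#' Returns the calibrated coefficients (with standard errors) of one of the
#' seven forms as estimated on the pooled development data of the source
#' study (seven experiments, 215 lactating-cow records). The three best
#' forms — M3, M4 and M7 — additionally carry the reported variance
#' components (1.7, 1.5 and 6.9 (g CH4/kg DMI)^2 for experiment, treatment
#' within experiment, and cow); the components were reported only for those
#' forms, so the others carry `NA`.
#'
#' @param form_id One of the seven form identifiers.
#' @return A `vfa_equation` with `source = "published"`.
#' @export
#' @examples
#' published_equation("M4")
published_equation <- function(form_id) {
  form <- model_form(form_id)
  entry <- .published[[form$form_id]]
  vc <- if (form$form_id %in% c("M3", "M4", "M7")) {
    c(experiment = 1.7, treatment = 1.5, cow = 6.9)
  } else {
    c(experiment = NA_real_, treatment = NA_real_, cow = NA_real_)
  }
  vfa_equation(form, entry$est, entry$se, vc, source = "published",
               metadata = list(origin = "pooled development data, n = 215"))
}

#' Predict methane yield from a fitted equation
#'
#' Deterministic fixed-effect prediction: the dot product of the equation's
#' coefficients with the design vector of each record. Random effects are
#' not involved (their expectation for a new experiment is zero).
#'
#' @param object A `vfa_equation`.
#' @param newdata Data frame of VFA profiles.
#' @param ... Unused.
#' @return Numeric vector of predicted methane yield, g CH4/kg DMI.
#' @export
predict.vfa_equation <- function(object, newdata, ...) {
  x <- design_matrix(object$form, newdata)
  drop(x %*% object$coefficients)
}

#' @export
print.vfa_equation <- function(x, ...) {
  cat(sprintf("<%s methane-yield equation %s>\n", x$source, x$form$form_id))
  cat("  ", x$form$label, "\n", sep = "")
  est <- sprintf("%s = %.4g +/- %.3g", names(x$coefficients),
                 x$coefficients, x$standard_errors)
  cat("  ", paste(est, collapse = ", "), "\n", sep = "")
  vc <- x$variance_components
  if (!all(is.na(vc))) {
    cat(sprintf("  variance components (exp/trt/cow): %.3g / %.3g / %.3g\n",
                vc[["experiment"]], vc[["treatment"]], vc[["cow"]]))
  }
  invisible(x)
}

#' Broom-style methods for methane-yield equations
#'
#' `tidy()` returns one row per coefficient; `glance()` a one-row summary
#' with the variance components and fit metadata; `augment()` appends
#' `.fitted` (and `.resid` when observations are present) to the data.
#'
#' @param x,object A `vfa_equation`.
#' @param data Data frame of records for `augment()`.
#' @param ... Unused.
#' @name vfa_equation_broom
NULL

#' @rdname vfa_equation_broom
#' @export
tidy.vfa_equation <- function(x, ...) {
  tibble::tibble(
    form_id = x$form$form_id,
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors)
  )
}

#' @rdname vfa_equation_broom
#' @export
glance.vfa_equation <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    form_id = x$form$form_id,
    source = x$source,
    sigma2_experiment = x$variance_components[["experiment"]],
    sigma2_treatment = x$variance_components[["treatment"]],
    sigma2_cow = x$variance_components[["cow"]],
    method = md$method %||% NA_character_,
    logLik = md$logLik %||% NA_real_,
    converged = md$converged %||% NA,
    nobs = md$nobs %||% NA_integer_
  )
}

#' @rdname vfa_equation_broom
#' @export
augment.vfa_equation <- function(x, data, ...) {
  data <- tibble::as_tibble(data)
  data$.fitted <- predict(x, data)
  if ("methane_yield" %in% names(data)) {
    data$.resid <- data$methane_yield - data$.fitted
  }
  data
}

#' Serialise an equation to JSON
#'
#' @param eq A `vfa_equation`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
equation_to_json <- function(eq, path = NULL) {
  stopifnot(inherits(eq, "vfa_equation"))
  payload <- list(
    form_id = eq$form$form_id,
    coefficients = as.list(eq$coefficients),
    standard_errors = as.list(stats::setNames(eq$standard_errors,
                                              names(eq$coefficients))),
    variance_components = as.list(eq$variance_components),
    source = eq$source,
    metadata = eq$metadata[setdiff(names(eq$metadata), "fit")]
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(json)) return(json)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
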