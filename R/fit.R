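# Three-level linear mixed-effects meta-analysis: fixed effects from a model
# form, random intercepts for experiment and treatment-within-experiment,
# cow-level residual.

#' Options for the mixed-effects meta-analysis
#'
#' @param method `"REML"` (default, the usual choice for variance-component
#'   estimation in meta-analysis of experiments) or `"ML"` for sensitivity.
#' @param max_iterations Optimiser evaluation budget.
#' @param convergence_tol Absolute tolerance on the optimiser's objective
#'   (the deviance / REML criterion) and parameters.
#' @param variance_floor Lower bound applied to reported variance components
#'   (the optimiser itself already constrains them to be non-negative).
#' @param random_effects When `FALSE` the two upper random levels are
#'   constrained to zero variance and the fit reduces to ordinary least
#'   squares on the pooled records (useful as a degenerate check).
#' @return A list of class `vfa_fit_options`.
#' @export
fit_options <- function(method = c("REML", "ML"), max_iterations = 20000,
                        convergence_tol = 1e-10, variance_floor = 0,
                        random_effects = TRUE) {
  method <- match.arg(method)
  stopifnot(max_iterations >= 1, convergence_tol > 0, variance_floor >= 0)
  structure(
    list(method = method, max_iterations = max_iterations,
         convergence_tol = convergence_tol, variance_floor = variance_floor,
         random_effects = random_effects),
    class = "vfa_fit_options"
  )
}

# internal: assemble the modelling frame for lme4
.fit_frame <- function(data, form) {
  x <- design_matrix(form, data)
  frame <- as.data.frame(x)
  names(frame) <- paste0(".x", seq_len(ncol(x)))
  frame$.y <- data$methane_yield
  frame$.experiment <- factor(data$experiment_id)
  frame$.trt <- factor(paste(data$experiment_id, data$treatment_id, sep = ":"))
  list(frame = frame, x = x)
}

#' Fit a model form by mixed-effects meta-analysis
#'
#' Estimates the fixed-effect coefficients of a model form from per-cow
#' records pooled across experiments, under the three-level model
#' `MY_ijk = x'beta + u_i + v_ij + e_ijk` with independent normal random
#' intercepts for experiment (`u`), treatment within experiment (`v`) and a
#' cow-level residual (`e`). Estimation is (RE)ML via [lme4::lmer()];
#' standard errors of the fixed effects come from the observed information.
#'
#' @param data A valid dataset with at least two experiments, two treatments
#'   and more records than fixed parameters.
#' @param form A model form or identifier (see [model_form()]).
#' @param options A [fit_options()] list.
#' @return A `vfa_equation` with `source = "fitted"`; `metadata` records the
#'   method, log-likelihood, convergence flag, iteration count and any
#'   optimiser messages, and carries the underlying `merMod` as
#'   `metadata$fit`.
#' @export
#' @examples
#' d <- make_fixture("tiny_2exp")
#' fit_meta(d, "M3")
fit_meta <- function(data, form, options = fit_options()) {
  form <- model_form(form)
  data <- validate_vfa_data(data)
  if (!inherits(options, "vfa_fit_options")) {
    stop("`options` must come from fit_options()", call. = FALSE)
  }
  counts <- .vfa_counts(data)
  n_par <- length(form$covariates) + form$has_intercept
  if (counts$records <= n_par) {
    stop("more records than fixed parameters are required", call. = FALSE)
  }

  ff <- .fit_frame(data, form)
  if (qr(ff$x)$rank < ncol(ff$x)) {
    stop("singular design for form ", form$form_id,
         " (constant or collinear covariate)", call. = FALSE)
  }
  xs <- paste(setdiff(names(ff$frame), c(".y", ".experiment", ".trt")),
              collapse = " + ")

  # random terms are only identifiable for grouping factors with >= 2
  # levels; a term that cannot be estimated is dropped and its variance
  # component reported as zero (recorded in the metadata)
  random_terms <- character()
  if (options$random_effects) {
    if (counts$experiments >= 2) random_terms <- "(1 | .experiment)"
    if (counts$treatments >= 2) {
      random_terms <- c(random_terms, "(1 | .trt)")
    }
  }

  if (length(random_terms) == 0) {
    fit <- stats::lm(stats::as.formula(paste(".y ~ 0 +", xs)), data = ff$frame)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    vc <- c(experiment = 0, treatment = 0,
            cow = max(summary(fit)$sigma^2, options$variance_floor))
    meta <- list(method = "OLS", logLik = as.numeric(stats::logLik(fit)),
                 converged = TRUE, iterations = NA_integer_,
                 nobs = counts$records, messages = character(), fit = fit)
    return(vfa_equation(form, beta, se, vc, source = "fitted", metadata = meta))
  }

  fml <- stats::as.formula(
    paste(".y ~ 0 +", xs, "+", paste(random_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(maxeval = options$max_iterations,
                   xtol_abs = options$convergence_tol,
                   ftol_abs = options$convergence_tol))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = ff$frame, REML = options$method == "REML",
               control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt != 0) {
    stop("mixed-model fit for form ", form$form_id,
         " did not converge within max_iterations; last messages: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }

  beta <- lme4::fixef(fit)
  names(beta) <- colnames(ff$x)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(group) {
    v <- vcs$vcov[vcs$grp == group]
    if (length(v) == 0) 0 else v  # dropped (single-level) term
  }
  vc <- c(experiment = get_vc(".experiment"), treatment = get_vc(".trt"),
          cow = get_vc("Residual"))
  vc <- pmax(vc, options$variance_floor)

  # convergence-checker notes (gradient etc.) are retained as metadata, not
  # errors: boundary fits on noiseless or near-noiseless data trip them
  meta <- list(method = options$method,
               logLik = as.numeric(stats::logLik(fit)),
               criterion = if (options$method == "REML")
                 lme4::REMLcrit(fit) else stats::deviance(fit),
               converged = length(msgs) == 0,
               iterations = fit@optinfo$feval %||% NA_integer_,
               nobs = counts$records, messages = msgs,
               dropped_random_terms = setdiff(c("(1 | .experiment)", "(1 | .trt)"),
                                              random_terms),
               fit = fit)
  vfa_equation(form, beta, se, vc, source = "fitted", metadata = meta)
}

#' Fit every (fittable) model form to a dataset
#'
#' Convenience wrapper running [fit_meta()] over all seven forms. Forms that
#' need the propionate concentration are skipped with a warning when the
#' column is absent; a failing form is recorded and does not abort the
#' others.
#'
#' @inheritParams fit_meta
#' @param forms Form identifiers to fit (default all seven).
#' @return A named list of `vfa_equation` objects for the forms that fitted;
#'   failures are reported in the `"errors"` attribute (named character).
#' @export
fit_all <- function(data, forms = model_forms(), options = fit_options()) {
  data <- validate_vfa_data(data)
  if (nrow(data) == 0) stop("cannot fit an empty dataset", call. = FALSE)
  fits <- list()
  errors <- character()
  for (id in forms) {
    form <- model_form(id)
    if (form$requires_conc &&
        (!"propionate_conc" %in% names(data) || anyNA(data$propionate_conc))) {
      warning("skipping form ", form$form_id,
              ": 'propionate_conc' not available", call. = FALSE)
      next
    }
    res <- tryCatch(fit_meta(data, form, options), error = function(e) e)
    if (inherits(res, "error")) {
      errors[form$form_id] <- conditionMessage(res)
      warning("form ", form$form_id, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      fits[[form$form_id]] <- res
    }
  }
  attr(fits, "errors") <- errors
  fits
}
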