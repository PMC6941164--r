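# ggplot2 views of datasets and results.

#' Observed methane yield against the VFA covariates
#'
#' Scatterplots of methane yield against acetate, butyrate, propionate and
#' the reciprocal of propionate — the standard first look at a development
#' dataset, showing the approximately linear association with A and B and
#' the reciprocal relationship with P.
#'
#' @param data A valid dataset.
#' @return A ggplot object (facetted by covariate).
#' @export
plot_vfa_relationships <- function(data) {
  data <- validate_vfa_data(data)
  long <- tidyr::pivot_longer(
    dplyr::mutate(data, inv_propionate = 1 / .data$propionate),
    cols = c("acetate", "propionate", "butyrate", "inv_propionate"),
    names_to = "covariate", values_to = "value")
  long$covariate <- factor(
    long$covariate,
    levels = c("acetate", "propionate", "butyrate", "inv_propionate"),
    labels = c("acetate (mol/100 mol)", "propionate (mol/100 mol)",
               "butyrate (mol/100 mol)", "1/propionate"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     y = .data$methane_yield)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "methane yield (g CH4/kg DMI)") +
    ggplot2::theme_minimal()
}

#' @describeIn loeo_crossval Observed-versus-predicted panels of the pooled
#'   out-of-fold predictions, one facet per model form, with the 1:1 line.
#' @param object A `vfa_crossval`.
#' @param ... Unused.
#' @export
autoplot.vfa_crossval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::facet_wrap(~form_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "predicted methane yield (g CH4/kg DMI)",
                  y = "observed methane yield (g CH4/kg DMI)") +
    ggplot2::theme_minimal()
}

#' @describeIn predict.vfa_equation Observed-versus-predicted plot of an
#'   equation applied to a dataset, with the 1:1 line.
#' @export
autoplot.vfa_equation <- function(object, newdata, ...) {
  aug <- augment(object, newdata)
  if (!"methane_yield" %in% names(aug)) {
    stop("`newdata` needs observed methane_yield for this plot", call. = FALSE)
  }
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$.fitted,
                                    y = .data$methane_yield)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("predicted methane yield, %s (g CH4/kg DMI)",
                  object$form$form_id),
      y = "observed methane yield (g CH4/kg DMI)") +
    ggplot2::theme_minimal()
}
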