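#' Clinical-only comparator architecture
#'
#' The same network as the full model with the convolutional branch and its
#' dense layer removed; trains and evaluates through the same
#' cross-validation path.
#'
#' @param ... Passed to [arch_config()].
#' @return An [arch_config()] with `use_images = FALSE`.
#' @export
clinical_arch <- function(...) arch_config(..., use_images = FALSE)

#' Perfusion-deficit extent (simplified surrogate)
#'
#' Percentage of pixels whose value falls below a fraction of the matching
#' normal-template value.  This is a simplified stand-in for clinical
#' total-perfusion-deficit quantitation, intended for synthetic maps; it is
#' scale-free in the sense that rescaling map and template jointly leaves
#' it unchanged.
#'
#' @param map Perfusion polar map, matrix `28 x 36` (or any shape).
#' @param template Normal template of the same shape.
#' @param threshold_fraction Defect threshold as a fraction of the template
#'   (default 0.7).
#' @return Extent in percent of map area.
#' @export
deficit_extent <- function(map, template, threshold_fraction = 0.7) {
  if (!all(dim(map) == dim(template)))
    stop("map and template dimensions differ")
  100 * mean(map < threshold_fraction * template)
}

#' Deficit extent for every patient in a cohort
#'
#' @param maps Array `n x 5 x 28 x 36` (channel 1 = perfusion).
#' @param template 5-channel template as from [polar_template()].
#' @param threshold_fraction As in [deficit_extent()].
#' @return Numeric vector of extents (percent).
#' @export
cohort_deficit_extent <- function(maps, template = polar_template(),
                                  threshold_fraction = 0.7) {
  vapply(seq_len(dim(maps)[1]), function(i)
    deficit_extent(maps[i, 1, , ], template[1, , ], threshold_fraction), 0)
}

#' Multivariable Cox comparator
#'
#' Fits a cause-specific Cox proportional-hazards model (Efron tie
#' handling) on the clinical features plus the perfusion-deficit extent.
#' Competing first events are censored at their event time; with
#' `event_kind = "MACE"` the composite of all three events is modelled.
#'
#' @param features Data.frame/matrix of predictors (no missing values).
#' @param outcomes An [outcome_table()].
#' @param event_kind Event of interest or "MACE".
#' @return Object of class `cox_model` wrapping the `survival::coxph` fit.
#' @export
fit_cox <- function(features, outcomes, event_kind = "MACE") {
  stopifnot(nrow(features) == nrow(outcomes))
  if (anyNA(features)) stop("features contain missing values; impute first")
  status <- if (event_kind == "MACE") outcomes$event_kind != "censored"
            else outcomes$event_kind == event_kind
  df <- as.data.frame(features)
  df$.time <- pmax(outcomes$time_days, 0.5)   # day-0 events: keep in risk set
  df$.status <- as.integer(status)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(setdiff(names(df), c(".time", ".status")), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) && any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge to finite coefficients")
  structure(list(fit = fit, event_kind = event_kind,
                 terms = names(stats::coef(fit))),
            class = "cox_model")
}

#' Cox linear predictor for new data
#'
#' @param model A `cox_model`.
#' @param features New predictor rows (same columns as the fit).
#' @return The linear predictor beta' x (centered as by `survival`).
#' @export
cox_risk <- function(model, features) {
  stopifnot(inherits(model, "cox_model"))
  unname(stats::predict(model$fit, newdata = as.data.frame(features),
                        type = "lp"))
}

#' Coefficient table of a Cox comparator
#' @param model A `cox_model`.
#' @return Data.frame (term, coefficient, se).
#' @export
cox_coefficients <- function(model) {
  s <- summary(model$fit)
  data.frame(term = rownames(s$coefficients),
             coefficient = s$coefficients[, "coef"],
             se = s$coefficients[, "se(coef)"],
             row.names = NULL)
}
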