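#' Clinical feature schema
#'
#' The model consumes 15 clinical features: demographics, prior procedures,
#' risk factors and stress-test measurements.  The final slot is
#' configurable; by default it carries left-ventricular ejection fraction.
#'
#' @param extra_name Name of the 15th (configurable) feature.
#' @param extra_kind Its kind, `"continuous"` or `"binary"`.
#' @return A data.frame with columns `name` and `kind`.
#' @export
clinical_schema <- function(extra_name = "lvef",
                            extra_kind = "continuous") {
  stopifnot(extra_kind %in% c("continuous", "binary"))
  data.frame(
    name = c("age", "male", "bmi", "prior_pci", "prior_cabg", "prior_tavr",
             "hypertension", "diabetes", "dyslipidemia", "family_history",
             "stress_pharmacologic", "resting_hr", "peak_stress_hr",
             "peak_stress_sbp", extra_name),
    kind = c("continuous", "binary", "continuous", "binary", "binary",
             "binary", "binary", "binary", "binary", "binary", "binary",
             "continuous", "continuous", "continuous", extra_kind),
    stringsAsFactors = FALSE)
}

#' Fit a mean/mode imputer on training rows
#'
#' Continuous features are imputed with the training mean of non-missing
#' values; categorical (binary) features with the training mode, ties going
#' to the smallest value.  Statistics are estimated on training rows only so
#' the same state can be replayed on test data without leakage.
#'
#' @param train A data.frame of clinical features (NAs allowed).
#' @param schema A [clinical_schema()]-style data.frame restricted to the
#'   columns of `train`; defaults to the standard schema.
#' @return An object of class `imputer_state`.
#' @export
fit_imputer <- function(train, schema = clinical_schema()) {
  schema <- schema[match(names(train), schema$name), , drop = FALSE]
  if (any(is.na(schema$name)))
    stop("columns missing from schema: ",
         paste(setdiff(names(train), schema$name), collapse = ", "))
  stats <- numeric(ncol(train))
  names(stats) <- names(train)
  for (j in seq_along(train)) {
    v <- train[[j]]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("feature '", names(train)[j],
           "' has no non-missing training values")
    stats[j] <- if (schema$kind[j] == "continuous") {
      mean(v)
    } else {
      tab <- table(v)
      best <- tab == max(tab)
      # ties: smallest value
      min(as.numeric(names(tab)[best]))
    }
  }
  structure(list(stats = stats, kind = schema$kind,
                 features = names(train)),
            class = "imputer_state")
}

#' Apply a fitted imputer
#'
#' Replaces missing cells with the stored training statistic; non-missing
#' cells are untouched.
#'
#' @param state An `imputer_state` from [fit_imputer()].
#' @param rows A data.frame with the same columns as the training data.
#' @return `rows` with all NAs filled in.
#' @export
apply_imputer <- function(state, rows) {
  stopifnot(inherits(state, "imputer_state"))
  if (!identical(names(rows), state$features))
    stop("column set/order differs from the fitted imputer")
  for (j in seq_along(rows)) {
    miss <- is.na(rows[[j]])
    if (any(miss)) rows[[j]][miss] <- state$stats[j]
  }
  rows
}

#' Fit input normalization on training rows
#'
#' Continuous clinical features are z-scored with training mean/SD; binary
#' features pass through.  A constant continuous feature (SD 0) is centered
#' only, with a warning.  Polar-map pixels are mapped from the 0-100 scale
#' to `[0, 1]` (no trainable state).
#'
#' @param train Imputed training clinical data.frame.
#' @param schema Feature schema as in [fit_imputer()].
#' @return An object of class `normalizer_state`.
#' @export
fit_normalizer <- function(train, schema = clinical_schema()) {
  schema <- schema[match(names(train), schema$name), , drop = FALSE]
  center <- numeric(ncol(train)); scale <- rep(1, ncol(train))
  for (j in seq_along(train)) {
    if (schema$kind[j] == "continuous") {
      center[j] <- mean(train[[j]])
      s <- stats::sd(train[[j]])
      if (!is.finite(s) || s == 0) {
        warning("constant continuous feature '", names(train)[j],
                "': centered only")
        s <- 1
      }
      scale[j] <- s
    }
  }
  structure(list(center = center, scale = scale, kind = schema$kind,
                 features = names(train)),
            class = "normalizer_state")
}

#' Apply input normalization
#'
#' @param state A `normalizer_state` from [fit_normalizer()].
#' @param clinical Imputed clinical data.frame (same columns as training).
#' @return A numeric matrix (patients x features) of normalized values.
#' @export
normalize_clinical <- function(state, clinical) {
  stopifnot(inherits(state, "normalizer_state"))
  if (!identical(names(clinical), state$features))
    stop("column set/order differs from the fitted normalizer")
  x <- as.matrix(clinical)
  for (j in seq_len(ncol(x)))
    if (state$kind[j] == "continuous")
      x[, j] <- (x[, j] - state$center[j]) / state$scale[j]
  x
}

#' Scale polar-map pixels from 0-100 to 0-1
#'
#' @param maps Numeric array of polar maps on the 0-100 scale.
#' @return The same array divided by 100.
#' @export
normalize_maps <- function(maps) {
  maps / 100
}
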