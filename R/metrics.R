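#' Kaplan-Meier censoring model for IPCW
#'
#' Estimates the censoring survival function G(t) by Kaplan-Meier with the
#' roles of event and censoring reversed (all first events are treated as
#' censored observations of the censoring time).  Weights for subjects
#' failing at time t are 1 / G(t).
#'
#' @param outcomes An [outcome_table()].
#' @return Object of class `censoring_model` with a step-function
#'   evaluator `G(t)`.
#' @export
fit_censoring_km <- function(outcomes) {
  status_cens <- as.integer(outcomes$event_kind == "censored")
  fit <- survival::survfit(
    survival::Surv(outcomes$time_days, status_cens) ~ 1)
  # left-continuous evaluation is not needed: weights use G at the event
  # time, taken from the right-continuous KM step function
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(G = sf, fit = fit), class = "censoring_model")
}

#' Evaluate the censoring survival function
#' @param cm A `censoring_model`.
#' @param t Times in days.
#' @export
censoring_weight_times <- function(cm, t) cm$G(t)

# risk-set bookkeeping for cause-specific analyses: competing first events
# are censored at their event time
.cause_specific <- function(outcomes, event_kind) {
  if (event_kind == "MACE") {
    delta <- outcomes$event_kind != "censored"
  } else {
    delta <- outcomes$event_kind == event_kind
  }
  list(time = outcomes$time_days, delta = delta)
}

#' Cumulative/dynamic AUC with inverse-probability-of-censoring weights
#'
#' At each evaluation time t, cases are subjects observed to fail (with the
#' event of interest) on or before t, weighted by `1 / G(t_i)`; controls
#' are subjects still under observation beyond t.  The statistic is the
#' weighted probability that a case ranks above a control, with ties
#' counting one half:
#' `AUC(t) = sum_ij w_i c(r_i, r_j) / (sum_i w_i * #controls)`.
#'
#' @param risks Numeric risk score per patient at the evaluation times:
#'   either a vector (time-constant score) or a matrix `n x length(times)`
#'   (e.g. CIF at each time).
#' @param outcomes An [outcome_table()].
#' @param event_kind "ACS", "death", "revascularization" or "MACE".
#' @param times Evaluation times in days.
#' @param censoring Optional `censoring_model`; fitted on `outcomes` when
#'   missing.
#' @return A data.frame of class `metric_curve` (columns `time`,
#'   `estimate`, `n_cases`, `n_controls`), with the mean over the first
#'   six months (183 days) attached as attribute `mean_6mo`.
#' @export
cumulative_dynamic_auc <- function(risks, outcomes, event_kind, times,
                                   censoring = NULL) {
  if (is.null(censoring)) censoring <- fit_censoring_km(outcomes)
  cs <- .cause_specific(outcomes, event_kind)
  n <- length(cs$time)
  if (is.vector(risks)) risks <- matrix(risks, n, length(times))
  stopifnot(nrow(risks) == n, ncol(risks) == length(times))
  est <- nc <- nco <- numeric(length(times))
  for (ti in seq_along(times)) {
    t <- times[ti]
    case <- cs$delta & cs$time <= t
    control <- cs$time > t
    nc[ti] <- sum(case); nco[ti] <- sum(control)
    if (!any(case) || !any(control)) {
      est[ti] <- NA_real_
      next
    }
    G <- censoring$G(cs$time[case])
    if (any(G <= 0))
      stop("censoring survival is zero at a required weight time ",
           min(cs$time[case][G <= 0]))
    w <- 1 / G
    r_case <- risks[case, ti]
    r_ctrl <- risks[control, ti]
    # rank-based weighted Mann-Whitney: for each case, count controls
    # below it (ties half)
    comp <- vapply(r_case, function(r)
      sum(r > r_ctrl) + 0.5 * sum(r == r_ctrl), 0)
    est[ti] <- sum(w * comp) / (sum(w) * length(r_ctrl))
  }
  out <- data.frame(time = times, estimate = est, n_cases = nc,
                    n_controls = nco)
  class(out) <- c("metric_curve", "data.frame")
  in6 <- times <= 183 & !is.na(est)
  attr(out, "mean_6mo") <- if (any(in6)) mean(est[in6]) else NA_real_
  out
}

#' Time-dependent concordance index
#'
#' Antolini-style concordance for time-varying predictions: a pair (i, j)
#' is comparable when i fails (from the event of interest) at t_i while j
#' is still under observation beyond t_i; it is concordant when the
#' predicted cumulative incidence at t_i is higher for i than for j.  Ties
#' count one half.
#'
#' @param surface A [risk_surface()] (or a matrix `n x T` of CIF values).
#' @param outcomes An [outcome_table()].
#' @param event_kind Event of interest (or "MACE").
#' @return Concordance in `[0, 1]`; NA (with a warning) when no pair is
#'   comparable.
#' @export
td_concordance <- function(surface, outcomes, event_kind) {
  cif <- if (inherits(surface, "risk_surface"))
    cif_matrix(surface, event_kind) else surface
  cs <- .cause_specific(outcomes, event_kind)
  bins <- outcomes$bin_index
  conc <- 0; comp <- 0
  for (i in which(cs$delta)) {
    js <- which(cs$time > cs$time[i])
    if (!length(js)) next
    ci <- cif[i, bins[i] + 1L]
    cj <- cif[js, bins[i] + 1L]
    conc <- conc + sum(ci > cj) + 0.5 * sum(ci == cj)
    comp <- comp + length(js)
  }
  if (comp == 0) {
    warning("no comparable pairs")
    return(NA_real_)
  }
  conc / comp
}

#' Fixed-time AUC (Mann-Whitney with tie correction)
#'
#' @param labels Logical/0-1 vector (positives = events by the horizon).
#' @param scores Numeric risk scores on the same patients.
#' @return The AUC.
#' @export
fixed_time_auc <- function(labels, scores) {
  keep <- !is.na(labels)
  labels <- as.logical(labels[keep]); scores <- scores[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("labels contain a single class")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong comparison of two correlated AUCs
#'
#' Computes both AUCs on the same labelled patients, the DeLong covariance
#' of the paired estimates via structural components, and a two-sided
#' normal p-value for the difference.
#'
#' @param scores_a,scores_b Two risk scores for the same patients.
#' @param labels Logical/0-1 labels.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  keep <- !is.na(labels)
  labels <- as.logical(labels[keep])
  sa <- scores_a[keep]; sb <- scores_b[keep]
  pos <- which(labels); neg <- which(!labels)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("labels contain a single class")
  comp <- function(s) {
    sp <- s[pos]; sn <- s[neg]
    # structural components by midrank identity
    rall <- rank(c(sp, sn))
    rp <- rank(sp); rn <- rank(sn)
    auc <- (sum(rall[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    v10 <- (rall[seq_len(m)] - rp) / n          # per positive
    v01 <- 1 - (rall[m + seq_len(n)] - rn) / m  # per negative
    list(auc = auc, v10 = v10, v01 = v01)
  }
  ca <- comp(sa); cb <- comp(sb)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff, z = z, p = p)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement B times, applies `metric_fn` to the
#' index vector of each resample, and returns the mean with the 2.5/97.5
#' percentile interval.  Resamples on which the metric is undefined (error
#' or NA) are redrawn, up to 10 B attempts.
#'
#' @param metric_fn Function of an integer index vector.
#' @param n Number of patients to resample from.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return List with `mean`, `lower`, `upper`, `values`.
#' @export
bootstrap_ci <- function(metric_fn, n, B = 100, seed = 1) {
  vals <- numeric(B)
  with_seed(seed, {
    b <- 1L; attempts <- 0L
    while (b <= B) {
      if (attempts >= 10L * B) stop("metric undefined on too many resamples")
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric_fn(idx), error = function(e) NA_real_)
      if (is.finite(v)) {
        vals[b] <- v
        b <- b + 1L
      }
    }
  })
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(mean = mean(vals), lower = q[1], upper = q[2], values = vals)
}
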