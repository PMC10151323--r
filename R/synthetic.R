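#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the model assumes: a
#' clinical table with marginals similar to a large MPI registry, polar-map
#' stacks equal to a smooth template minus a localized defect, and
#' right-censored competing-risks event times drawn from known discrete
#' cause-specific hazards
#' `h_k(t | x) = plogis(b0_k(t) + beta_k' z + gamma_k * E)`,
#' where `z` are standardized clinical covariates and `E` is the true defect
#' extent (fraction of perfusion pixels below 70% of the template).
#'
#' Default coefficients are calibrated so that, over a five-year window,
#' roughly 6-7% of patients die, ~3% have an acute coronary syndrome and
#' ~7% undergo revascularization, mirroring published registry prevalences.
#' The revascularization baseline hazard decays with time (most
#' revascularizations happen soon after the scan); death and ACS baselines
#' are flat.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed for every random draw in the generator.
#' @param defect_prob Base probability that a patient has a perfusion defect.
#' @param defect_amplitude Range (min, max) of defect depth on the 0-100
#'   pixel scale.
#' @param defect_sigma_row,defect_sigma_col Ranges of the defect's Gaussian
#'   radial/angular extents, in pixels.
#' @param noise_sd Per-channel pixel noise SD (0-100 scale).
#' @param extent_threshold A pixel counts as defective when the noiseless
#'   map falls below this fraction of the template (default 0.7).
#' @param beta 15 x 3 matrix of clinical log-odds coefficients
#'   (columns ACS, death, revascularization) on standardized covariates.
#' @param gamma Length-3 defect-extent coefficients, same column order.
#' @param b0 Length-3 baseline per-bin logit intercepts at time 0.
#' @param b0_slope Length-3 linear decay of the intercept over the horizon
#'   (logits from first to last bin).
#' @param admin_censor_days Administrative censoring window in days.
#' @param dropout_hazard Per-bin probability of random loss to follow-up.
#' @param missing_rate Fraction of continuous clinical cells set missing in
#'   the exported table (the hazards always use the complete values).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1000,
                             seed = 42,
                             defect_prob = 0.40,
                             defect_amplitude = c(20, 70),
                             defect_sigma_row = c(1.5, 5),
                             defect_sigma_col = c(2, 7),
                             noise_sd = 2,
                             extent_threshold = 0.7,
                             beta = NULL,
                             gamma = c(ACS = 4, death = 3,
                                       revascularization = 6),
                             b0 = c(ACS = -8.6, death = -7.65,
                                    revascularization = -6.8),
                             b0_slope = c(ACS = 0, death = 0,
                                          revascularization = -5),
                             admin_censor_days = 1825,
                             dropout_hazard = 0.004,
                             missing_rate = 0.01) {
  schema <- clinical_schema()
  if (is.null(beta)) {
    beta <- matrix(0, nrow = 15, ncol = 3,
                   dimnames = list(schema$name,
                                   c("ACS", "death", "revascularization")))
    beta[, "death"] <- c(age = 0.55, male = 0.2, bmi = -0.1,
                         prior_pci = 0.1, prior_cabg = 0.2, prior_tavr = 0.3,
                         hypertension = 0.2, diabetes = 0.4,
                         dyslipidemia = 0, family_history = -0.1,
                         stress_pharmacologic = 0.5, resting_hr = 0.30,
                         peak_stress_hr = -0.45, peak_stress_sbp = -0.25,
                         lvef = -0.40)
    beta[, "ACS"] <- c(age = 0.15, male = 0.4, bmi = 0,
                       prior_pci = 0.5, prior_cabg = 0.3, prior_tavr = 0.2,
                       hypertension = 0.3, diabetes = 0.3,
                       dyslipidemia = 0.3, family_history = 0.1,
                       stress_pharmacologic = 0.3, resting_hr = 0,
                       peak_stress_hr = -0.3, peak_stress_sbp = -0.1,
                       lvef = -0.1)
    beta[, "revascularization"] <- c(age = 0.1, male = 0.5, bmi = 0,
                                     prior_pci = 0.6, prior_cabg = 0.3,
                                     prior_tavr = 0, hypertension = 0.15,
                                     diabetes = 0.25, dyslipidemia = 0.35,
                                     family_history = 0.05,
                                     stress_pharmacologic = 0.1,
                                     resting_hr = 0, peak_stress_hr = -0.15,
                                     peak_stress_sbp = 0, lvef = -0.1)
  }
  stopifnot(nrow(beta) == 15, ncol(beta) == 3, length(gamma) == 3)
  dimnames(beta) <- list(schema$name, c("ACS", "death", "revascularization"))
  names(gamma) <- names(b0) <- names(b0_slope) <-
    c("ACS", "death", "revascularization")
  # theoretical marginals used both for sampling and for standardizing the
  # covariates entering the hazards
  marginals <- list(
    age = c(mean = 64, sd = 12), male = 0.57,
    bmi = c(mean = 27.8, sd = 4.8),
    prior_pci = 0.19, prior_cabg = 0.083, prior_tavr = 0.002,
    hypertension = 0.63, diabetes = 0.26, dyslipidemia = 0.63,
    family_history = 0.28, stress_pharmacologic = 0.52,
    resting_hr = c(mean = 69, sd = 13),
    peak_stress_hr = c(mean = 122, sd = 28),
    peak_stress_sbp = c(mean = 150, sd = 25),
    lvef = c(mean = 58, sd = 10))
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    defect_prob = defect_prob, defect_amplitude = defect_amplitude,
    defect_sigma_row = defect_sigma_row, defect_sigma_col = defect_sigma_col,
    noise_sd = noise_sd, extent_threshold = extent_threshold,
    beta = beta, gamma = gamma, b0 = b0, b0_slope = b0_slope,
    admin_censor_days = admin_censor_days, dropout_hazard = dropout_hazard,
    missing_rate = missing_rate, marginals = marginals,
    channels = c("perfusion", "motion", "thickening", "phase", "amplitude"),
    # how strongly the defect imprints on each channel, relative to perfusion
    channel_defect_scale = c(perfusion = 1, motion = 0.6, thickening = 0.5,
                             phase = -0.4, amplitude = 0.4)),
    class = "synthetic_config")
}

#' The smooth normal polar-map template
#'
#' A noiseless 5 x 28 x 36 stack representing a normal study: high uniform
#' perfusion/function with a gentle radial fall-off towards the map edge.
#'
#' @param config A [synthetic_config()].
#' @return Array of dim `c(5, 28, 36)` on the 0-100 scale.
#' @export
polar_template <- function(config = synthetic_config()) {
  H <- 28; W <- 36
  r <- (row(matrix(0, H, W)) - (H + 1) / 2) / (H / 2)
  c_ <- (col(matrix(0, H, W)) - (W + 1) / 2) / (W / 2)
  radial <- sqrt(r^2 + c_^2) / sqrt(2)      # 0 center .. 1 corner
  base <- c(perfusion = 88, motion = 82, thickening = 78, phase = 50,
            amplitude = 72)
  falloff <- c(perfusion = 10, motion = 8, thickening = 8, phase = 0,
               amplitude = 6)
  out <- array(0, dim = c(5, H, W), dimnames = list(config$channels))
  for (ch in seq_len(5))
    out[ch, , ] <- base[ch] - falloff[ch] * radial^2
  out
}

# draw per-patient defect parameters; defect odds increase with prior PCI so
# image and clinical information are correlated (non-trivial SHAP structure)
.draw_defects <- function(config, prior_pci) {
  n <- length(prior_pci)
  present <- stats::runif(n) <
    stats::plogis(stats::qlogis(config$defect_prob) + 1.2 * prior_pci)
  amp <- stats::runif(n, config$defect_amplitude[1],
                      config$defect_amplitude[2]) * present
  data.frame(
    present = present, amplitude = amp,
    row0 = stats::runif(n, 5, 24), col0 = stats::runif(n, 5, 32),
    sigma_row = stats::runif(n, config$defect_sigma_row[1],
                             config$defect_sigma_row[2]),
    sigma_col = stats::runif(n, config$defect_sigma_col[1],
                             config$defect_sigma_col[2]))
}

#' Generate polar-map stacks with localized defects
#'
#' Each stack equals the smooth template minus a per-channel-scaled Gaussian
#' defect of drawn amplitude and extent, plus pixel noise, clipped to
#' `[0, 100]`.  The true defect extent `E` is the fraction of perfusion
#' pixels of the *noiseless* field below `extent_threshold` times the
#' template.
#'
#' @param config A [synthetic_config()].
#' @param defects Per-patient defect parameters (internal draw when NULL).
#' @param prior_pci Binary vector used to correlate defect presence with
#'   prior PCI when `defects` is NULL.
#' @param seed Seed for the draw (default from config).
#' @param compute_maps FALSE returns only the defect extents (the
#'   extent draw is identical either way; pixel noise is skipped).
#' @return List with `maps` (array n x 5 x 28 x 36, or NULL) and
#'   `extent` (vector E).
#' @export
generate_polar_maps <- function(config, defects = NULL, prior_pci = NULL,
                                seed = config$seed, compute_maps = TRUE) {
  template <- polar_template(config)
  H <- 28; W <- 36
  with_seed(sub_seed(seed, "polar_maps"), {
    if (is.null(defects)) {
      if (is.null(prior_pci)) prior_pci <- rep(0, config$n_patients)
      defects <- .draw_defects(config, prior_pci)
    }
    n <- nrow(defects)
    maps <- if (compute_maps) array(0, dim = c(n, 5, H, W))
    extent <- numeric(n)
    rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
    thr <- config$extent_threshold * template[1, , ]
    scl <- config$channel_defect_scale
    for (i in seq_len(n)) {
      d <- defects[i, ]
      field <- if (d$present) {
        d$amplitude * exp(-((rr - d$row0)^2 / (2 * d$sigma_row^2) +
                            (cc - d$col0)^2 / (2 * d$sigma_col^2)))
      } else matrix(0, H, W)
      extent[i] <- mean(template[1, , ] - field < thr)
      if (compute_maps) {
        for (ch in seq_len(5)) {
          clean <- template[ch, , ] - scl[ch] * field
          maps[i, ch, , ] <- pmin(pmax(
            clean + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W),
            0), 100)
        }
      }
    }
    list(maps = maps, extent = extent, defects = defects)
  })
}

# standardize the complete clinical table with the generator's theoretical
# marginals (the same scale the hazard coefficients are defined on)
.standardize_clinical <- function(config, clinical) {
  z <- as.matrix(clinical)
  for (nm in colnames(z)) {
    m <- config$marginals[[nm]]
    if (length(m) == 2) z[, nm] <- (z[, nm] - m["mean"]) / m["sd"]
  }
  z
}

#' Sample clinical covariates with registry-like marginals
#'
#' Continuous features are (truncated) Gaussian, binary features Bernoulli;
#' resting heart rate is correlated with age through a Gaussian copula
#' (rho = 0.3) and peak stress heart rate is lower under pharmacologic
#' stress.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed (default from config).
#' @return A complete (no missing values) data.frame of 15 features.
#' @export
generate_clinical <- function(config, seed = config$seed) {
  n <- config$n_patients
  m <- config$marginals
  with_seed(sub_seed(seed, "clinical"), {
    z_age <- stats::rnorm(n)
    z_hr <- 0.3 * z_age + sqrt(1 - 0.3^2) * stats::rnorm(n)
    pharm <- as.numeric(stats::runif(n) < m$stress_pharmacologic)
    df <- data.frame(
      age = pmin(pmax(m$age["mean"] + m$age["sd"] * z_age, 20), 95),
      male = as.numeric(stats::runif(n) < m$male),
      bmi = pmin(pmax(stats::rnorm(n, m$bmi["mean"], m$bmi["sd"]), 15), 55),
      prior_pci = as.numeric(stats::runif(n) < m$prior_pci),
      prior_cabg = as.numeric(stats::runif(n) < m$prior_cabg),
      prior_tavr = as.numeric(stats::runif(n) < m$prior_tavr),
      hypertension = as.numeric(stats::runif(n) < m$hypertension),
      diabetes = as.numeric(stats::runif(n) < m$diabetes),
      dyslipidemia = as.numeric(stats::runif(n) < m$dyslipidemia),
      family_history = as.numeric(stats::runif(n) < m$family_history),
      stress_pharmacologic = pharm,
      resting_hr = m$resting_hr["mean"] + m$resting_hr["sd"] * z_hr,
      peak_stress_hr = pmax(135 - 26 * pharm + stats::rnorm(n, 0, 20), 50),
      peak_stress_sbp = pmax(stats::rnorm(n, m$peak_stress_sbp["mean"],
                                          m$peak_stress_sbp["sd"]), 80),
      lvef = pmin(pmax(stats::rnorm(n, m$lvef["mean"], m$lvef["sd"]),
                       15), 80))
    rownames(df) <- NULL
    df
  })
}

# per-cause hazard matrices h_k(t | x), each n x T
.hazard_matrices <- function(config, z, extent, grid) {
  T_ <- grid$n_bins
  tfrac <- (seq_len(T_) - 1) / max(T_ - 1, 1)
  lapply(c("ACS", "death", "revascularization"), function(k) {
    lp <- drop(z %*% config$beta[, k]) + config$gamma[k] * extent
    b0t <- config$b0[k] + config$b0_slope[k] * tfrac
    stats::plogis(outer(lp, b0t, "+"))
  }) |> stats::setNames(c("ACS", "death", "revascularization"))
}

#' Sample competing-risks outcomes from known discrete hazards
#'
#' At each 30-day bin at most one cause fires: the first-event time is drawn
#' from `P(first event at t) = s(t) prod_{u<t} (1 - s(u))` with
#' `s(t) = sum_k h_k(t)`, and the cause at that bin is drawn multinomially
#' with probabilities `h_k(t) / s(t)`.  Censoring is independent: a
#' geometric loss-to-follow-up time (per-bin `dropout_hazard`) truncated by
#' the administrative window.  An event in the same bin as censoring is
#' observed.
#'
#' @param config A [synthetic_config()].
#' @param clinical Complete clinical data.frame (as from
#'   [generate_clinical()]).
#' @param extent True defect extents E.
#' @param grid A [time_grid()].
#' @param seed Seed (default from config).
#' @return List with `outcomes` (an [outcome_table()]) and `truth` (class
#'   `synthetic_truth`: per-patient hazard and CIF matrices plus `extent`).
#' @export
sample_outcomes <- function(config, clinical, extent, grid,
                            seed = config$seed) {
  z <- .standardize_clinical(config, clinical)
  h <- .hazard_matrices(config, z, extent, grid)
  n <- nrow(z); T_ <- grid$n_bins
  s_tot <- h[[1]] + h[[2]] + h[[3]]
  if (max(s_tot) > 1)
    stop("total per-bin hazard exceeds 1; rescale the configuration")
  truth <- synthetic_truth(h, extent, grid)
  with_seed(sub_seed(seed, "outcomes"), {
    # inverse-CDF draw of the first-event bin
    u <- stats::runif(n)
    cum <- matrix(0, n, T_)
    surv_prev <- rep(1, n)
    acc <- rep(0, n)
    for (t in seq_len(T_)) {
      acc <- acc + s_tot[, t] * surv_prev
      cum[, t] <- acc
      surv_prev <- surv_prev * (1 - s_tot[, t])
    }
    event_bin <- rowSums(cum < u)          # T_ if no event by horizon
    has_event <- event_bin < T_
    bin1 <- pmin(event_bin + 1L, T_)       # 1-based column of the event bin
    pick <- cbind(seq_len(n), bin1)
    ph <- cbind(h[[1]][pick], h[[2]][pick], h[[3]][pick])
    tot <- rowSums(ph)
    ph <- ph / ifelse(tot > 0, tot, 1)   # rows without events are unused
    u2 <- stats::runif(n)
    cause_idx <- 1L + (u2 > ph[, 1]) + (u2 > ph[, 1] + ph[, 2])
    cause <- c("ACS", "death", "revascularization")[cause_idx]
    # independent censoring: geometric dropout (in bins) + administrative
    drop_bin <- if (config$dropout_hazard > 0)
      stats::rgeom(n, config$dropout_hazard) else rep(Inf, n)
    admin_bin <- discretize_time(config$admin_censor_days, grid)
    cens_bin <- pmin(drop_bin, admin_bin)
    observed_event <- has_event & event_bin <= cens_bin
    kind <- ifelse(observed_event, cause, "censored")
    bin <- ifelse(observed_event, event_bin, cens_bin)
    outcomes <- outcome_table(kind, bin * grid$bin_width_days, grid)
    list(outcomes = outcomes, truth = truth)
  })
}

#' Ground-truth container with analytic cumulative incidence
#'
#' @param hazards Named list of three n x T hazard matrices.
#' @param extent True defect extents.
#' @param grid The [time_grid()].
#' @return Object of class `synthetic_truth` with `hazards`, `cif` (same
#'   shape), `surv` (n x T overall survival) and `extent`.
#' @export
synthetic_truth <- function(hazards, extent, grid) {
  s_tot <- hazards[[1]] + hazards[[2]] + hazards[[3]]
  n <- nrow(s_tot); T_ <- ncol(s_tot)
  surv <- matrix(0, n, T_)
  surv_prev <- rep(1, n)
  cif <- lapply(hazards, function(h) matrix(0, n, T_))
  acc <- lapply(hazards, function(h) rep(0, n))
  for (t in seq_len(T_)) {
    for (k in seq_along(hazards)) {
      acc[[k]] <- acc[[k]] + hazards[[k]][, t] * surv_prev
      cif[[k]][, t] <- acc[[k]]
    }
    surv_prev <- surv_prev * (1 - s_tot[, t])
    surv[, t] <- surv_prev
  }
  structure(list(hazards = hazards, cif = cif, surv = surv,
                 extent = extent, grid = grid),
            class = "synthetic_truth")
}

#' Query the analytic ground-truth CIF
#'
#' `CIF_k(t | x) = sum_{s<=t} h_k(s | x) prod_{u<s} (1 - sum_j h_j(u | x))`.
#'
#' @param truth A `synthetic_truth`.
#' @param patient Patient index (row).
#' @param event One of "ACS", "death", "revascularization".
#' @param bin Zero-based bin index (vectorized).
#' @return True cumulative incidence value(s).
#' @export
true_cif <- function(truth, patient, event, bin) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!event %in% names(truth$cif)) stop("unknown event: ", event)
  truth$cif[[event]][patient, bin + 1L]
}

#' Generate a complete synthetic cohort
#'
#' Draws clinical covariates, polar maps (defect presence correlated with
#' prior PCI), competing-risks outcomes and the analytic truth, and applies
#' the configured missingness to the exported clinical table.
#'
#' @param config A [synthetic_config()].
#' @param grid A [time_grid()].
#' @return List with `clinical` (NAs included), `clinical_complete`, `maps`,
#'   `extent`, `outcomes`, `truth`, `config`, `grid`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            grid = time_grid()) {
  clin <- generate_clinical(config)
  pm <- generate_polar_maps(config, prior_pci = clin$prior_pci)
  so <- sample_outcomes(config, clin, pm$extent, grid)
  clinical <- clin
  if (config$missing_rate > 0) {
    schema <- clinical_schema()
    cont <- schema$name[schema$kind == "continuous"]
    with_seed(sub_seed(config$seed, "missingness"), {
      for (nm in intersect(cont, names(clinical))) {
        miss <- stats::runif(nrow(clinical)) < config$missing_rate
        clinical[[nm]][miss] <- NA
      }
    })
  }
  list(clinical = clinical, clinical_complete = clin, maps = pm$maps,
       extent = pm$extent, outcomes = so$outcomes, truth = so$truth,
       config = config, grid = grid)
}
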