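#' Time-averaged event risk
#'
#' The scalar that patient-level explanations attribute: the mean of the
#' event's cumulative incidence function over all grid bins.
#'
#' @param surface A [risk_surface()] (single patient or batch).
#' @param event Event name.
#' @return Numeric vector (one value per patient).
#' @export
average_risk <- function(surface, event) {
  rowMeans(cif_matrix(surface, event))
}

# value-function machinery: players are the 15 clinical features plus the
# 5 polar-map channels (a present channel uses the patient's pixels, an
# absent one the background patient's pixels); the value of a coalition is
# the background-marginalized prediction
.player_names <- function(schema = clinical_schema()) {
  c(schema$name, c("map_perfusion", "map_motion", "map_thickening",
                   "map_phase", "map_amplitude"))
}

# build a composite batch: for each background row, patient values where
# the player is present, background values elsewhere; returns f averaged
# over the background
.coalition_value_fn <- function(model, patient_maps, patient_clin,
                                bg_maps, bg_clin, event) {
  B <- nrow(bg_clin)
  n_clin <- ncol(bg_clin)
  use_images <- model$arch$use_images
  eval_chunk <- function(subsets) {
    ns <- nrow(subsets)
    clin <- bg_clin[rep(seq_len(B), ns), , drop = FALSE]
    maps <- if (use_images)
      bg_maps[rep(seq_len(B), ns), , , , drop = FALSE]
    for (si in seq_len(ns)) {
      rows <- (si - 1L) * B + seq_len(B)
      on_clin <- which(subsets[si, seq_len(n_clin)])
      for (j in on_clin)
        clin[rows, j] <- patient_clin[j]
      if (use_images) {
        on_map <- which(subsets[si, n_clin + 1:5])
        for (ch in on_map)
          maps[rows, ch, , ] <- rep(patient_maps[1, ch, , ],
                                    each = length(rows))
      }
    }
    surf <- predict(model, maps, as.data.frame(clin))
    v <- average_risk(surf, event)
    # average over the background per subset
    vapply(seq_len(ns), function(si)
      mean(v[(si - 1L) * B + seq_len(B)]), 0)
  }
  # keep composite batches below ~2000 rows
  chunk <- max(1L, 2000L %/% B)
  function(subsets) {
    ns <- nrow(subsets)
    out <- numeric(ns)
    for (s0 in seq(1L, ns, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, ns)
      out[s0:s1] <- eval_chunk(subsets[s0:s1, , drop = FALSE])
    }
    out
  }
}

# shared Shapley engine: vfn maps a logical subset matrix (rows =
# coalitions over atomic players) to coalition values; `member` maps each
# (possibly grouped) player to its atomic indices
.shapley_engine <- function(vfn, member, np_atomic, n_perm, exact_max,
                            seed) {
  np <- length(member)
  expand <- function(S) {
    out <- logical(np_atomic)
    out[unlist(member[S])] <- TRUE
    out
  }
  if (np <= exact_max) {
    n_sub <- 2^np
    subs <- matrix(FALSE, n_sub, np_atomic)
    gmask <- matrix(FALSE, n_sub, np)
    for (s in seq_len(n_sub)) {
      bits <- as.logical(bitwAnd(s - 1L, 2^(seq_len(np) - 1L)))
      gmask[s, ] <- bits
      subs[s, ] <- expand(bits)
    }
    vals <- vfn(subs)
    phi <- numeric(np)
    fact <- factorial(np)
    for (j in seq_len(np)) {
      without <- which(!gmask[, j])
      k <- rowSums(gmask[without, , drop = FALSE])
      wgt <- factorial(k) * factorial(np - k - 1) / fact
      phi[j] <- sum(wgt * (vals[without + 2^(j - 1L)] - vals[without]))
    }
    list(phi = phi, se = rep(0, np), expected = vals[1],
         final = vals[n_sub], method = "exact")
  } else {
    contrib <- matrix(0, n_perm, np)
    with_seed(seed, {
      for (pi in seq_len(n_perm)) {
        ord <- sample.int(np)
        pres <- logical(np)
        subs <- matrix(FALSE, np + 1L, np_atomic)
        for (j in seq_len(np)) {
          pres[ord[j]] <- TRUE
          subs[j + 1L, ] <- expand(pres)
        }
        vals <- vfn(subs)
        contrib[pi, ord] <- diff(vals)
      }
    })
    phi <- colMeans(contrib)
    expected <- vfn(matrix(FALSE, 1, np_atomic))
    list(phi = phi, se = apply(contrib, 2, stats::sd) / sqrt(n_perm),
         expected = expected,
         # exact by the telescoping sum within each permutation
         final = expected + sum(phi), method = "permutation")
  }
}

#' Shapley values of a generic prediction function
#'
#' Low-level estimator used by [shapley_attributions()]: players are the
#' columns of a feature matrix, an absent player takes the background
#' row's value, and the value of a coalition is the mean prediction over
#' the background sample.
#'
#' @param f Function mapping a numeric matrix (rows = inputs) to a numeric
#'   vector of predictions.
#' @param x Numeric vector, the input being explained.
#' @param background Numeric matrix of background rows (same columns).
#' @param n_perm,exact_max,seed As in [shapley_attributions()].
#' @return List with `phi`, `se`, `expected`, `final`, `method`.
#' @export
shapley_values <- function(f, x, background, n_perm = 128,
                           exact_max = 12, seed = 1) {
  background <- as.matrix(background)
  np <- length(x)
  stopifnot(ncol(background) == np)
  if (nrow(background) == 0) stop("empty background set")
  B <- nrow(background)
  vfn <- function(subsets) {
    ns <- nrow(subsets)
    rows <- background[rep(seq_len(B), ns), , drop = FALSE]
    for (si in seq_len(ns)) {
      on <- which(subsets[si, ])
      if (length(on))
        rows[(si - 1L) * B + seq_len(B), on] <-
          matrix(x[on], B, length(on), byrow = TRUE)
    }
    v <- f(rows)
    vapply(seq_len(ns), function(si) mean(v[(si - 1L) * B + seq_len(B)]), 0)
  }
  member <- as.list(seq_len(np))
  .shapley_engine(vfn, member, np, n_perm, exact_max, seed)
}

#' Shapley attributions for one patient
#'
#' Attributes the patient's time-averaged event risk to 20 players: the 15
#' clinical features and the 5 polar-map channels (each channel is an
#' atomic player whose "absent" state takes a background patient's pixels;
#' the channel's attribution equals the sum of per-pixel attributions under
#' the same marginal value function).  With at most `exact_max` players
#' (after optional grouping) the Shapley value is computed exactly by
#' subset enumeration; otherwise by a Monte-Carlo permutation estimator
#' whose efficiency (sum of attributions = f(x) - E[f]) holds exactly by
#' construction.
#'
#' @param model A fitted `deephit_model` (with preprocessing state).
#' @param maps Patient polar maps, array `1 x 5 x 28 x 36` (raw scale);
#'   NULL for clinical-only models.
#' @param clinical Patient clinical row (raw data.frame, 1 row).
#' @param background List with `maps` and `clinical` for the background
#'   sample (training patients).
#' @param event Event to explain.
#' @param groups Optional named list collapsing players into groups (names
#'   = group label, values = character vectors of player names); grouped
#'   players enter coalitions together.
#' @param n_perm Number of Monte-Carlo permutations (default 128).
#' @param exact_max Enumerate exactly when players <= this (default 12).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `attribution`: data.frame (`feature`,
#'   `contribution`, `se`) ordered by |contribution|, with attributes
#'   `expected_value` (E[f] over background), `final_value` (f(x)),
#'   `event`, `method`.
#' @export
shapley_attributions <- function(model, maps, clinical, background, event,
                                 groups = NULL, n_perm = 128,
                                 exact_max = 12, seed = 1) {
  if (is.null(background$clinical) || nrow(background$clinical) == 0)
    stop("empty background set")
  imp <- model$preprocess$imputer
  pat_clin <- as.numeric(apply_imputer(imp, clinical))
  bg_clin <- as.matrix(apply_imputer(imp, background$clinical))
  players <- .player_names()
  if (!model$arch$use_images) players <- players[seq_len(15)]
  np_atomic <- length(players)
  if (is.null(groups)) {
    member <- as.list(seq_len(np_atomic))
    names(member) <- players
  } else {
    member <- lapply(groups, function(g) {
      idx <- match(g, players)
      if (anyNA(idx)) stop("unknown player in groups: ",
                           paste(g[is.na(idx)], collapse = ", "))
      idx
    })
    left <- setdiff(seq_len(np_atomic), unlist(member))
    member <- c(member, stats::setNames(as.list(left), players[left]))
  }
  np <- length(member)
  vfn <- .coalition_value_fn(model, maps, pat_clin, background$maps,
                             bg_clin, event)
  res <- .shapley_engine(vfn, member, np_atomic, n_perm, exact_max,
                         sub_seed(seed, "shapley"))
  phi <- res$phi; se <- res$se
  ev <- res$expected; fx <- res$final; method <- res$method
  out <- data.frame(feature = names(member), contribution = phi, se = se,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$contribution)), ]
  rownames(out) <- NULL
  structure(out, expected_value = ev, final_value = fx, event = event,
            method = method, class = c("attribution", "data.frame"))
}

#' Waterfall-ordered explanation record
#'
#' Orders attributions by decreasing magnitude, truncates to `top_n` rows
#' with a residual "all others" row, and carries the running total from the
#' population expected value down to the patient's final value.
#'
#' @param attr An `attribution` from [shapley_attributions()].
#' @param top_n Number of named rows to keep.
#' @return Data.frame (`feature`, `contribution`, `direction`,
#'   `running_total`) with attributes `expected_value`, `final_value`.
#' @export
waterfall_data <- function(attr, top_n = 10) {
  if (top_n < 1) stop("`top_n` must be at least 1")
  ev <- attr(attr, "expected_value")
  fx <- attr(attr, "final_value")
  df <- attr[order(-abs(attr$contribution)), c("feature", "contribution")]
  if (nrow(df) > top_n) {
    rest <- sum(df$contribution[-seq_len(top_n)])
    df <- rbind(df[seq_len(top_n), ],
                data.frame(feature = "all others", contribution = rest))
  }
  df$direction <- ifelse(df$contribution >= 0, "risk-increasing",
                         "risk-decreasing")
  df$running_total <- ev + cumsum(df$contribution)
  rownames(df) <- NULL
  structure(df, expected_value = ev, final_value = fx,
            event = attr(attr, "event"))
}

#' Counterfactual what-if simulation
#'
#' Re-predicts a patient with named clinical features replaced by
#' counterfactual values (polar maps unchanged; the model's stored
#' training normalization is reapplied) and reports the percent reduction
#' in time-averaged risk, plus full before/after CIF curves for all
#' events.
#'
#' @param model A fitted `deephit_model`.
#' @param maps Patient maps (raw scale) or NULL.
#' @param clinical Patient clinical row (raw).
#' @param modifications Named list of replacement values, e.g.
#'   `list(resting_hr = 70)`.
#' @param event Event whose average risk is reported.
#' @return List with `delta_percent` (positive = risk reduction),
#'   `risk_before`, `risk_after`, and `curves` (data.frame: event, t_days,
#'   cif_before, cif_after).
#' @export
counterfactual_delta <- function(model, maps, clinical, modifications,
                                 event) {
  unknown <- setdiff(names(modifications), names(clinical))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  before <- predict(model, maps, clinical)
  clin2 <- clinical
  for (nm in names(modifications)) clin2[[nm]] <- modifications[[nm]]
  after <- predict(model, maps, clin2)
  f0 <- average_risk(before, event)
  f1 <- average_risk(after, event)
  if (f0 == 0) {
    warning("baseline risk is zero; percent change undefined")
    dp <- NA_real_
  } else {
    dp <- 100 * (f0 - f1) / f0
  }
  grid <- model$grid
  curves <- do.call(rbind, lapply(before$events, function(ev)
    data.frame(event = ev, t_days = grid$bin_days,
               cif_before = as.vector(cif_matrix(before, ev)),
               cif_after = as.vector(cif_matrix(after, ev)))))
  list(delta_percent = dp, risk_before = f0, risk_after = f1,
       curves = curves)
}

#' Individual CIF curves across an ensemble of models
#'
#' @param surfaces List of [risk_surface()]s (one per model) covering the
#'   same patients.
#' @param patient Patient index.
#' @return Data.frame (`event`, `t_days`, `model_id`, `cif`) including a
#'   `model_id = "mean"` row set with the across-model average.
#' @export
patient_curves <- function(surfaces, patient) {
  if (!length(surfaces)) stop("no prediction sets supplied")
  grid <- surfaces[[1]]$grid
  events <- surfaces[[1]]$events
  out <- list()
  for (ev in events) {
    per_model <- vapply(surfaces, function(s)
      cif_matrix(s, ev)[patient, ], numeric(grid$n_bins))
    per_model <- matrix(per_model, nrow = grid$n_bins)
    for (mi in seq_along(surfaces))
      out[[length(out) + 1L]] <- data.frame(
        event = ev, t_days = grid$bin_days,
        model_id = as.character(mi), cif = per_model[, mi])
    out[[length(out) + 1L]] <- data.frame(
      event = ev, t_days = grid$bin_days, model_id = "mean",
      cif = rowMeans(per_model))
  }
  do.call(rbind, out)
}
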