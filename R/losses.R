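#' Loss configuration
#'
#' The training objective mixes the hitting-time log-likelihood with an
#' event-specific pairwise ranking term:
#' `alpha * L_likelihood + (1 - alpha) * L_ranking`.
#'
#' @param alpha Mixing weight in `[0, 1]`.
#' @param sigma Scale of the ranking kernel `exp(-(a - b) / sigma)`.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, sigma = 0.1) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (sigma <= 0) stop("`sigma` must be positive")
  structure(list(alpha = alpha, sigma = sigma), class = "loss_config")
}

# integer cause codes aligned with surface$events; 0 = censored
.event_codes <- function(outcomes, events) {
  k <- match(outcomes$event_kind, events)
  k[outcomes$event_kind == "censored"] <- 0L
  if (any(is.na(k))) stop("outcome event kinds not present in the surface")
  k
}

#' Hitting-time negative log-likelihood
#'
#' Mean over the batch of `-log y[k_i, t_i]` for a patient with observed
#' event `k_i` in bin `t_i`, and `-log(1 - sum_k cif_k(t_i))` for a patient
#' censored in bin `t_i`.  Probabilities are floored at 1e-12 before the
#' logarithm.
#'
#' @param surface A [risk_surface()].
#' @param outcomes An [outcome_table()] on the same grid.
#' @return Scalar loss.
#' @export
likelihood_loss <- function(surface, outcomes) {
  n <- n_patients(surface)
  stopifnot(nrow(outcomes) == n)
  k <- .event_codes(outcomes, surface$events)
  t1 <- outcomes$bin_index + 1L
  if (any(t1 < 1L | t1 > surface$grid$n_bins)) stop("bin index out of range")
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    contrib[i] <- if (k[i] > 0) {
      -log(max(surface$pmf[i, k[i], t1[i]], 1e-12))
    } else {
      -log(max(surface$surv[i, t1[i]], 1e-12))
    }
  }
  mean(contrib)
}

#' Event-specific pairwise ranking loss
#'
#' For every event `k` and every ordered pair `(i, j)` where `i` had event
#' `k` in bin `t_i` and `j` was still event-free and under observation after
#' `t_i` (`t_j > t_i`), the pair contributes
#' `exp(-(cif_k(t_i | x_i) - cif_k(t_i | x_j)) / sigma)`.  The mean over
#' valid pairs is returned (0 when no pair is valid), so batch size does not
#' rescale the term.
#'
#' @param surface A [risk_surface()].
#' @param outcomes An [outcome_table()] on the same grid.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
ranking_loss <- function(surface, outcomes, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  k <- .event_codes(outcomes, surface$events)
  tv <- outcomes$bin_index
  total <- 0; count <- 0
  for (ev in seq_along(surface$events)) {
    ii <- which(k == ev)
    if (!length(ii)) next
    Ck <- cif_matrix(surface, surface$events[ev])   # n x T
    for (i in ii) {
      js <- which(tv > tv[i])
      if (!length(js)) next
      a <- Ck[i, tv[i] + 1L]
      b <- Ck[js, tv[i] + 1L]
      total <- total + sum(exp(-(a - b) / cfg$sigma))
      count <- count + length(js)
    }
  }
  if (count == 0) 0 else total / count
}

#' Combined training loss
#'
#' @inheritParams ranking_loss
#' @return `alpha * likelihood + (1 - alpha) * ranking`.
#' @export
total_loss <- function(surface, outcomes, cfg = loss_config()) {
  cfg$alpha * likelihood_loss(surface, outcomes) +
    (1 - cfg$alpha) * ranking_loss(surface, outcomes, cfg)
}

# loss value and gradient wrt the softmax logits, on the training
# representation: pmf matrix (K*T x n, event index fastest), integer cause
# codes kv (0 censored) and 0-based bins tv
.loss_and_grad <- function(pmf, kv, tv, K, T_, cfg) {
  n <- ncol(pmf)
  M <- array(pmf, dim = c(K, T_, n))
  tot <- apply(M, c(2, 3), sum)                       # T x n
  tot <- matrix(tot, nrow = T_)
  cumtot <- apply(tot, 2, cumsum)
  cumtot <- matrix(cumtot, nrow = T_)
  ## likelihood term and its logit gradient
  L1 <- 0
  dz1 <- matrix(0, K * T_, n)
  cell <- function(k, t) k + K * t                    # row of (k, t)
  for (i in seq_len(n)) {
    if (kv[i] > 0) {
      r <- cell(kv[i], tv[i])
      L1 <- L1 - log(max(pmf[r, i], 1e-12))
      dz1[, i] <- pmf[, i]
      dz1[r, i] <- dz1[r, i] - 1
    } else {
      S <- 1 - cumtot[tv[i] + 1L, i]
      L1 <- L1 - log(max(S, 1e-12))
      if (S > 1e-12) {
        inB <- rep(seq_len(T_) - 1L <= tv[i], each = K)
        dz1[, i] <- pmf[, i] * (inB - 1 + S) / S
      }
      # at the probability floor the loss is flat: no gradient signal
    }
  }
  L1 <- L1 / n
  dz1 <- dz1 / n
  ## ranking term on the cause-specific CIFs
  L2 <- 0; count <- 0
  gy <- matrix(0, K * T_, n)                          # dL2/dpmf (unscaled)
  for (ev in seq_len(K)) {
    ii <- which(kv == ev)
    if (!length(ii)) next
    Ck <- apply(matrix(M[ev, , ], nrow = T_), 2, cumsum)
    Ck <- matrix(Ck, nrow = T_)                       # T x n
    dC <- matrix(0, T_, n)
    for (i in ii) {
      js <- which(tv > tv[i])
      if (!length(js)) next
      r <- tv[i] + 1L
      eta <- exp(-(Ck[r, i] - Ck[r, js]) / cfg$sigma)
      L2 <- L2 + sum(eta)
      count <- count + length(js)
      dC[r, i] <- dC[r, i] - sum(eta) / cfg$sigma
      dC[r, js] <- dC[r, js] + eta / cfg$sigma
    }
    if (any(dC != 0)) {
      # dL/dy[ev, s, j] = sum_{t >= s} dC[t, j]
      dyk <- apply(dC, 2, function(v) rev(cumsum(rev(v))))
      gy[cell(ev, seq_len(T_) - 1L), ] <- gy[cell(ev, seq_len(T_) - 1L), ] +
        matrix(dyk, nrow = T_)
    }
  }
  if (count > 0) {
    L2 <- L2 / count
    gy <- gy / count
    # softmax vector-Jacobian product per column
    dz2 <- pmf * sweep(gy, 2, colSums(gy * pmf), "-")
  } else {
    dz2 <- matrix(0, K * T_, n)
  }
  list(loss = cfg$alpha * L1 + (1 - cfg$alpha) * L2,
       likelihood = L1, ranking = L2,
       dlogits = cfg$alpha * dz1 + (1 - cfg$alpha) * dz2)
}
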