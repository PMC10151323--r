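#' Training configuration
#'
#' Minibatch Adam with early stopping: within each fold's training data a
#' random 20% validation split drives model selection (lowest validation
#' total loss), and training stops after `patience` epochs without
#' improvement.
#'
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs.
#' @param lr Adam learning rate (beta1 0.9, beta2 0.999).
#' @param val_fraction Fraction of training rows held out for validation.
#' @param seed Integer seed for split, shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 256, max_epochs = 30, patience = 10,
                         lr = 1e-3, val_fraction = 0.2, seed = 1,
                         verbose = FALSE) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# evaluation-mode total loss on a patient subset
.eval_loss <- function(model, maps, clinical, kv, tv, loss_cfg) {
  fw <- .net_forward(model, maps, clinical, training = FALSE)
  .loss_and_grad(fw$pmf, kv, tv, model$arch$n_events, model$grid$n_bins,
                 loss_cfg)$loss
}

#' Fit the hitting-time network on one training set
#'
#' Fits the imputer and normalizer on the supplied rows, holds out a
#' stratified validation fraction for early stopping, and trains with
#' minibatch Adam on the mixed likelihood/ranking loss.  The fitted
#' preprocessing state is stored in the returned model so test data is
#' always transformed with training statistics only.
#'
#' @param maps Raw polar maps, array `n x 5 x 28 x 36` on the 0-100 scale
#'   (NULL for clinical-only architectures).
#' @param clinical Raw clinical data.frame (NAs allowed).
#' @param outcomes An [outcome_table()] for the same patients.
#' @param arch An [arch_config()].
#' @param grid A [time_grid()].
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param schema Clinical feature schema.
#' @return A fitted `deephit_model` with `$preprocess` and `$history`.
#' @export
deephit_fit <- function(maps, clinical, outcomes, arch = arch_config(),
                        grid = time_grid(), train_cfg = train_config(),
                        loss_cfg = loss_config(),
                        schema = clinical_schema()) {
  n <- nrow(clinical)
  stopifnot(nrow(outcomes) == n)
  imp <- fit_imputer(clinical, schema)
  clin_imp <- apply_imputer(imp, clinical)
  norm <- fit_normalizer(clin_imp, schema)
  X <- normalize_clinical(norm, clin_imp)
  Xmaps <- if (arch$use_images) normalize_maps(maps)
  kv <- .event_codes(outcomes,
                     c("ACS", "death", "revascularization")[
                       seq_len(arch$n_events)])
  tv <- outcomes$bin_index
  model <- init_model(arch, grid, seed = train_cfg$seed)
  model$preprocess <- list(imputer = imp, normalizer = norm,
                           schema = schema)
  ## stratified validation split for early stopping / model selection
  val_idx <- with_seed(sub_seed(train_cfg$seed, "valsplit"), {
    unlist(lapply(split(seq_len(n), outcomes$event_kind), function(ix) {
      m <- max(1L, round(length(ix) * train_cfg$val_fraction))
      ix[sample.int(length(ix), m)]
    }), use.names = FALSE)
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  vmaps <- if (arch$use_images) Xmaps[val_idx, , , , drop = FALSE]
  vX <- X[val_idx, , drop = FALSE]
  opt <- .adam_init(model$params)
  best <- list(loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  bad <- 0L
  history <- NULL
  with_seed(sub_seed(train_cfg$seed, "sgd"), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      nb <- ceiling(length(ord) / train_cfg$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        bi <- ord[((b - 1L) * train_cfg$batch_size + 1L):
                    min(b * train_cfg$batch_size, length(ord))]
        bmaps <- if (arch$use_images) Xmaps[bi, , , , drop = FALSE]
        fw <- .net_forward(model, bmaps, X[bi, , drop = FALSE],
                           training = TRUE, cache = TRUE)
        model$running[names(fw$running)] <- fw$running
        lg <- .loss_and_grad(fw$pmf, kv[bi], tv[bi], arch$n_events,
                             grid$n_bins, loss_cfg)
        grads <- .net_backward(model, fw, lg$dlogits)
        upd <- .adam_step(model$params, grads, opt, train_cfg$lr)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bi)
      }
      ep_loss <- ep_loss / length(ord)
      val_loss <- .eval_loss(model, vmaps, vX, kv[val_idx], tv[val_idx],
                             loss_cfg)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss,
                                  val_loss = val_loss))
      if (train_cfg$verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch, ep_loss,
                        val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = model$params,
                     running = model$running, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= train_cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$running <- best$running
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Predict risk surfaces for raw cohort data
#'
#' Applies the model's stored imputer and normalizer (fitted on its own
#' training rows) before the forward pass.
#'
#' @param object A fitted `deephit_model`.
#' @param maps Raw polar maps on the 0-100 scale (NULL for clinical-only).
#' @param clinical Raw clinical data.frame.
#' @param ... Unused.
#' @return A [risk_surface()].
#' @export
predict.deephit_model <- function(object, maps, clinical, ...) {
  if (is.null(object$preprocess))
    stop("model carries no stored preprocessing state")
  clin <- apply_imputer(object$preprocess$imputer, clinical)
  X <- normalize_clinical(object$preprocess$normalizer, clin)
  m <- if (object$arch$use_images) normalize_maps(maps)
  forward(object, m, X)
}

#' 10-fold cross-validated training
#'
#' Implements the repeated hold-out protocol: the cohort is split into `k`
#' stratified folds; for each fold a model is trained on the other `k - 1`
#' (with its own imputer/normalizer and internal 20% validation split) and
#' predicts the held-out fold.  Out-of-fold predictions are concatenated so
#' every patient is predicted exactly once by a model that never saw them.
#'
#' @param cohort List with `maps`, `clinical`, `outcomes` (as produced by
#'   [generate_cohort()] or [read_cohort()]).
#' @param arch An [arch_config()].
#' @param grid A [time_grid()].
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param k Number of folds.
#' @param seed Master seed (folds, per-fold training).
#' @return List with `models` (length `k`), `oof` (a [risk_surface()] in
#'   original patient order), `fold` (fold id per patient).
#' @export
train_cv <- function(cohort, arch = arch_config(), grid = time_grid(),
                     train_cfg = train_config(), loss_cfg = loss_config(),
                     k = 10, seed = 1) {
  outcomes <- cohort$outcomes
  n <- nrow(outcomes)
  fold <- stratified_kfold(outcomes, k = k, seed = sub_seed(seed, "folds"))
  K <- arch$n_events; T_ <- grid$n_bins
  pmf <- array(NA_real_, dim = c(n, K, T_))
  models <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(intersect(te, tr)))
      stop("leakage: test patients present in the training set")
    cfg_f <- train_cfg
    cfg_f$seed <- sub_seed(seed, "fold_fit", f)
    m <- deephit_fit(
      if (arch$use_images) cohort$maps[tr, , , , drop = FALSE],
      cohort$clinical[tr, , drop = FALSE],
      outcomes[tr, , drop = FALSE],
      arch, grid, cfg_f, loss_cfg)
    surf <- predict(m,
                    if (arch$use_images) cohort$maps[te, , , , drop = FALSE],
                    cohort$clinical[te, , drop = FALSE])
    pmf[te, , ] <- surf$pmf
    models[[f + 1L]] <- m
    if (train_cfg$verbose)
      message(sprintf("fold %d: best epoch %d, val loss %.4f",
                      f, m$best_epoch,
                      min(m$history$val_loss)))
  }
  if (anyNA(pmf)) stop("out-of-fold predictions do not cover the cohort")
  list(models = models,
       oof = risk_surface(pmf, grid,
                          events = c("ACS", "death",
                                     "revascularization")[seq_len(K)]),
       fold = fold)
}

#' Evaluate an ensemble of fold models on an external cohort
#'
#' Each of the `k` cross-validation models predicts the full external
#' cohort using its own stored preprocessing state; downstream metrics are
#' computed per prediction set and summarized across models.
#'
#' @param models List of fitted `deephit_model`s.
#' @param cohort External cohort list (`maps`, `clinical`).
#' @return List of [risk_surface()]s, one per model.
#' @export
predict_external <- function(models, cohort) {
  lapply(models, function(m) {
    predict(m, if (m$arch$use_images) cohort$maps, cohort$clinical)
  })
}
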