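#' Stratified k-fold assignment
#'
#' Partitions the cohort into `k` folds with the same fraction of each
#' adjudicated event kind (to within one patient per stratum), as used by
#' the 10-fold repeated hold-out training protocol.  Deterministic for a
#' given seed; the caller's RNG state is left untouched.
#'
#' @param outcomes An [outcome_table()] (or any data.frame with an
#'   `event_kind` column).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `0:(k-1)`, one per patient.
#' @export
stratified_kfold <- function(outcomes, k = 10, seed = 1) {
  n <- nrow(outcomes)
  if (n < k) stop("fewer patients than folds")
  fold <- integer(n)
  with_seed(seed, {
    for (s in unique(outcomes$event_kind)) {
      idx <- which(outcomes$event_kind == s)
      if (length(idx) < k)
        warning("stratum '", s, "' has fewer patients than folds; ",
                "distributed round-robin")
      # shuffle members, deal fold labels in a shuffled round-robin so the
      # strata that do not divide evenly overflow into random folds
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k) - 1L, length(idx))
    }
  })
  fold
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so library randomness never perturbs user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so results of one module do not depend on how much randomness
#' another module consumed.
#'
#' @param seed Master integer seed.
#' @param name Substream name.
#' @param i Optional integer index (e.g. fold number).
#' @return A deterministic integer seed below 2^31.
#' @export
sub_seed <- function(seed, name, i = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + as.numeric(i) * 13) %%
               2147483647)
}
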