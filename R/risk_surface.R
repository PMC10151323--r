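#' Per-patient joint event-time probability surfaces
#'
#' The model output for a batch of patients: a probability mass `y[k, t]`
#' for each event kind `k` and time bin `t`, normalized over all `K x T`
#' cells, with derived cumulative incidence
#' `cif_k(t) = sum_{s<=t} y[k, s]` and survival
#' `S(t) = 1 - sum_k cif_k(t)`.
#'
#' @param pmf Numeric array of dim `c(n, K, T)`, or a `(K*T) x n` matrix
#'   whose rows run over events fastest.
#' @param grid A [time_grid()].
#' @param events Event names (default the three MACE components).
#' @return Object of class `risk_surface` with fields `pmf`, `cif`
#'   (arrays `n x K x T`), `surv` (matrix `n x T`), `events`, `grid`.
#' @export
risk_surface <- function(pmf, grid,
                         events = c("ACS", "death", "revascularization")) {
  K <- length(events)
  if (is.matrix(pmf)) {
    stopifnot(nrow(pmf) == K * grid$n_bins)
    n <- ncol(pmf)
    pmf <- aperm(array(pmf, dim = c(K, grid$n_bins, n)), c(3, 1, 2))
  }
  stopifnot(length(dim(pmf)) == 3, dim(pmf)[2] == K,
            dim(pmf)[3] == grid$n_bins)
  n <- dim(pmf)[1]
  if (grid$n_bins == 1L) {
    cif <- pmf
  } else {
    cif <- aperm(apply(pmf, c(1, 2), cumsum), c(2, 3, 1))
    if (n == 1) cif <- array(cif, dim = dim(pmf))
  }
  surv <- 1 - apply(cif, c(1, 3), sum)
  surv <- matrix(surv, nrow = n)
  dimnames(pmf) <- dimnames(cif) <- list(NULL, events, NULL)
  structure(list(pmf = pmf, cif = cif, surv = surv, events = events,
                 grid = grid),
            class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("risk_surface: %d patients x %d events x %d bins\n",
              dim(x$pmf)[1], dim(x$pmf)[2], dim(x$pmf)[3]))
  invisible(x)
}

#' Number of patients in a risk surface
#' @param surface A [risk_surface()].
#' @export
n_patients <- function(surface) dim(surface$pmf)[1]

#' Extract a cumulative incidence matrix
#'
#' @param surface A [risk_surface()].
#' @param event Event name, or `"MACE"` for the sum over all events.
#' @return Matrix `n x T` of CIF values.
#' @export
cif_matrix <- function(surface, event) {
  if (event == "MACE") {
    m <- surface$cif[, 1, ] + surface$cif[, 2, ] + surface$cif[, 3, ]
    matrix(m, nrow = dim(surface$cif)[1])
  } else {
    if (!event %in% surface$events) stop("unknown event: ", event)
    matrix(surface$cif[, event, ], nrow = dim(surface$cif)[1])
  }
}

#' Subset a risk surface by patient
#' @param surface A [risk_surface()].
#' @param idx Patient indices.
#' @export
subset_surface <- function(surface, idx) {
  risk_surface(surface$pmf[idx, , , drop = FALSE], surface$grid,
               surface$events)
}

#' Row-bind risk surfaces on the same grid
#' @param ... `risk_surface` objects.
#' @export
rbind_surfaces <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "risk_surface"))
    xs <- xs[[1]]
  pmf <- do.call(abind3, lapply(xs, function(s) s$pmf))
  risk_surface(pmf, xs[[1]]$grid, xs[[1]]$events)
}

# bind 3-D arrays along the first margin
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, dim = c(sum(vapply(xs, function(x) dim(x)[1], 0L)),
                          d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}
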