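#' Discrete 30-day time grid
#'
#' The model, losses and metrics share a common discretization of follow-up
#' time: probabilities are carried at time 0 and every `bin_width_days` up to
#' `horizon_days`.  With the default horizon of 3900 days and 30-day bins the
#' grid has 131 columns.
#'
#' Bin `t` (zero-based) covers the right-closed interval
#' `((t-1) * bin_width, t * bin_width]`; day 0 falls in bin 0.
#'
#' @param horizon_days Maximum follow-up time in days.
#' @param bin_width_days Width of one bin in days (default 30).
#' @return An object of class `time_grid` with fields `horizon_days`,
#'   `bin_width_days`, `n_bins` and `bin_days` (the grid points in days).
#' @examples
#' g <- time_grid()
#' g$n_bins  # 131
#' @export
time_grid <- function(horizon_days = 3900, bin_width_days = 30) {
  if (!is.numeric(bin_width_days) || length(bin_width_days) != 1 ||
      bin_width_days <= 0)
    stop("`bin_width_days` must be a single positive number")
  if (!is.numeric(horizon_days) || length(horizon_days) != 1 ||
      horizon_days < bin_width_days)
    stop("`horizon_days` must be >= `bin_width_days`")
  n_bins <- as.integer(floor(horizon_days / bin_width_days)) + 1L
  structure(
    list(horizon_days = as.integer(horizon_days),
         bin_width_days = as.integer(bin_width_days),
         n_bins = n_bins,
         bin_days = as.integer(seq_len(n_bins) - 1L) *
           as.integer(bin_width_days)),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d bins of %d days (horizon %d days)\n",
              x$n_bins, x$bin_width_days, x$horizon_days))
  invisible(x)
}

#' Map times in days to grid bins
#'
#' Day 0 maps to bin 0; day `d > 0` maps to `ceiling(d / bin_width)`, clamped
#' to the last bin of the grid.
#'
#' @param time_days Vector of non-negative times in days.
#' @param grid A [time_grid()].
#' @return Integer vector of zero-based bin indices in `[0, n_bins - 1]`.
#' @export
discretize_time <- function(time_days, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (any(!is.finite(time_days)) || any(time_days < 0))
    stop("`time_days` must be finite and non-negative")
  pmin.int(as.integer(ceiling(time_days / grid$bin_width_days)),
           grid$n_bins - 1L)
}
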