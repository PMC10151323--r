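# shared fixtures: tiny grids, hand-written probability surfaces and small
# synthetic cohorts used across test files

tiny_grid <- function(T_ = 5, width = 30) {
  time_grid(horizon_days = width * (T_ - 1), bin_width_days = width)
}

# a valid risk surface from explicit per-patient (K x T) mass grids
surface_from_list <- function(grids, grid) {
  K <- nrow(grids[[1]])
  pmf <- array(0, dim = c(length(grids), K, ncol(grids[[1]])))
  for (i in seq_along(grids)) pmf[i, , ] <- grids[[i]]
  risk_surface(pmf, grid,
               events = c("ACS", "death", "revascularization")[seq_len(K)])
}

# random normalized surfaces (softmax of random logits)
random_surface <- function(n, grid, K = 3, seed = 1) {
  set.seed(seed)
  logits <- matrix(rnorm(K * grid$n_bins * n), K * grid$n_bins, n)
  pmf <- apply(logits, 2, function(z) exp(z) / sum(exp(z)))
  risk_surface(matrix(pmf, K * grid$n_bins, n), grid,
               events = c("ACS", "death", "revascularization")[seq_len(K)])
}

small_cohort <- function(n = 80, seed = 5, grid = time_grid()) {
  generate_cohort(synthetic_config(n_patients = n, seed = seed), grid)
}

tiny_arch <- function(...) {
  arch_config(conv_channels = c(2, 3), image_dense_width = 8,
              clinical_dense_width = 6, shared_width = 8, head_width = 6,
              ...)
}
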