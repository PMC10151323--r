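# independent brute-force reference implementations, written directly from
# the loss definitions
brute_likelihood <- function(surface, outcomes) {
  n <- n_patients(surface)
  acc <- 0
  for (i in seq_len(n)) {
    k <- outcomes$event_kind[i]
    t1 <- outcomes$bin_index[i] + 1
    if (k == "censored") {
      s <- 1 - sum(vapply(surface$events, function(ev)
        cif_matrix(surface, ev)[i, t1], 0))
      acc <- acc - log(max(s, 1e-12))
    } else {
      acc <- acc - log(max(surface$pmf[i, k, t1], 1e-12))
    }
  }
  acc / n
}

brute_ranking <- function(surface, outcomes, cfg) {
  n <- n_patients(surface)
  tot <- 0; cnt <- 0
  for (ev in surface$events) {
    C <- cif_matrix(surface, ev)
    for (i in seq_len(n)) {
      if (outcomes$event_kind[i] != ev) next
      for (j in seq_len(n)) {
        if (outcomes$bin_index[j] <= outcomes$bin_index[i]) next
        a <- C[i, outcomes$bin_index[i] + 1]
        b <- C[j, outcomes$bin_index[i] + 1]
        tot <- tot + exp(-(a - b) / cfg$sigma)
        cnt <- cnt + 1
      }
    }
  }
  if (cnt == 0) 0 else tot / cnt
}

test_that("likelihood loss matches brute force on hand-written grids", {
  g <- tiny_grid(T_ = 3)
  grids <- list(rbind(c(0.2, 0.1, 0.0), c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.1)),
                rbind(c(0.05, 0.05, 0.1), c(0.2, 0.1, 0.1), c(0.1, 0.2, 0.05)),
                rbind(c(0.3, 0.1, 0.1), c(0.1, 0.05, 0.05), c(0.1, 0.1, 0.1)))
  s <- surface_from_list(grids, g)
  out <- outcome_table(c("ACS", "censored", "death"), c(0, 60, 30), g)
  expect_equal(likelihood_loss(s, out), brute_likelihood(s, out),
               tolerance = 1e-8)
  # direct arithmetic on the written-out grid:
  # patient 1: -log y[ACS, 0]; patient 2: -log(1 - sum cif(2));
  # patient 3: -log y[death, 1]
  expected <- -(log(0.2) + log(1 - 0.95) + log(0.05)) / 3
  expect_equal(likelihood_loss(s, out), expected, tolerance = 1e-8)
})

test_that("censoring at the last bin contributes -log survival there", {
  g <- tiny_grid(T_ = 3)
  grids <- list(rbind(c(0.1, 0.1, 0.0), c(0.1, 0.0, 0.1), c(0.0, 0.0, 0.0)))
  s <- surface_from_list(grids, g)     # total CIF at last bin = 0.4
  out <- outcome_table("censored", 60, g)
  expect_equal(likelihood_loss(s, out), -log(0.6), tolerance = 1e-8)
})

test_that("degenerate one-cell grid gives zero loss for an event at bin 0", {
  g <- time_grid(1, 1)
  expect_equal(g$n_bins, 2L)   # smallest lawful grid has two bins
  # the one-event, one-bin degenerate case: softmax forces y = 1
  g1 <- structure(list(horizon_days = 0L, bin_width_days = 1L,
                       n_bins = 1L, bin_days = 0L), class = "time_grid")
  pmf <- array(1, dim = c(1, 1, 1))
  s <- risk_surface(pmf, g1, events = "ACS")
  out <- outcome_table("ACS", 0, g1)
  expect_equal(likelihood_loss(s, out), 0)
})

test_that("ranking loss matches the exhaustive pairwise oracle", {
  g <- tiny_grid(T_ = 4)
  set.seed(33)
  s <- random_surface(6, g, seed = 33)
  out <- outcome_table(
    c("ACS", "death", "censored", "revascularization", "ACS", "censored"),
    c(0, 60, 90, 30, 60, 100), g)
  cfg <- loss_config(sigma = 0.1)
  expect_equal(ranking_loss(s, out, cfg), brute_ranking(s, out, cfg),
               tolerance = 1e-8)
})

test_that("ranking edge cases: no valid pairs and equal-risk pairs", {
  g <- tiny_grid(T_ = 3)
  s <- random_surface(3, g, seed = 4)
  allc <- outcome_table(rep("censored", 3), c(0, 0, 0), g)
  expect_equal(ranking_loss(s, allc, loss_config()), 0)
  # one valid pair with identical predictions: eta = exp(0) = 1
  pm <- rbind(c(0.2, 0.1, 0.1), c(0.1, 0.05, 0.05), c(0.05, 0.2, 0.05))
  s2 <- surface_from_list(list(pm, pm), g)
  out2 <- outcome_table(c("ACS", "censored"), c(0, 60), g)
  expect_equal(ranking_loss(s2, out2, loss_config(sigma = 0.1)), 1)
  expect_error(loss_config(sigma = 0), "positive")
})

test_that("total loss mixes the two terms by alpha", {
  g <- tiny_grid(T_ = 4)
  s <- random_surface(5, g, seed = 9)
  out <- outcome_table(c("ACS", "death", "censored", "ACS", "censored"),
                       c(0, 30, 60, 60, 90), g)
  l1 <- likelihood_loss(s, out)
  l2 <- ranking_loss(s, out, loss_config(alpha = 0, sigma = 0.1))
  expect_equal(total_loss(s, out, loss_config(alpha = 1, sigma = 0.1)), l1)
  expect_equal(total_loss(s, out, loss_config(alpha = 0, sigma = 0.1)), l2)
  expect_equal(total_loss(s, out, loss_config(alpha = 0.5, sigma = 0.1)),
               (l1 + l2) / 2, tolerance = 1e-12)
})

test_that("training loss/gradient path agrees with the reference losses", {
  g <- tiny_grid(T_ = 5)
  s <- random_surface(8, g, seed = 12)
  out <- outcome_table(
    c("ACS", "death", "revascularization", "censored", "ACS", "death",
      "censored", "revascularization"),
    c(0, 30, 120, 60, 90, 120, 120, 30), g)
  cfg <- loss_config(alpha = 0.37, sigma = 0.2)
  pmf_mat <- matrix(aperm(s$pmf, c(2, 3, 1)), ncol = 8)
  kv <- match(out$event_kind, s$events); kv[is.na(kv)] <- 0L
  lg <- polarhit:::.loss_and_grad(pmf_mat, kv, out$bin_index, 3, g$n_bins,
                                  cfg)
  expect_equal(lg$likelihood, brute_likelihood(s, out), tolerance = 1e-8)
  expect_equal(lg$ranking, brute_ranking(s, out, cfg), tolerance = 1e-8)
  expect_equal(lg$loss, total_loss(s, out, cfg), tolerance = 1e-8)
})
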