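test_that("average risk is the mean CIF over bins", {
  g <- tiny_grid(T_ = 3)
  pm <- rbind(c(0.1, 0.1, 0.1), c(0, 0, 0), c(0, 0, 0))
  s <- surface_from_list(list(pm), g)
  expect_equal(average_risk(s, "ACS"), mean(c(0.1, 0.2, 0.3)))
  expect_equal(average_risk(s, "death"), 0)
  expect_error(average_risk(s, "stroke"), "unknown")
})

test_that("exact Shapley values satisfy the closed form for linear models", {
  set.seed(2)
  beta <- c(2, -1, 0.5, 0, 3)
  f <- function(X) as.vector(X %*% beta)
  bg <- matrix(rnorm(40 * 5), 40, 5)
  x <- c(1, -2, 0.3, 5, -1)
  r <- shapley_values(f, x, bg, exact_max = 12)
  closed <- beta * (x - colMeans(bg))
  expect_equal(r$phi, closed, tolerance = 1e-10)
  expect_equal(sum(r$phi), r$final - r$expected, tolerance = 1e-10)
  expect_equal(r$final, f(matrix(x, 1)), tolerance = 1e-10)
})

test_that("Shapley axioms: efficiency, symmetry, dummy (exact estimator)", {
  # symmetric model in players 1 and 2; player 4 is ignored entirely
  f <- function(X) X[, 1] * X[, 3] + X[, 2] * X[, 3] + sin(X[, 3])
  bg <- matrix(rnorm(30 * 4), 30, 4)
  bg[, 2] <- bg[, 1]            # symmetric positions need equal backgrounds
  x <- c(1.5, 1.5, -0.7, 99)
  r <- shapley_values(f, x, bg, exact_max = 12)
  expect_equal(sum(r$phi), r$final - r$expected, tolerance = 1e-10)
  expect_equal(r$phi[1], r$phi[2], tolerance = 1e-10)   # symmetry
  expect_equal(r$phi[4], 0, tolerance = 1e-10)          # dummy
})

test_that("patient identical to a single background point gets zero", {
  f <- function(X) as.vector(X %*% c(1, 2, 3))
  x <- c(0.4, -0.2, 1)
  bg <- matrix(x, 1, 3)
  r <- shapley_values(f, x, bg, exact_max = 12)
  expect_equal(r$phi, rep(0, 3), tolerance = 1e-12)
  expect_error(shapley_values(f, x, bg[0, , drop = FALSE]), "empty")
})

test_that("Monte-Carlo estimate agrees with enumeration on 6 players", {
  set.seed(10)
  W <- matrix(rnorm(36), 6, 6)
  f <- function(X) rowSums(tanh(X %*% W))
  bg <- matrix(rnorm(25 * 6), 25, 6)
  x <- rnorm(6)
  exact <- shapley_values(f, x, bg, exact_max = 12)
  mc <- shapley_values(f, x, bg, exact_max = 0, n_perm = 400, seed = 3)
  for (j in 1:6)
    expect_lt(abs(mc$phi[j] - exact$phi[j]), 3 * max(mc$se[j], 1e-6))
  # MC efficiency holds exactly by telescoping
  expect_equal(sum(mc$phi), mc$final - mc$expected, tolerance = 1e-10)
})

test_that("model-based attributions are seeded and sum correctly", {
  coh <- small_cohort(n = 25, seed = 41)
  m <- deephit_fit(coh$maps, coh$clinical, coh$outcomes, tiny_arch(),
                   time_grid(),
                   train_config(batch_size = 16, max_epochs = 1,
                                patience = 1),
                   loss_config())
  bg <- list(maps = coh$maps[1:8, , , , drop = FALSE],
             clinical = coh$clinical[1:8, , drop = FALSE])
  a1 <- shapley_attributions(m, coh$maps[9, , , , drop = FALSE],
                             coh$clinical[9, , drop = FALSE], bg, "death",
                             n_perm = 8, seed = 5)
  a2 <- shapley_attributions(m, coh$maps[9, , , , drop = FALSE],
                             coh$clinical[9, , drop = FALSE], bg, "death",
                             n_perm = 8, seed = 5)
  expect_identical(a1$contribution, a2$contribution)
  expect_equal(sum(a1$contribution),
               attr(a1, "final_value") - attr(a1, "expected_value"),
               tolerance = 1e-10)
  expect_equal(nrow(a1), 20L)   # 15 clinical + 5 map channels
  expect_true(all(c("map_perfusion", "resting_hr") %in% a1$feature))
})

test_that("waterfall rows are ordered, truncated and telescoping", {
  phi <- c(a = 0.05, b = -0.3, c = 0.02, d = 0.1, e = -0.01)
  attr_ <- structure(
    data.frame(feature = names(phi), contribution = unname(phi),
               se = 0),
    expected_value = 0.2, final_value = 0.2 + sum(phi), event = "death",
    class = c("attribution", "data.frame"))
  wf <- waterfall_data(attr_, top_n = 3)
  expect_equal(wf$feature[1:3], c("b", "d", "a"))
  expect_equal(wf$feature[4], "all others")
  expect_equal(wf$contribution[4], 0.02 - 0.01)
  expect_equal(wf$running_total[1], 0.2 - 0.3)
  expect_equal(wf$running_total[nrow(wf)], attr(attr_, "final_value"))
  expect_equal(wf$direction[1], "risk-decreasing")
  expect_error(waterfall_data(attr_, top_n = 0), "at least 1")
  # all-zero attributions: expected equals final, rows all zero
  attr0 <- structure(
    data.frame(feature = "a", contribution = 0, se = 0),
    expected_value = 0.4, final_value = 0.4,
    class = c("attribution", "data.frame"))
  wf0 <- waterfall_data(attr0, top_n = 2)
  expect_equal(wf0$running_total, 0.4)
})

test_that("counterfactuals are identity-stable and order-free", {
  coh <- small_cohort(n = 20, seed = 47)
  m <- deephit_fit(coh$maps, coh$clinical, coh$outcomes, tiny_arch(),
                   time_grid(),
                   train_config(batch_size = 16, max_epochs = 1,
                                patience = 1),
                   loss_config())
  pm <- coh$maps[3, , , , drop = FALSE]
  pc <- coh$clinical[3, , drop = FALSE]
  r0 <- counterfactual_delta(m, pm, pc, list(), "death")
  expect_equal(r0$delta_percent, 0)
  r_joint <- counterfactual_delta(m, pm, pc,
                                  list(resting_hr = 70, diabetes = 0),
                                  "death")
  pc2 <- pc; pc2$resting_hr <- 70
  r_seq <- counterfactual_delta(m, pm, pc2, list(diabetes = 0), "death")
  expect_equal(r_joint$risk_after, r_seq$risk_after, tolerance = 1e-12)
  expect_error(counterfactual_delta(m, pm, pc, list(shoe_size = 44),
                                    "death"), "unknown feature")
  expect_equal(nrow(r_joint$curves), 3 * 131)
})

test_that("lowering all cause-specific hazards lowers every true risk", {
  # counterfactual sanity on the analytic truth: reducing a covariate with
  # positive coefficients for every cause reduces each CIF, and the percent
  # change recomputed from the hazard formulas matches exactly
  cfg <- synthetic_config(n_patients = 1, seed = 1)
  g <- time_grid()
  clin <- generate_clinical(cfg)
  clin$diabetes <- 1; clin$hypertension <- 1; clin$prior_cabg <- 1
  E <- 0.1
  before <- sample_outcomes(cfg, clin, E, g)$truth
  clin2 <- clin
  clin2$diabetes <- 0; clin2$hypertension <- 0   # beta > 0 for all causes
  clin2$prior_cabg <- 0
  after <- sample_outcomes(cfg, clin2, E, g)$truth
  for (ev in c("ACS", "death", "revascularization")) {
    f0 <- mean(true_cif(before, 1, ev, 0:130))
    f1 <- mean(true_cif(after, 1, ev, 0:130))
    expect_gt(100 * (f0 - f1) / f0, 0)
  }
})

test_that("patient curves average across the ensemble", {
  g <- tiny_grid(T_ = 4)
  s1 <- random_surface(3, g, seed = 1)
  s2 <- random_surface(3, g, seed = 2)
  pc <- patient_curves(list(s1, s2), patient = 2)
  m_rows <- pc[pc$event == "death" & pc$model_id == "mean", ]
  hand <- (cif_matrix(s1, "death")[2, ] + cif_matrix(s2, "death")[2, ]) / 2
  expect_equal(m_rows$cif, hand)
  expect_true(all(tapply(pc$cif, interaction(pc$event, pc$model_id),
                         function(v) all(diff(v) >= -1e-12))))
  one <- patient_curves(list(s1), 1)
  expect_equal(one[one$model_id == "mean", ]$cif,
               one[one$model_id == "1", ]$cif)
})
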