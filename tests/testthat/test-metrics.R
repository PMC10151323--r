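test_that("censoring KM matches a hand-computed table", {
  g <- time_grid()
  # 5 patients: censored at 10, 30; events at 20, 40; censored at 50
  out <- outcome_table(c("censored", "death", "censored", "ACS", "censored"),
                       c(10, 20, 30, 40, 50), g)
  cm <- fit_censoring_km(out)
  # censoring KM: risk sets 5,4,3,2,1; censorings at 10, 30, 50
  expect_equal(cm$G(5), 1)
  expect_equal(cm$G(10), 4 / 5)
  expect_equal(cm$G(20), 4 / 5)            # event does not drop G
  expect_equal(cm$G(30), 4 / 5 * 2 / 3)
  expect_equal(cm$G(49), 4 / 5 * 2 / 3)
  # with no censoring G is identically 1
  out2 <- outcome_table(c("death", "ACS"), c(10, 20), g)
  cm2 <- fit_censoring_km(out2)
  expect_equal(cm2$G(c(0, 10, 25)), c(1, 1, 1))
})

test_that("G is non-increasing on random cohorts", {
  for (seed in 1:3) {
    coh <- small_cohort(n = 120, seed = seed)
    cm <- fit_censoring_km(coh$outcomes)
    tt <- seq(0, 1900, by = 10)
    expect_true(all(diff(cm$G(tt)) <= 1e-12))
  }
})

test_that("cAUC is 1 for a perfect marker and 0 for an inverted one", {
  g <- time_grid()
  out <- outcome_table(c("death", "death", "censored", "censored"),
                       c(30, 60, 400, 500), g)
  risk <- c(10, 9, 1, 2)
  curve <- cumulative_dynamic_auc(risk, out, "death", c(90, 180))
  expect_equal(curve$estimate, c(1, 1))
  curve2 <- cumulative_dynamic_auc(-risk, out, "death", c(90, 180))
  expect_equal(curve2$estimate, c(0, 0))
})

test_that("cAUC equals the exhaustive weighted pair sum on 6 patients", {
  g <- time_grid()
  out <- outcome_table(
    c("death", "censored", "death", "censored", "censored", "death"),
    c(50, 80, 150, 400, 500, 700), g)
  risk <- c(0.9, 0.3, 0.52, 0.52, 0.1, 0.6)
  t_eval <- 200
  cm <- fit_censoring_km(out)
  # direct transcription of the estimator over all ordered pairs
  cases <- which(out$event_kind == "death" & out$time_days <= t_eval)
  controls <- which(out$time_days > t_eval)
  num <- 0; den_w <- 0
  for (i in cases) {
    w <- 1 / cm$G(out$time_days[i])
    den_w <- den_w + w
    for (j in controls)
      num <- num + w * (if (risk[i] > risk[j]) 1
                        else if (risk[i] == risk[j]) 0.5 else 0)
  }
  oracle <- num / (den_w * length(controls))
  curve <- cumulative_dynamic_auc(risk, out, "death", t_eval, cm)
  expect_equal(curve$estimate, oracle, tolerance = 1e-12)
})

test_that("with zero censoring cAUC equals the fixed-time AUC", {
  g <- time_grid()
  set.seed(14)
  for (rep in 1:4) {
    n <- 40
    kinds <- sample(c("death", "ACS"), n, replace = TRUE)
    days <- sample(c(30, 90, 400, 800), n, replace = TRUE)
    out <- outcome_table(kinds, days, g)
    risk <- runif(n)
    t_eval <- 365
    curve <- cumulative_dynamic_auc(risk, out, "MACE", t_eval)
    lab <- label_fixed_time(out, t_eval, "MACE")
    expect_equal(curve$estimate, fixed_time_auc(lab$label, risk),
                 tolerance = 1e-12)
  }
})

test_that("cAUC is invariant to strictly monotone score transforms", {
  coh <- small_cohort(n = 150, seed = 3)
  risk <- coh$extent + 0.01 * seq_len(150) / 150
  a <- cumulative_dynamic_auc(risk, coh$outcomes, "MACE", c(365, 730))
  b <- cumulative_dynamic_auc(exp(3 * risk), coh$outcomes, "MACE",
                              c(365, 730))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
})

test_that("td-concordance reduces to Harrell's C for constant scores", {
  g <- time_grid()
  set.seed(21)
  n <- 8
  days <- sample(30 * (1:20), n)
  out <- outcome_table(rep("death", n), days, g)
  score <- runif(n)
  cifs <- matrix(score, n, g$n_bins)    # time-constant predictions
  ours <- td_concordance(cifs, out, "death")
  ref <- survival::concordance(survival::Surv(days, rep(1, n)) ~ score,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
  # with some censoring as well
  out2 <- outcome_table(sample(c("death", "censored"), n, replace = TRUE),
                        days, g)
  ours2 <- td_concordance(cifs, out2, "death")
  ref2 <- survival::concordance(
    survival::Surv(days, out2$event_kind == "death") ~ score,
    reverse = TRUE)$concordance
  expect_equal(ours2, ref2, tolerance = 1e-12)
})

test_that("identical predictions give concordance one half", {
  g <- time_grid()
  out <- outcome_table(c("death", "death", "censored"), c(30, 90, 400), g)
  cifs <- matrix(0.3, 3, g$n_bins)
  expect_equal(td_concordance(cifs, out, "death"), 0.5)
  out3 <- outcome_table(rep("censored", 3), c(10, 10, 10), g)
  expect_warning(v <- td_concordance(cifs, out3, "death"), "comparable")
  expect_true(is.na(v))
})

test_that("fixed-time AUC equals pair counting and DeLong self-test is null", {
  set.seed(31)
  labels <- c(rep(TRUE, 4), rep(FALSE, 6))
  scores <- c(5, 3, 3, 9, 1, 2, 3, 0, 7, 4)
  # enumeration over all positive x negative pairs
  num <- 0
  for (i in which(labels)) for (j in which(!labels))
    num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(fixed_time_auc(labels, scores), num / (4 * 6))
  expect_equal(fixed_time_auc(labels, as.numeric(labels)), 1)
  d <- delong_compare(scores, scores, labels)
  expect_equal(d$p, 1)
  expect_equal(d$auc_a, d$auc_b)
  expect_error(fixed_time_auc(rep(TRUE, 3), 1:3), "single class")
})

test_that("DeLong p agrees with a resampling oracle on 10 patients", {
  set.seed(8)
  labels <- rep(c(TRUE, FALSE), each = 5)
  sa <- c(3, 6, 1, 6, 9, 6, 0, 1, 2, 2)
  sb <- c(5, 5, 3, 7, 3, 8, 8, 6, 7, 2)
  d <- delong_compare(sa, sb, labels)
  # label-preserving bootstrap of the paired AUC difference
  B <- 20000
  diffs <- numeric(B)
  pos <- which(labels); neg <- which(!labels)
  for (b in seq_len(B)) {
    ip <- sample(pos, length(pos), replace = TRUE)
    ineg <- sample(neg, length(neg), replace = TRUE)
    idx <- c(ip, ineg)
    lab <- labels[idx]
    diffs[b] <- fixed_time_auc(lab, sa[idx]) - fixed_time_auc(lab, sb[idx])
  }
  # normal-approximation p from the bootstrap spread of the difference
  p_boot <- 2 * pnorm(-abs((d$auc_a - d$auc_b) / sd(diffs)))
  expect_lt(abs(d$p - p_boot), 0.02)
})

test_that("metrics are null-calibrated under risk shuffling", {
  coh <- small_cohort(n = 400, seed = 17)
  set.seed(99)
  risk <- sample(seq_len(400)) / 400
  auc <- cumulative_dynamic_auc(risk, coh$outcomes, "MACE", 365)$estimate
  n_case <- sum(coh$outcomes$event_kind != "censored" &
                  coh$outcomes$time_days <= 365)
  n_ctrl <- sum(coh$outcomes$time_days > 365)
  se <- sqrt((n_case + n_ctrl + 1) / (12 * n_case * n_ctrl))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("bootstrap intervals behave on constants and are seeded", {
  r1 <- bootstrap_ci(function(idx) 0.7, n = 50, B = 100, seed = 5)
  expect_equal(r1$mean, 0.7)
  expect_equal(r1$lower, 0.7)
  expect_equal(r1$upper, 0.7)
  f <- function(idx) mean(idx)
  r2 <- bootstrap_ci(f, n = 50, B = 100, seed = 6)
  r3 <- bootstrap_ci(f, n = 50, B = 100, seed = 6)
  expect_identical(r2, r3)
})

test_that("bootstrap interval of a sample mean covers the truth", {
  # mean of N(0,1), n = 1000: the 95% interval should cover 0 in at least
  # 90 of 100 seeded repetitions
  cover <- 0
  for (seed in 1:100) {
    set.seed(seed + 1000)
    x <- rnorm(1000)
    ci <- bootstrap_ci(function(idx) mean(x[idx]), n = 1000, B = 100,
                       seed = seed)
    cover <- cover + (ci$lower <= 0 && 0 <= ci$upper)
  }
  expect_gte(cover, 90)
})
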