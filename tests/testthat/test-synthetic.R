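test_that("null defects give template + noise and zero extent", {
  cfg <- synthetic_config(n_patients = 3, seed = 2, defect_prob = 0,
                          noise_sd = 0)
  pm <- generate_polar_maps(cfg, prior_pci = rep(0, 3))
  expect_equal(pm$extent, rep(0, 3))
  tpl <- polar_template(cfg)
  for (i in 1:3) expect_equal(pm$maps[i, , , ], unname(tpl[, , ]),
                              ignore_attr = TRUE)
})

test_that("map generation is deterministic given the seed", {
  cfg <- synthetic_config(n_patients = 4, seed = 31)
  a <- generate_polar_maps(cfg, prior_pci = rep(0, 4))
  b <- generate_polar_maps(cfg, prior_pci = rep(0, 4))
  expect_identical(a$maps, b$maps)
  expect_identical(a$extent, b$extent)
})

test_that("defect extent counts pixels below the template threshold", {
  # a hand-constructed defect: full-amplitude pixels in a known block
  cfg <- synthetic_config(n_patients = 1, seed = 1, noise_sd = 0)
  tpl <- polar_template(cfg)
  # extent is defined on the noiseless perfusion field via deficit_extent
  map <- tpl[1, , ]
  map[1:14, 1:18] <- 0            # exactly a quarter of 28 x 36
  expect_equal(deficit_extent(map, tpl[1, , ], 0.7), 25)
})

test_that("analytic truth satisfies conservation and monotonicity", {
  g <- time_grid()
  coh <- small_cohort(n = 50, seed = 21)
  tr <- coh$truth
  total <- tr$cif[[1]][, g$n_bins] + tr$cif[[2]][, g$n_bins] +
    tr$cif[[3]][, g$n_bins] + tr$surv[, g$n_bins]
  expect_equal(total, rep(1, 50), tolerance = 1e-12)
  for (k in 1:3) expect_true(all(apply(tr$cif[[k]], 1, diff) >= 0))
  expect_true(all(tr$surv >= 0 & tr$surv <= 1))
})

test_that("true_cif matches exhaustive path enumeration on a tiny grid", {
  # 3 bins, two causes with printed hazards; enumerate all event paths
  h1 <- matrix(c(0.10, 0.05, 0.20), 1)
  h2 <- matrix(c(0.02, 0.08, 0.01), 1)
  g3 <- tiny_grid(T_ = 3)
  tr <- synthetic_truth(list(ACS = h1, death = h2,
                             revascularization = matrix(0, 1, 3)),
                        extent = 0, grid = g3)
  # brute force: P(cause k at bin t) = h_k(t) prod_{u<t}(1 - h1(u) - h2(u))
  surv <- cumprod(1 - (h1[1, ] + h2[1, ]))
  lag <- c(1, surv[1:2])
  expect_equal(true_cif(tr, 1, "ACS", 0:2), cumsum(h1[1, ] * lag))
  expect_equal(true_cif(tr, 1, "death", 0:2), cumsum(h2[1, ] * lag))
  expect_equal(true_cif(tr, 1, "revascularization", 2), 0)
  expect_error(true_cif(tr, 1, "stroke", 1), "unknown")
  # first-bin identity and null-hazard limit
  expect_equal(true_cif(tr, 1, "ACS", 0), h1[1, 1])
})

test_that("larger defect extent strictly increases the true CIF", {
  cfg <- synthetic_config(n_patients = 2, seed = 1)
  g <- time_grid()
  clin <- generate_clinical(cfg)
  clin[2, ] <- clin[1, ]                   # identical covariates
  so <- sample_outcomes(cfg, clin, extent = c(0.02, 0.2), grid = g)
  for (ev in c("ACS", "death", "revascularization"))
    expect_true(all(true_cif(so$truth, 2, ev, 0:130) >
                      true_cif(so$truth, 1, ev, 0:130)))
})

test_that("single-cause constant hazard matches the geometric law", {
  # empirical CIF at bin t within 3 Monte-Carlo SE of 1 - (1-h)^(t+1)
  n <- 20000; h <- 0.01
  g <- tiny_grid(T_ = 25)
  cfg <- synthetic_config(n_patients = n, seed = 77,
                          beta = matrix(0, 15, 3),
                          gamma = c(ACS = 0, death = 0,
                                    revascularization = 0),
                          b0 = c(ACS = -Inf, death = log(h / (1 - h)),
                                 revascularization = -Inf),
                          b0_slope = c(ACS = 0, death = 0,
                                       revascularization = 0),
                          admin_censor_days = 1e6, dropout_hazard = 0)
  clin <- generate_clinical(cfg)
  so <- sample_outcomes(cfg, clin, extent = rep(0, n), grid = g)
  for (tb in c(4, 12, 24)) {
    p_true <- 1 - (1 - h)^(tb + 1)
    emp <- mean(so$outcomes$event_kind == "death" &
                  so$outcomes$bin_index <= tb)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(emp - p_true), 3 * se)
  }
})

test_that("two identical causes split events 50/50", {
  n <- 20000
  g <- tiny_grid(T_ = 20)
  cfg <- synthetic_config(n_patients = n, seed = 78,
                          beta = matrix(0, 15, 3),
                          gamma = c(ACS = 0, death = 0,
                                    revascularization = 0),
                          b0 = c(ACS = -5, death = -5,
                                 revascularization = -Inf),
                          b0_slope = c(ACS = 0, death = 0,
                                       revascularization = 0),
                          admin_censor_days = 1e6, dropout_hazard = 0)
  clin <- generate_clinical(cfg)
  so <- sample_outcomes(cfg, clin, extent = rep(0, n), grid = g)
  ev <- so$outcomes$event_kind[so$outcomes$event_kind != "censored"]
  share <- mean(ev == "ACS")
  se <- sqrt(0.25 / length(ev))
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("all-zero hazards censor everyone administratively", {
  n <- 200
  g <- time_grid()
  cfg <- synthetic_config(n_patients = n, seed = 5,
                          beta = matrix(0, 15, 3),
                          gamma = c(ACS = 0, death = 0,
                                    revascularization = 0),
                          b0 = c(ACS = -Inf, death = -Inf,
                                 revascularization = -Inf),
                          b0_slope = c(ACS = 0, death = 0,
                                       revascularization = 0),
                          dropout_hazard = 0)
  clin <- generate_clinical(cfg)
  so <- sample_outcomes(cfg, clin, extent = rep(0, n), grid = g)
  expect_true(all(so$outcomes$event_kind == "censored"))
  admin_bin <- discretize_time(cfg$admin_censor_days, g)
  expect_true(all(so$outcomes$bin_index == admin_bin))
})

test_that("hazard configuration exceeding total probability 1 errors", {
  cfg <- synthetic_config(n_patients = 5, seed = 1,
                          b0 = c(ACS = 3, death = 3,
                                 revascularization = 3))
  clin <- generate_clinical(cfg)
  expect_error(sample_outcomes(cfg, clin, extent = rep(0, 5),
                               grid = time_grid()),
               "exceeds 1")
})
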