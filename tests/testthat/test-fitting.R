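test_that("noise-free synthetic data are recovered exactly", {
  obs <- make_dataset(60, seed = 3, noise_sd = 0)
  fit <- fit_aging_model(obs, free = c("B", "N", "F"), multistart = 3)
  expect_equal(fit$params$B, 1.14, tolerance = 1e-6)
  expect_equal(fit$params$N, 214.91, tolerance = 1e-6)
  expect_equal(fit$params$F, 2.85, tolerance = 1e-6)
  expect_lt(fit$objective, 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("pure-diffusion truth drives B and F to the zero boundary", {
  truth <- aging_params(B = 0, F = 0)
  soils <- generate_soils(50, seed = 6)
  obs <- simulate_observations(soils, truth, noise_sd = 0.02, seed = 66)
  fit <- fit_aging_model(obs, multistart = 6, seed = 2)
  expect_lt(fit$params$B, 0.02)
  expect_lt(fit$params$F, 0.02)
})

test_that("multi-start objectives coincide and KKT conditions hold", {
  obs <- make_dataset(120, seed = 5, noise_sd = 0.02)
  fit <- fit_aging_model(obs, multistart = 10, seed = 9)
  o <- fit$multistart_objectives
  expect_true(all(o - min(o) < 1e-6))
  kkt <- check_kkt(fit, obs)
  expect_true(kkt$ok)
})

test_that("the fit is invariant to observation order", {
  obs <- make_dataset(80, seed = 14, noise_sd = 0.02)
  fit1 <- fit_aging_model(obs, multistart = 4, seed = 9)
  set.seed(99)
  fit2 <- fit_aging_model(obs[sample(nrow(obs)), ], multistart = 4,
                          seed = 9)
  expect_equal(unlist(fit1$params), unlist(fit2$params),
               tolerance = 1e-6)
  expect_equal(fit1$objective, fit2$objective, tolerance = 1e-9)
})

test_that("trend anchors constrain the long-horizon extrapolation", {
  truth <- aging_params()
  # short incubation window only: diffusion barely expressed
  soils <- generate_soils(80, seed = 41, time_range = c(1, 360))
  obs <- simulate_observations(soils, truth, noise_sd = 0.02, seed = 42)
  anchor_soils <- soils[1:10, ]
  anchors <- rbind(transform(anchor_soils, time = 3600),
                   transform(anchor_soils, time = 7200))
  anchors$e_add_obs <- suppressWarnings(
    predict_e_add(anchors, truth))$e_add_pred
  fit_anc <- fit_aging_model(obs, anchors = anchors, multistart = 6,
                             seed = 3)
  expect_equal(fit_anc$n_anchors, 20L)
  # anchored fit must track the truth at horizons far beyond the data
  far <- data.frame(ph = 5.5, corg = 3, temperature = 288, time = 7200)
  expect_equal(predict_e_add(far, fit_anc$params)$e_add_pred,
               predict_e_add(far, truth)$e_add_pred, tolerance = 0.05)
  # anchors enter the objective but not the reported R2/RMSE sample size
  expect_equal(fit_anc$n_obs, 80L)
})

test_that("goodness of fit matches hand arithmetic and flags degeneracy", {
  g <- goodness_of_fit(c(0.2, 0.4, 0.6), c(0.3, 0.4, 0.5))
  expect_equal(g$r2, 0.75)
  expect_equal(g$rmse, sqrt(0.02 / 3))
  perf <- goodness_of_fit(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(perf$r2, 1)
  expect_equal(perf$rmse, 0)
  # constant predictor at the mean: SSres = SStot
  obs <- c(0.2, 0.4, 0.9)
  g0 <- goodness_of_fit(obs, rep(mean(obs), 3))
  expect_equal(g0$r2, 0)
  expect_error(goodness_of_fit(0.5, 0.5), "at least 2")
  expect_error(goodness_of_fit(c(0.4, 0.4), c(0.3, 0.5)), "zero variance")
})

test_that("rmse is consistent with the stored residuals", {
  obs <- make_dataset(40, seed = 8, noise_sd = 0.03)
  fit <- fit_aging_model(obs, multistart = 2, seed = 1)
  expect_equal(fit$rmse, sqrt(sum(fit$residuals^2) / fit$n_obs),
               tolerance = 1e-12)
  expect_lte(fit$r2, 1)
})

test_that("freeing pK0 recovers a shifted hydrolysis constant", {
  truth <- aging_params(pK0 = 6.65)
  soils <- generate_soils(150, seed = 51)
  obs <- simulate_observations(soils, truth, noise_sd = 0.01, seed = 52)
  fit <- fit_free_pk(obs, multistart = 6, seed = 4)
  expect_true("pK0" %in% fit$free)
  expect_equal(fit$params$pK0, 6.65, tolerance = 0.05)
})

test_that("unidentifiable and degenerate fitting setups are reported", {
  obs <- make_dataset(30, seed = 61, noise_sd = 0.02)
  expect_warning(
    fit_aging_model(obs, start = aging_params(B = 0),
                    free = c("N", "F", "pK0"), multistart = 2),
    "unidentifiable")
  expect_error(fit_aging_model(obs[1:2, ]), "at least as many")
  bad <- obs
  bad$e_add_obs <- NULL
  expect_error(fit_aging_model(bad), "e_add_obs")
})
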