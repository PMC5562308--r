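test_that("hydroxide fraction follows the two-species partition", {
  expect_equal(hydroxide_fraction(7.7, 7.7), 0.5)
  expect_equal(hydroxide_fraction(4.3, 4.3), 0.5)
  # frozen from direct high-precision evaluation of 1/(10^2.27 + 1)
  expect_equal(hydroxide_fraction(5.43, 7.7), 0.0053416317030123518,
               tolerance = 1e-12)
  expect_lt(hydroxide_fraction(7.7 - 10, 7.7), 1.01e-10)
  ph <- seq(0, 14, by = 0.25)
  f <- hydroxide_fraction(ph)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
})

test_that("precipitation loss Y1 scales with B and the CuOH+ fraction", {
  s0 <- aging_params(B = 0)
  expect_equal(precipitation_fraction(6.5, 100, s0), 0)
  p <- aging_params(B = 1.14, C = 0)
  expect_equal(precipitation_fraction(5.43, 10, p),
               0.0060894601414340803, tolerance = 1e-12)
  # C = 0: kinetic factor is exactly 1, Y1 independent of time
  expect_identical(precipitation_fraction(5.43, 1, p),
                   precipitation_fraction(5.43, 20000, p))
  # t = 0 with C > 0 resolves to the t -> 0+ limit of t^(C/t), which is 0
  pc <- aging_params(C = 2)
  expect_equal(precipitation_fraction(5.43, 0, pc), 0)
})

test_that("occlusion loss Y2 is linear in organic carbon", {
  expect_equal(occlusion_fraction(0, 50), 0)
  p <- aging_params(F = 2.85, G = 0)
  expect_equal(occlusion_fraction(2.58, 50, p), 0.07353, tolerance = 1e-12)
  expect_equal(occlusion_fraction(23.32, 50, p), 0.66462,
               tolerance = 1e-12)
  expect_equal(occlusion_fraction(c(1, 2, 4), 50, p),
               c(1, 2, 4) / 100 * 2.85, tolerance = 1e-14)
})

test_that("diffusion survival matches the quadrature oracle and is stable", {
  expect_identical(scaled_erfc_survival(0), 1)
  # frozen from the quadrature oracle (helper-oracles.R)
  p <- aging_params()
  expect_equal(diffusion_survival(28470, 288.0, p),
               0.34899475039859568, tolerance = 1e-9)
  expect_equal(diffusion_survival(360, 293, p), 0.83216625656830778,
               tolerance = 1e-9)
  # oracle equivalence on a log grid
  x <- 10^seq(-8, 4, length.out = 60)
  s <- scaled_erfc_survival(x)
  expect_equal(s, survival_quadrature(x), tolerance = 1e-9)
  # strictly decreasing, positive, finite far beyond the erfc overflow range
  xl <- 10^seq(-8, 8, length.out = 200)
  sl <- scaled_erfc_survival(xl)
  expect_true(all(is.finite(sl)))
  expect_true(all(sl > 0 & sl <= 1))
  expect_true(all(diff(sl) < 0))
})

test_that("survival term has square-root short-time and power-law
           long-time limits", {
  xs <- 10^seq(-8, -4, length.out = 30)
  loss <- 1 - scaled_erfc_survival(xs)
  lim <- 2 * sqrt(xs / pi)
  expect_true(all(abs(loss - lim) / lim < 0.01))
  xl <- 10^seq(2, 6, length.out = 30)
  s <- scaled_erfc_survival(xl)
  asym <- 1 / sqrt(pi * xl)
  expect_true(all(abs(s - asym) / s < 0.01))
})

test_that("predict_e_add reproduces the long-aged Danish field soil", {
  hygum1 <- data.frame(ph = 5.43, corg = 2.58, temperature = 288.0,
                       time = 78 * 365)
  out <- predict_e_add(hygum1)
  # frozen from oracle arithmetic: S(1.8078) * (1 - Y1 - Y2)
  expect_equal(out$e_add_pred, 0.32120797677966495, tolerance = 1e-9)
  expect_false(out$clamped)
})

test_that("predict_e_add honours the fresh-addition and no-loss limits", {
  soils <- generate_soils(20, seed = 11)
  soils$time <- 0
  out <- predict_e_add(soils)
  expect_true(all(out$e_add_pred == 1))
  expect_true(all(out$y1 == 0 & out$y2 == 0))
  off <- aging_params(B = 0, F = 0, N = 0)
  soils2 <- generate_soils(20, seed = 12)
  expect_true(all(predict_e_add(soils2, off)$e_add_pred == 1))
})

test_that("loss decomposition is internally consistent (product vs sum)", {
  soils <- generate_soils(300, seed = 21)
  out <- suppressWarnings(predict_e_add(soils))
  keep <- !out$clamped & out$time > 0
  y3 <- (1 - out$y1 - out$y2) * (1 - out$diffusion_survival)
  expect_equal(out$e_add_pred[keep],
               (1 - out$y1 - out$y2 - y3)[keep], tolerance = 1e-12)
})

test_that("predicted lability is monotone non-increasing in each driver", {
  p <- aging_params()  # C = G = 0
  base <- data.frame(ph = 5.5, corg = 4, temperature = 288, time = 100)
  for (i in 1:20) {
    set.seed(100 + i)
    b <- data.frame(ph = runif(1, 3, 6.5), corg = runif(1, 0.5, 10),
                    temperature = runif(1, 278, 298),
                    time = 10^runif(1, 0, 4))
    for (var in c("time", "temperature", "ph", "corg")) {
      grid <- b[rep(1, 15), ]
      grid[[var]] <- switch(var,
        time = 10^seq(0, 4.4, length.out = 15),
        temperature = seq(270, 310, length.out = 15),
        ph = seq(3, 7, length.out = 15),
        corg = seq(0.41, 15, length.out = 15))
      e <- suppressWarnings(predict_e_add(grid, p))$e_add_pred
      expect_true(all(diff(e) <= 1e-12),
                  info = paste("monotone in", var))
    }
  }
})

test_that("negative bracket soils are clamped, flagged and warned about", {
  bad <- data.frame(ph = 7.5, corg = 23, temperature = 288, time = 100)
  expect_warning(out <- predict_e_add(bad), "clamped")
  expect_true(out$clamped)
  expect_identical(out$e_add_pred, 0)
  # bounds always hold after clamping
  soils <- generate_soils(500, seed = 31)
  e <- suppressWarnings(predict_e_add(soils))$e_add_pred
  expect_true(all(e >= 0 & e <= 1))
})

test_that("soil table validation rejects out-of-domain inputs", {
  expect_error(predict_e_add(data.frame(ph = 15, corg = 1,
                                        temperature = 288, time = 1)),
               "ph outside")
  expect_error(predict_e_add(data.frame(ph = 5, corg = -1,
                                        temperature = 288, time = 1)),
               "corg")
  expect_error(predict_e_add(data.frame(ph = 5, corg = 1,
                                        temperature = 0, time = 1)),
               "temperature")
  expect_error(predict_e_add(data.frame(ph = 5, corg = 1,
                                        temperature = 288, time = -1)),
               "time")
  expect_error(predict_e_add(data.frame(ph = 5, corg = 1)),
               "missing required column")
})

test_that("parameter constructor enforces sign constraints", {
  expect_error(aging_params(B = -0.1), "non-negative")
  expect_error(aging_params(K = 5), "K")
  expect_error(as_aging_params(list(Q = 1)), "unknown parameter")
  expect_equal(as_aging_params(list(N = 10))$N, 10)
  expect_equal(as_aging_params(list(N = 10))$B, 1.14)
})

test_that("Arrhenius composite converts activation energy correctly", {
  expect_equal(arrhenius_k(36), -36000 / 8.314, tolerance = 1e-15)
  expect_equal(arrhenius_k(0), 0)
  expect_error(arrhenius_k(-1))
})
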