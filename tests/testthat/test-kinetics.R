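test_that("two-point Arrhenius fit matches the closed form", {
  # tau changes by 10x between 318 and 260 K:
  # EA = kB * ln(10) / (1/260 - 1/318)
  d <- tibble::tibble(temperature = c(260, 318), tau = c(1, 0.1))
  fit <- fit_arrhenius(d)
  ea_closed <- hydro_constants$kB * log(10) / (1 / 260 - 1 / 318)
  expect_equal(fit$EA, ea_closed, tolerance = 1e-10)
  expect_equal(ea_closed, 282.9, tolerance = 0.01)
})

test_that("constant tau fits to zero activation energy", {
  d <- tibble::tibble(temperature = c(250, 280, 310), tau = rep(0.7, 3))
  fit <- fit_arrhenius(d)
  expect_equal(fit$EA, 0, tolerance = 1e-12)
  expect_equal(fit$tau0, 0.7, tolerance = 1e-12)
  expect_error(fit_arrhenius(tibble::tibble(temperature = c(300, 300),
                                            tau = c(1, 2))), "singular")
})

test_that("Arrhenius recovery within 5% at 2% noise", {
  set.seed(21)
  Ts <- c(260, 278, 298, 308, 318)
  tau <- 1e-3 * exp(200 / (hydro_constants$kB * Ts)) * exp(0.02 * rnorm(5))
  fit <- fit_arrhenius(tibble::tibble(temperature = Ts, tau = tau))
  expect_equal(fit$EA, 200, tolerance = 0.05)
  expect_equal(fit$tau0, 1e-3, tolerance = 0.05)
})

test_that("noiseless VFT data round-trips through the fit to 1e-6 relative", {
  Ts <- c(260, 278, 298, 308, 318)
  tau <- 2.0e-4 * exp(3.6 * 176 / (Ts - 176))
  fit <- fit_super_arrhenius(tibble::tibble(temperature = Ts, tau = tau),
                             T0 = 176)
  expect_equal(fit$tau0, 2.0e-4, tolerance = 1e-6)
  expect_equal(fit$K, 3.6, tolerance = 1e-6)
})

test_that("degenerate and invalid VFT inputs are handled", {
  Ts <- c(260, 280, 300)
  flat <- fit_super_arrhenius(tibble::tibble(temperature = Ts,
                                             tau = rep(0.4, 3)), T0 = 176)
  expect_equal(flat$K, 0, tolerance = 1e-12)
  expect_equal(flat$tau0, 0.4, tolerance = 1e-12)
  expect_error(fit_super_arrhenius(tibble::tibble(temperature = c(150, 260),
                                                  tau = c(1, 2)), T0 = 176),
               "150")
})

test_that("the three divergence-temperature choices give three parameter sets", {
  Ts <- c(260, 278, 298, 308, 318)
  tau <- 2.0e-4 * exp(3.6 * 176 / (Ts - 176))
  d <- tibble::tibble(temperature = Ts, tau = tau)
  fits <- purrr::map(c(124, 136, 176), ~fit_super_arrhenius(d, T0 = .x))
  ks <- vapply(fits, function(f) f$K, numeric(1))
  expect_equal(length(unique(round(ks, 6))), 3L)
  # shallower divergence temperature -> larger fragility constant needed
  expect_true(all(diff(ks) < 0))
})

test_that("extrapolation to 220 K reproduces the printed relaxation times", {
  cases <- list(list(tau0 = 5.2e-6, K = 12.3, T0 = 124, printed = 39, pm = 19),
                list(tau0 = 1.2e-5, K = 9.4, T0 = 136, printed = 52, pm = 22),
                list(tau0 = 2.0e-4, K = 3.6, T0 = 176, printed = 370, pm = 70))
  direct <- c(41.3, 48.8, 358.8)  # tau0 * exp(K T0 / (220 - T0)) by hand
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    got <- evaluate_tau(vft_params(cs$tau0, cs$K, cs$T0), 220)
    expect_equal(got$tau, direct[i], tolerance = 1e-3)
    expect_lte(abs(got$tau - cs$printed), cs$pm)
  }
})

test_that("evaluate_tau limits and domain errors", {
  p <- vft_params(2.0e-4, 3.6, 176)
  expect_equal(evaluate_tau(p, 1e9)$tau, 2.0e-4, tolerance = 1e-6)
  expect_error(evaluate_tau(p, 170), "exceed T0")
  # monotone decreasing in T for positive K
  taus <- evaluate_tau(p, c(200, 220, 260, 300))$tau
  expect_true(all(diff(taus) < 0))
  a <- arrhenius_params(1e-3, 250)
  taus_a <- evaluate_tau(a, c(200, 250, 300))$tau
  expect_true(all(diff(taus_a) < 0))
})

test_that("uncertainty propagation grows with the extrapolation distance", {
  p <- vft_params(2.0e-4, 3.6, 176, tau0_se = 2.4e-5, K_se = 0.1)
  near <- evaluate_tau(p, 300)
  far <- evaluate_tau(p, 220)
  expect_gt(far$tau_se / far$tau, near$tau_se / near$tau)
  expect_gt(far$tau_se, 0)
})

test_that("crossover bisection agrees with a dense-grid oracle to 0.01 K", {
  arr <- arrhenius_params(1e-5, 300)
  vft <- vft_params(1e-4, 2, 176)
  tx <- crossover_temperature(arr, vft, c(180, 400))
  grid <- seq(180, 400, by = 0.001)
  g <- log(1e-5) + 300 / (hydro_constants$kB * grid) -
    (log(1e-4) + 2 * 176 / (grid - 176))
  expect_equal(tx, grid[which.min(abs(g))], tolerance = 0.011)
  expect_error(crossover_temperature(arr, vft, c(300, 400)), "sign")
})

test_that("VFT converges to Arrhenius as T0 -> 0 with K T0 fixed", {
  # K T0 = 2000 K corresponds to EA = kB * 2000 meV
  Ts <- seq(220, 320, by = 20)
  ea <- hydro_constants$kB * 2000
  arr_tau <- 1e-4 * exp(ea / (hydro_constants$kB * Ts))
  for (T0 in c(1, 0.1, 0.01)) {
    vft_tau <- 1e-4 * exp((2000 / T0) * T0 / (Ts - T0))
    expect_equal(vft_tau, arr_tau, tolerance = 10 * T0 / min(Ts))
  }
})
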