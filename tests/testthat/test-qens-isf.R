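test_that("an elastic scatterer transforms to F(t) = 1 at every retained time", {
  dE <- seq(-100, 100, by = 0.5)
  res <- tibble::tibble(q = 1, dE = dE,
                        S = exp(-dE^2 / 8) / sqrt(8 * pi), err = 0)
  isf <- isf_from_spectrum(res, res, times = seq(0, 50, by = 2))
  expect_equal(isf$F, rep(1, nrow(isf)), tolerance = 1e-12)
})

test_that("a Lorentzian spectrum transforms to exp(-Gamma t / hbar)", {
  hbar <- hydro_constants$hbar
  G <- 10
  dE <- seq(-500, 500, by = 0.5)
  samp <- tibble::tibble(q = 1, dE = dE, S = (G / pi) / (dE^2 + G^2), err = 0)
  # delta-like resolution: all weight in the central bin
  res <- tibble::tibble(q = 1, dE = dE, S = as.numeric(dE == 0), err = 0)
  isf <- isf_from_spectrum(samp, res, times = seq(0, 200, by = 1))
  at <- hbar / G  # 65.82 ps, where the decay reaches 1/e
  expect_lt(abs(approx(isf$t, isf$F, at)$y - exp(-1)), 0.01)
})

test_that("the generator round trip recovers the generating KWW curve", {
  # the energy window must hold the stretched-exponential's slow tails, and
  # times below the truncation kernel width (hbar / window) are excluded
  dE <- seq(-6000, 6000, by = 3)
  gen <- gen_kww_spectra(qs = 1.0, tau1 = 30, power = 0, beta = 0.6,
                         resolution_fwhm = 17.5, noise_frac = 0, dE = dE,
                         seed = 1)
  times <- exp(seq(log(2), log(300), length.out = 50))
  isf <- isf_from_spectrum(gen$sample, gen$resolution, times)
  truth <- exp(-(isf$t / 30)^0.6)
  expect_lt(sqrt(mean((isf$F - truth)^2)), 0.02)
  fit <- fit_kww(isf)
  expect_equal(fit$tau, 30, tolerance = 1e-3)
  expect_equal(fit$beta, 0.6, tolerance = 1e-3)
})

test_that("time points beyond the resolution decay are dropped, not returned", {
  dE <- seq(-100, 100, by = 0.25)
  sigma_e <- 5
  res <- tibble::tibble(q = 1, dE = dE,
                        S = exp(-dE^2 / (2 * sigma_e^2)), err = 0)
  long_t <- seq(0, 2000, by = 50)  # far beyond hbar/sigma_e ~ 132 ps
  isf <- isf_from_spectrum(res, res, long_t)
  expect_gt(nrow(attr(isf, "dropped")), 0)
  expect_true(all(isf$F == 1))
  expect_error(isf_from_spectrum(res, res, times = c(1500, 2000)),
               "resolution limit")
})

test_that("KWW fitting is exact on noiseless stretched exponentials", {
  t <- exp(seq(log(0.1), log(2000), length.out = 50))
  # simple exponential
  f1 <- fit_kww(tibble::tibble(t = t, F = exp(-t / 100)))
  expect_equal(f1$A, 1, tolerance = 1e-6)
  expect_equal(f1$tau, 100, tolerance = 1e-4)
  expect_equal(f1$beta, 1, tolerance = 1e-6)
  # beta = 0.5: mean tau is exactly 2 tau since Gamma(2) = 1
  f2 <- fit_kww(tibble::tibble(t = t, F = 0.95 * exp(-sqrt(t / 50))))
  expect_equal(f2$A, 0.95, tolerance = 1e-4)
  expect_equal(f2$tau, 50, tolerance = 1e-4)
  expect_equal(f2$beta, 0.5, tolerance = 1e-4)
  expect_equal(f2$mean_tau, 100, tolerance = 1e-3)
  # property: recovery across the physical beta range
  for (b in c(0.3, 0.8, 1.0)) {
    fb <- fit_kww(tibble::tibble(t = t, F = exp(-(t / 50)^b)))
    expect_equal(fb$tau, 50, tolerance = 1e-4)
    expect_equal(fb$beta, b, tolerance = 1e-4)
  }
})

test_that("KWW fitting recovers parameters within 5% at 1% noise", {
  set.seed(11)
  t <- exp(seq(log(0.5), log(2000), length.out = 60))
  F <- 0.95 * exp(-(t / 50)^0.6) * (1 + 0.01 * rnorm(length(t)))
  F <- pmin(pmax(F, -0.2), 1.2)
  fit <- fit_kww(tibble::tibble(t = t, F = F))
  expect_equal(fit$A, 0.95, tolerance = 0.05)
  expect_equal(fit$tau, 50, tolerance = 0.05)
  expect_equal(fit$beta, 0.6, tolerance = 0.05)
})

test_that("KWW preconditions are enforced", {
  expect_error(fit_kww(tibble::tibble(t = 1:4, F = exp(-(1:4) / 2))),
               "at least 6")
  expect_error(fit_kww(tibble::tibble(t = 1:10, F = rep(1.5, 10))),
               "outside")
})

test_that("q-power regression is exact on a pure power law", {
  sc <- tibble::tibble(q = c(0.5, 1.0, 1.5), mean_tau = c(0.5, 1.0, 1.5)^-2)
  fit <- fit_q_power(sc)
  expect_equal(fit$exponent, -2, tolerance = 1e-12)
  expect_equal(fit$exponent_magnitude, 2, tolerance = 1e-12)
  expect_error(fit_q_power(tibble::tibble(q = c(1, 2, 3), mean_tau = c(1, -1, 1))),
               "positive")
})

test_that("q-power slope estimator is unbiased under multiplicative noise", {
  qs <- c(0.53, 0.85, 1.05, 1.45, 1.85)
  res <- purrr::map_dfr(1:100, function(s) {
    set.seed(s)
    sc <- tibble::tibble(q = qs,
                         mean_tau = 30 * qs^-2.65 * exp(0.05 * rnorm(5)))
    fit <- fit_q_power(sc)
    tibble::tibble(slope = fit$exponent, se = fit$stderr)
  })
  expect_lt(abs(mean(res$slope) + 2.65), mean(res$se))
})

test_that("F(q, 0) is 1 for every ISF the pipeline produces (invariant)", {
  dE <- seq(-1200, 1200, by = 4)
  gen <- gen_kww_spectra(qs = c(0.8, 1.3), tau1 = 25, power = -2, beta = 0.7,
                         resolution_fwhm = 17.5, noise_frac = 0.01, dE = dE,
                         seed = 5)
  isf <- isf_from_spectrum(gen$sample, gen$resolution, times = c(0, 1, 5, 20))
  f0 <- isf[isf$t == 0, ]
  expect_equal(f0$F, rep(1, nrow(f0)), tolerance = 1e-9)
})
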