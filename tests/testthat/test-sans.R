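test_that("scattering length densities match hand calculations", {
  expect_equal(sld_from_composition(c(H = 2, O = 1), 0.9982), -0.56e-6,
               tolerance = 0.01)
  expect_equal(sld_from_composition(c(D = 2, O = 1), 1.107), 6.36e-6,
               tolerance = 0.01)
  # volume-fraction mixing is linear
  a <- sld_from_composition(c(H = 2, O = 1), 0.9982)
  b <- sld_from_composition(c(D = 2, O = 1), 1.107)
  expect_equal(0.5 * a + 0.5 * b, (a + b) / 2)
  expect_error(sld_from_composition(c(Xx = 1), 1), "unknown element")
})

test_that("match point is exact on a noiseless parabolic series", {
  f <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  d <- tibble::tibble(fraction = f, intensity = (f - 0.66)^2 * 3.7)
  expect_equal(match_point(d)$f_match, 0.66, tolerance = 1e-10)
})

test_that("match point estimator bias is below 0.01 at 3% noise", {
  errs <- vapply(1:200, function(s) {
    d <- gen_contrast_series(f_match = 0.66, fractions = seq(0.2, 1, by = 0.1),
                             noise_frac = 0.03, seed = s)
    match_point(d)$f_match - 0.66
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("degenerate contrast series are rejected", {
  d <- tibble::tibble(fraction = c(0.2, 0.5, 0.8), intensity = rep(2, 3))
  expect_error(match_point(d), "degenerate")
  expect_error(match_point(tibble::tibble(fraction = c(0.2, 0.5),
                                          intensity = c(1, 2))), "at least 3")
})

test_that("form factor normalizes to 1 at q = 0 and equals Debye at v = 1/2", {
  expect_identical(excluded_volume_form_factor(0, 20, 0.6), 1)
  qr <- seq(0, 10, length.out = 200)
  Rg <- 1
  P <- excluded_volume_form_factor(qr, Rg, 0.5)
  x <- qr^2 * Rg^2
  debye <- ifelse(x < 1e-12, 1, 2 * (exp(-x) + x - 1) / x^2)
  expect_equal(P, debye, tolerance = 1e-6)
})

test_that("the high-q slope is the Porod exponent -1/v (property)", {
  qr <- exp(seq(log(20), log(50), length.out = 60))
  for (v in c(1 / 3, 1 / 2, 3 / 5)) {
    P <- excluded_volume_form_factor(qr, 1, v)
    slope <- coef(lm(log(P) ~ log(qr)))[[2L]]
    expect_equal(slope, -1 / v, tolerance = 0.02 / (1 / v))
  }
})

test_that("the form factor is in (0, 1] and non-increasing (property)", {
  q <- seq(0, 30, length.out = 400)
  for (v in c(1 / 3, 0.5, 0.6)) {
    P <- excluded_volume_form_factor(q, 2, v)
    expect_true(all(P > 0 & P <= 1))
    expect_true(all(diff(P) <= 1e-12))
  }
})

test_that("the average-contrast term vanishes exactly at the match point", {
  rho_h <- 0.6e-6; rho_d <- 7e-6
  rho_bar <- (rho_d + rho_h) / 2  # equal volume fractions
  m <- contrast_model(rho_d, rho_h, rho_s = rho_bar,
                      phi_dPEG = 0.007, phi_hPEG = 0.007,
                      phi_H2O = 0.4, phi_D2O = 0.586,
                      n_PEG = 1e-6, v_PEG = 4000, Rg = 20, v = 0.6)
  zi <- zac_intensity(m, c(0.005, 0.02, 0.1))
  expect_equal(zi$average_contrast, rep(0, 3))
  expect_equal(zi$intensity, zi$single_chain)
})

test_that("a single-population model reduces to the total-term form", {
  rho_h <- 0.6e-6; rho_s <- 3e-6
  m <- contrast_model(rho_d = 7e-6, rho_h = rho_h, rho_s = rho_s,
                      phi_dPEG = 0, phi_hPEG = 0.02,
                      phi_H2O = 0.5, phi_D2O = 0.48,
                      n_PEG = 1e-6, v_PEG = 4000, Rg = 15, v = 0.5)
  q <- c(0.01, 0.05, 0.2)
  zi <- zac_intensity(m, q)
  P <- excluded_volume_form_factor(q, 15, 0.5)
  expect_equal(zi$single_chain, rep(0, 3))
  expect_equal(zi$intensity, (rho_h - rho_s)^2 * 1e-6 * 0.02 * 4000 * P)
})

test_that("the intensity formula agrees with the partial-structure-factor
           decomposition (algebraic oracle)", {
  set.seed(8)
  for (i in 1:10) {
    phi_p <- runif(1, 0.01, 0.4)
    xd <- runif(1, 0.1, 0.9)
    phi_s <- 1 - phi_p
    fd2o <- runif(1)
    m <- contrast_model(rho_d = runif(1, 5e-6, 8e-6),
                        rho_h = runif(1, 0, 2e-6),
                        rho_s = runif(1, -0.6e-6, 6.4e-6),
                        phi_dPEG = phi_p * xd, phi_hPEG = phi_p * (1 - xd),
                        phi_H2O = phi_s * (1 - fd2o), phi_D2O = phi_s * fd2o,
                        n_PEG = 10^runif(1, -7, -5), v_PEG = runif(1, 2e3, 6e3),
                        Rg = runif(1, 10, 40), v = runif(1, 0.35, 0.65),
                        P_I = runif(1, 0, 0.3))
    q <- c(0.005, 0.02, 0.08)
    zi <- zac_intensity(m, q)
    # partials implied by the two-term decomposition
    P_S <- excluded_volume_form_factor(q, m$Rg, m$v)
    P_T <- P_S + m$phi_PEG * m$P_I(q)
    nv <- m$n_PEG * m$v_PEG
    xh <- 1 - xd
    S_dd <- nv * (xd * xh * P_S + xd^2 * m$phi_PEG * P_T)
    S_hh <- nv * xh^2 * m$phi_PEG * P_T
    S_hd <- nv * xd * xh * m$phi_PEG * P_T
    dd <- (m$rho_d - m$rho_s); dh <- (m$rho_h - m$rho_s)
    three_term <- dd^2 * S_dd + dh^2 * S_hh + 2 * dd * dh * S_hd
    expect_equal(zi$intensity, three_term, tolerance = 1e-10)
  }
})

test_that("SANS fits recover generating parameters", {
  q <- exp(seq(log(0.004), log(0.3), length.out = 60))
  clean <- gen_sans_curve(q, Rg = 20, v = 0.6, scale = 1, background = 0.01,
                          noise_frac = 0, seed = 2)
  f0 <- fit_sans(clean)
  expect_equal(f0$Rg, 20, tolerance = 1e-6)
  expect_equal(f0$v, 0.6, tolerance = 1e-6)
  expect_equal(f0$scale, 1, tolerance = 1e-6)
  expect_equal(f0$background, 0.01, tolerance = 1e-4)

  noisy <- gen_sans_curve(q, 20, 0.6, 1, 0.01, noise_frac = 0.02, seed = 2)
  f1 <- fit_sans(noisy)
  expect_equal(f1$Rg, 20, tolerance = 0.05)
  expect_equal(f1$v, 0.6, tolerance = 0.05)
  expect_equal(f1$scale, 1, tolerance = 0.05)

  # freezing v at the wrong theory value must cost fit quality
  f_fixed <- fit_sans(noisy, v_fixed = 0.5)
  expect_gt(f_fixed$sse, f1$sse)
  expect_equal(f_fixed$porod_exponent, 2)
})

test_that("segment-statistics radius of gyration follows the scaling law", {
  # doubling n multiplies Rg by 2^v
  for (v in c(0.5, 0.6)) {
    r1 <- rg_from_segments(b = 5, n = 50, v = v)
    r2 <- rg_from_segments(b = 5, n = 100, v = v)
    expect_equal(r2 / r1, 2^v, tolerance = 1e-12)
  }
})
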