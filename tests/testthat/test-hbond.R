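test_that("ideal collinear geometry is one bond; too-far geometry is none", {
  top <- make_water_peg_topology(1, 1)
  # O_d at origin, H on +x, acceptor further along +x (collinear, 180 deg)
  coords <- rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(7.8, 5, 5))
  b <- find_hbonds(coords, rep(20, 3), top)
  expect_equal(nrow(b), 1L)
  expect_equal(b$donor_o, 0L)
  expect_equal(b$acceptor_o, 3L)
  expect_equal(b$distance, 2.8)
  expect_equal(b$angle, 180)
  coords_far <- coords; coords_far[4, 1] <- 5 + 3.6
  expect_equal(nrow(find_hbonds(coords_far, rep(20, 3), top)), 0L)
  # bent geometry below the angle cut
  coords_bent <- coords; coords_bent[4, ] <- c(6.5, 7.5, 5)
  expect_equal(nrow(find_hbonds(coords_bent, rep(20, 3), top)), 0L)
})

test_that("minimum-image convention finds bonds across the boundary", {
  top <- make_water_peg_topology(1, 1)
  coords <- rbind(c(0.5, 5, 5), c(19.8, 5, 5), c(0.5, 6, 5), c(18.2, 5, 5))
  b <- find_hbonds(coords, rep(20, 3), top)
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 2.3, tolerance = 1e-12)
})

test_that("find_hbonds matches the brute-force all-pairs oracle (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n_w <- 14; n_p <- 8; L <- 12
    top <- make_water_peg_topology(n_w, n_p)
    coords <- matrix(runif((3 * n_w + n_p) * 3, 0, L), ncol = 3)
    for (m in seq_len(n_w) - 1L) {
      for (j in 1:2) coords[3 * m + 1 + j, ] <- coords[3 * m + 1, ] + rnorm(3, sd = 0.7)
    }
    for (sel in c("water_peg", "water_water")) {
      got <- find_hbonds(coords, rep(L, 3), top, selection = sel)
      ref <- brute_force_hbonds(coords, rep(L, 3), top, selection = sel)
      got_keys <- sort(paste(got$donor_o, got$h, got$acceptor_o))
      ref_keys <- sort(paste(ref[, 1], ref[, 2], ref[, 3]))
      expect_identical(got_keys, ref_keys)
    }
  }
})

test_that("a static bonded frame yields a single all-ones series", {
  top <- make_water_peg_topology(1, 1)
  coords <- rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(7.8, 5, 5))
  arr <- array(NA_real_, c(10, 4, 3))
  for (f in 1:10) arr[f, , ] <- coords
  traj <- md_trajectory(arr, c(20, 20, 20), 1)
  s <- hbond_timeseries(traj, top)
  expect_equal(dim(s$h), c(1L, 10L))
  expect_true(all(s$h == 1L))
})

test_that("a toggling geometry alternates the bond indicator", {
  top <- make_water_peg_topology(1, 1)
  bonded <- rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(7.8, 5, 5))
  broken <- bonded; broken[2, ] <- c(5, 4, 5)  # H rotated away
  arr <- array(NA_real_, c(6, 4, 3))
  for (f in 1:6) arr[f, , ] <- if (f %% 2 == 1) bonded else broken
  traj <- md_trajectory(arr, c(20, 20, 20), 1)
  s <- hbond_timeseries(traj, top)
  expect_equal(as.integer(s$h[1, ]), c(1L, 0L, 1L, 0L, 1L, 0L))
})

test_that("a bond-free trajectory gives an empty series, not an error", {
  top <- make_water_peg_topology(1, 1)
  coords <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(10, 10, 10))
  arr <- array(NA_real_, c(3, 4, 3)); for (f in 1:3) arr[f, , ] <- coords
  s <- hbond_timeseries(md_trajectory(arr, c(20, 20, 20), 1), top)
  expect_equal(nrow(s$h), 0L)
  expect_error(correlation_functions(s), "zero")
})

test_that("a permanent bond has C = S = 1 at all lags", {
  s <- structure(list(pairs = tibble::tibble(donor_o = 0L, h = 1L,
                                             acceptor_o = 2L),
                      h = matrix(1L, 1, 50), timestep = 2),
                 class = "hbond_series")
  cf <- correlation_functions(s, max_lag = 20)
  expect_equal(cf$C, rep(1, 21))
  expect_equal(cf$S, rep(1, 21))
  expect_equal(cf$t, seq(0, 40, by = 2))
})

test_that("estimators match a brute-force origin-enumeration oracle", {
  cases <- list(c(1L, 1L, 0L, 1L),
                c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L),
                c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L))
  for (hvec in cases) {
    s <- structure(list(pairs = tibble::tibble(donor_o = 0L, h = 1L,
                                               acceptor_o = 2L),
                        h = matrix(hvec, 1), timestep = 1),
                   class = "hbond_series")
    lag_max <- 2L
    cf <- correlation_functions(s, max_lag = lag_max)
    ref <- brute_force_correlators(hvec, lag_max)
    expect_equal(cf$C, ref$C[seq_len(nrow(cf))])
    expect_equal(cf$S, ref$S[seq_len(nrow(cf))])
  }
})

test_that("telegraph series reproduce the two-state closed forms", {
  s <- gen_telegraph(k_on = 0.01, k_off = 0.01, n_frames = 1e5, timestep = 1,
                     n_pairs = 60, seed = 5)
  cf <- correlation_functions(s, max_lag = 400)
  p <- 0.5; k <- 0.02
  expect_lt(sqrt(mean((cf$C - (p + (1 - p) * exp(-k * cf$t)))^2)), 0.02)
  expect_lt(sqrt(mean((cf$S - exp(-0.01 * cf$t))^2)), 0.02)
  expect_equal(relax_time_1e(cf$t, cf$S), 1 / 0.01, tolerance = 0.05)
})

test_that("the intermittent correlator dominates the continuous one (property)", {
  for (seed in c(2, 9)) {
    # p = k_on/(k_on + k_off) = 0.2 < 1/e, so C(t) crosses the threshold
    s <- gen_telegraph(k_on = 0.005, k_off = 0.02, n_frames = 5000,
                       timestep = 1, n_pairs = 25, seed = seed)
    cf <- correlation_functions(s, max_lag = 300)
    expect_true(all(cf$C >= cf$S))
    expect_true(all(diff(cf$S) <= 1e-12))
    tau_r <- relax_time_1e(cf$t, cf$C)
    tau_hb <- relax_time_1e(cf$t, cf$S)
    expect_gte(tau_r, tau_hb)
  }
})

test_that("1/e times interpolate linearly between samples", {
  t <- seq(0, 30, by = 0.5)
  expect_equal(relax_time_1e(t, exp(-t / 5)), 5, tolerance = 1e-3)
  # hand interpolation between (4, 0.40) and (6, 0.30)
  got <- relax_time_1e(c(0, 4, 6), c(1, 0.40, 0.30))
  expect_equal(got, 4 + (0.40 - exp(-1)) / (0.40 - 0.30) * 2, tolerance = 1e-12)
  expect_equal(got, 4.64, tolerance = 0.002)
  expect_error(relax_time_1e(c(0, 5, 10), c(1, 0.6, 0.5)), "never crosses")
})
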