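#' Synthetic resolution-broadened KWW spectra
#'
#' Emulates a quasi-elastic spectrometer measuring a stretched-exponential
#' relaxor whose time scale follows a power law in q,
#' \eqn{\tau(q) = \tau_1 q^{power}} (power negative for sub-diffusion).
#' Each spectrum is the numeric cosine transform of
#' \eqn{\exp[-(t/\tau)^\beta]} multiplied by the Gaussian resolution's
#' time-domain factor (equivalent to energy-domain convolution), sampled on
#' the requested energy grid, with multiplicative Gaussian noise. The
#' matching resolution spectra (analytic Gaussians of the stated FWHM) are
#' returned alongside, and the generating parameters are stored as a truth
#' record.
#'
#' @param qs Momentum transfers, 1/Angstrom.
#' @param tau1 Relaxation time at q = 1 (ps).
#' @param power Power-law exponent of tau(q) (e.g. -2.65).
#' @param beta Stretching exponent in (0, 1].
#' @param resolution_fwhm Gaussian resolution FWHM in micro-eV (> 0).
#' @param noise_frac Multiplicative noise fraction (0 for noiseless).
#' @param dE Energy-transfer grid in micro-eV (symmetric grids recommended).
#' @param seed Integer seed (mandatory; identical arguments give identical
#'   output).
#' @param temperature Temperature label stored with the sample (K).
#' @return List with `sample` and `resolution` spectrum tibbles
#'   (`temperature`, `q`, `dE`, `S`, `err`) and a `truth` list.
#' @export
gen_kww_spectra <- function(qs, tau1, power, beta, resolution_fwhm,
                            noise_frac, dE, seed, temperature = 298) {
  stopifnot(beta > 0, beta <= 1, resolution_fwhm > 0)
  set.seed(seed)
  hbar <- hydro_constants$hbar
  sigma_e <- resolution_fwhm / (2 * sqrt(2 * log(2)))
  sigma_t <- hbar / sigma_e
  taus <- tau1 * qs^power
  res_S <- exp(-dE^2 / (2 * sigma_e^2)) / (sigma_e * sqrt(2 * pi))
  out_s <- list(); out_r <- list()
  for (i in seq_along(qs)) {
    tau <- taus[i]
    t_max <- min(tau * 25^(1 / beta), 6.5 * sigma_t)
    tg <- seq(0, t_max, length.out = 4000L)
    G <- exp(-(tg / tau)^beta) * exp(-(tg / sigma_t)^2 / 2)
    S <- vapply(dE, function(e) trapz(tg, G * cos(e * tg / hbar)) / (pi * hbar),
                numeric(1))
    norm <- trapz(dE, S)
    if (norm < 0.9) {
      abort(sprintf("dE window too narrow for the KWW linewidth at q=%g (integral %.3f < 0.9)",
                    qs[i], norm))
    }
    Sn <- S * (1 + noise_frac * rnorm(length(S)))
    out_s[[i]] <- tibble::tibble(temperature = temperature, q = qs[i], dE = dE,
                                 S = Sn, err = noise_frac * abs(S))
    out_r[[i]] <- tibble::tibble(temperature = 10, q = qs[i], dE = dE,
                                 S = res_S, err = 0)
  }
  list(sample = dplyr::bind_rows(out_s),
       resolution = dplyr::bind_rows(out_r),
       truth = list(qs = qs, tau = taus, tau1 = tau1, power = power,
                    beta = beta, resolution_fwhm = resolution_fwhm,
                    noise_frac = noise_frac, seed = seed))
}

#' Synthetic two-state (telegraph) hydrogen-bond series
#'
#' Stationary two-state Markov chains emulating bonds that break and
#' reform: on/off rates `k_on`, `k_off` (1/ps), started from the
#' equilibrium occupancy `p = k_on / (k_on + k_off)` and stepped with the
#' exact discrete-time transition probabilities of the continuous-time
#' process. Closed forms for the estimators:
#' `C(t) -> p + (1 - p) exp(-(k_on + k_off) t)` and (for
#' `timestep * rates` small) `S(t) -> exp(-k_off t)`.
#'
#' @param k_on,k_off Formation and rupture rates, 1/ps (> 0; the product
#'   `timestep * max(rate)` must stay below 0.1 so the discrete chain
#'   resolves the kinetics).
#' @param n_frames,timestep Series length and frame spacing (ps).
#' @param n_pairs Number of independent bonds.
#' @param seed Integer seed.
#' @return An `hbond_series` (see [hbond_timeseries()]) with a `truth`
#'   attribute.
#' @export
gen_telegraph <- function(k_on, k_off, n_frames, timestep, n_pairs, seed) {
  if (k_on <= 0 || k_off <= 0) abort("rates must be positive")
  if (timestep * max(k_on, k_off) >= 0.1) {
    abort("timestep too coarse: timestep * max(rate) must be < 0.1")
  }
  set.seed(seed)
  k <- k_on + k_off
  p <- k_on / k
  decay <- exp(-k * timestep)
  p01 <- p * (1 - decay)        # off -> on
  p11 <- p + (1 - p) * decay    # on -> on
  h <- matrix(0L, n_pairs, n_frames)
  h[, 1] <- as.integer(runif(n_pairs) < p)
  for (f in 2:n_frames) {
    stay <- ifelse(h[, f - 1L] == 1L, p11, p01)
    h[, f] <- as.integer(runif(n_pairs) < stay)
  }
  structure(list(
    pairs = tibble::tibble(donor_o = seq_len(n_pairs) - 1L,
                           h = rep(NA_integer_, n_pairs),
                           acceptor_o = rep(NA_integer_, n_pairs)),
    h = h, timestep = timestep,
    truth = list(k_on = k_on, k_off = k_off, p = p, seed = seed)),
    class = "hbond_series")
}

#' Synthetic trap-and-jump water trajectory
#'
#' Walkers emulating trapping-site diffusion: each vibrates (isotropic
#' Gaussian libration of width `libration_sigma`) around a site of a simple
#' cubic lattice with spacing `site_spacing`, and after an exponentially
#' distributed residence relocates to one of the six neighbor sites chosen
#' uniformly. Positions are wrapped into the box; all atoms carry the water
#' oxygen role.
#'
#' @param n_walkers Number of walkers.
#' @param site_spacing Lattice constant / jump length, Angstrom.
#' @param mean_residence Mean residence time per site, ps (`Inf` for
#'   permanently trapped walkers).
#' @param libration_sigma In-trap Gaussian width, Angstrom (must be well
#'   below `site_spacing`).
#' @param timestep,n_frames Frame spacing (ps) and count.
#' @param box Length-3 (or scalar) box edges, Angstrom.
#' @param seed Integer seed.
#' @return List with `trajectory` ([md_trajectory]), `topology` (tibble)
#'   and `truth` (including the realized jump count per walker).
#' @export
gen_trap_jump_trajectory <- function(n_walkers, site_spacing, mean_residence,
                                     libration_sigma, timestep, n_frames,
                                     box, seed) {
  if (libration_sigma >= site_spacing / 3) {
    abort("libration_sigma must be small compared to site_spacing")
  }
  set.seed(seed)
  box <- rep(box, length.out = 3L)
  p_jump <- if (is.infinite(mean_residence)) 0 else 1 - exp(-timestep / mean_residence)
  sites <- matrix(runif(3L * n_walkers), n_walkers, 3L) %*% diag(box)
  sites <- round(sites / site_spacing) * site_spacing
  coords <- array(NA_real_, c(n_frames, n_walkers, 3L))
  njump <- integer(n_walkers)
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * site_spacing
  for (f in seq_len(n_frames)) {
    if (f > 1L && p_jump > 0) {
      who <- which(runif(n_walkers) < p_jump)
      if (length(who)) {
        sites[who, ] <- sites[who, , drop = FALSE] +
          steps[sample.int(6L, length(who), replace = TRUE), , drop = FALSE]
        njump[who] <- njump[who] + 1L
      }
    }
    pos <- sites + matrix(rnorm(3L * n_walkers, sd = libration_sigma),
                          n_walkers, 3L)
    coords[f, , ] <- pos %% matrix(box, n_walkers, 3L, byrow = TRUE)
  }
  top <- tibble::tibble(index = seq_len(n_walkers) - 1L,
                        molecule_id = seq_len(n_walkers) - 1L,
                        molecule_type = "WAT", role = "OW")
  list(trajectory = md_trajectory(coords, box, timestep),
       topology = top,
       truth = list(site_spacing = site_spacing,
                    mean_residence = mean_residence,
                    libration_sigma = libration_sigma,
                    n_jumps = njump, seed = seed))
}

#' Synthetic SANS curve from the excluded-volume form factor
#'
#' `I(q) = scale * P(q; Rg, v) + background` with multiplicative Gaussian
#' noise.
#'
#' @param q Momentum transfers, 1/Angstrom.
#' @param Rg,v Form-factor parameters.
#' @param scale,background Intensity scale and flat background.
#' @param noise_frac Multiplicative noise fraction.
#' @param seed Integer seed.
#' @return Tibble (`q`, `intensity`, `err`) with a `truth` attribute.
#' @export
gen_sans_curve <- function(q, Rg, v, scale = 1, background = 0,
                           noise_frac = 0, seed = 1L) {
  set.seed(seed)
  ideal <- scale * excluded_volume_form_factor(q, Rg, v) + background
  noisy <- ideal * (1 + noise_frac * rnorm(length(q)))
  out <- tibble::tibble(q = q, intensity = noisy,
                        err = pmax(noise_frac, 1e-6) * ideal)
  attr(out, "truth") <- list(Rg = Rg, v = v, scale = scale,
                             background = background,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Synthetic contrast-variation series
#'
#' Sweeps the D2O volume fraction of the solvent at fixed chain composition
#' (equal volumes of h- and d-polymer) and records the forward-model
#' intensity at one q. The d-polymer SLD is constructed so that the
#' zero-average-contrast condition falls exactly at `f_match`, which the
#' truth record stores.
#'
#' @param f_match D2O volume fraction of the intended match point.
#' @param fractions D2O volume fractions sampled.
#' @param q_eval Momentum transfer at which intensities are recorded.
#' @param phi_PEG Polymer volume fraction.
#' @param Rg,v Single-chain form-factor parameters.
#' @param noise_frac Multiplicative noise fraction.
#' @param include_single_chain If `TRUE`, adds the single-chain
#'   (zero-average-contrast) component to the recorded intensity; the
#'   default `FALSE` emulates the regime where the average-contrast term
#'   dominates the detector signal, which is what makes `sqrt(I)` linear in
#'   the solvent fraction with an exact root at the match point. With the
#'   single-chain floor included the apparent minimum is offset — a real
#'   systematic of the method.
#' @param seed Integer seed.
#' @return Tibble (`fraction`, `intensity`, `err`) with a `truth`
#'   attribute.
#' @export
gen_contrast_series <- function(f_match = 0.66,
                                fractions = seq(0.1, 1, by = 0.1),
                                q_eval = 0.02, phi_PEG = 0.014,
                                Rg = 20, v = 0.6, noise_frac = 0,
                                include_single_chain = FALSE, seed = 1L) {
  set.seed(seed)
  rho_h2o <- sld_from_composition(c(H = 2, O = 1), 0.9982)
  rho_d2o <- sld_from_composition(c(D = 2, O = 1), 1.107)
  rho_h <- sld_from_composition(c(C = 2, H = 4, O = 1), 1.12)
  rho_target <- f_match * rho_d2o + (1 - f_match) * rho_h2o
  rho_d <- 2 * rho_target - rho_h  # equal-volume mix averages to the target
  phi_s <- 1 - phi_PEG
  inten <- vapply(fractions, function(f) {
    m <- contrast_model(rho_d = rho_d, rho_h = rho_h,
                        rho_s = f * rho_d2o + (1 - f) * rho_h2o,
                        phi_dPEG = phi_PEG / 2, phi_hPEG = phi_PEG / 2,
                        phi_H2O = phi_s * (1 - f), phi_D2O = phi_s * f,
                        n_PEG = 1e-6, v_PEG = 4000, Rg = Rg, v = v)
    zi <- zac_intensity(m, q_eval)
    if (include_single_chain) zi$intensity else zi$average_contrast
  }, numeric(1))
  noisy <- inten * (1 + noise_frac * rnorm(length(inten)))
  out <- tibble::tibble(fraction = fractions, intensity = pmax(noisy, 0),
                        err = pmax(noise_frac, 1e-6) * pmax(inten, max(inten) * 1e-4))
  attr(out, "truth") <- list(f_match = f_match, rho_d = rho_d, rho_h = rho_h,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Synthetic two-phase box for volume-distribution tests
#'
#' Fills a stated sub-volume of the box with water oxygen points so that
#' the union of `water_radius` spheres around them (the water region probed
#' by [water_volume_distribution()]) occupies the requested volume
#' fraction. The slab is built on a regular grid dense enough that the
#' sphere union covers it without holes, with the outer grid planes offset
#' so the dilated region spans exactly the target thickness — making the
#' constructed fraction exact, not approximate. Spheres are filled with
#' uniformly random points inside radii shrunk by `water_radius`.
#'
#' @param water_fraction Target water volume fraction, in (0, 1].
#' @param geometry `"slab"` or `"spheres"`.
#' @param box Length-3 (or scalar) box edges, Angstrom.
#' @param n_water_points Approximate number of water oxygen points (the
#'   slab grid rounds it; it is also capped below by the covering density).
#' @param water_radius Sphere radius used by the probe analysis (default
#'   1.7 Angstrom).
#' @param sphere_radius Radius of each water sphere for
#'   `geometry = "spheres"` (Angstrom).
#' @param seed Integer seed.
#' @return List with `trajectory` (single frame), `topology` and `truth`
#'   (the exact constructed fraction).
#' @export
gen_two_phase_box <- function(water_fraction, geometry = c("slab", "spheres"),
                              box = 40, n_water_points = 2000,
                              water_radius = 1.7, sphere_radius = 8,
                              seed = 1L) {
  geometry <- match.arg(geometry)
  if (water_fraction <= 0 || water_fraction > 1) {
    abort("water_fraction must lie in (0, 1]")
  }
  set.seed(seed)
  box <- rep(box, length.out = 3L)
  if (geometry == "slab") {
    h <- water_fraction * box[3]
    # regular grid dense enough that the union of water_radius spheres
    # covers the slab without holes (cell diagonal below the radius), with
    # the outermost planes offset so the dilated region spans [0, h]:
    # c is the full-coverage depth below a plane, t_b the mean extra depth
    # of the partial-coverage bumps beyond it
    a_max <- 2 * water_radius / sqrt(3) * 0.9
    a_guess <- max((box[1] * box[2] * max(h, a_max) / n_water_points)^(1 / 3), 1e-3)
    a <- min(a_guess, a_max)
    nx <- max(2L, ceiling(box[1] / a)); ny <- max(2L, ceiling(box[2] / a))
    ax <- box[1] / nx; ay <- box[2] / ny
    cz <- sqrt(water_radius^2 - (ax^2 + ay^2) / 4)
    t_b <- (pi / (ax * ay)) *
      (water_radius^2 * (water_radius - cz) - (water_radius^3 - cz^3) / 3)
    xy <- as.matrix(expand.grid(x = (seq_len(nx) - 0.5) * ax,
                                y = (seq_len(ny) - 0.5) * ay))
    if (water_fraction < 1) {
      z_lo <- cz + t_b; z_hi <- h - cz - t_b
      if (z_hi < z_lo) abort("slab thinner than the grid coverage depth")
      nz <- max(2L, ceiling((z_hi - z_lo) / a) + 1L)
      zs <- seq(z_lo, z_hi, length.out = nz)
    } else {
      nz <- max(2L, ceiling(box[3] / a))
      zs <- (seq_len(nz) - 0.5) * box[3] / nz
    }
    pts <- cbind(xy[rep(seq_len(nrow(xy)), times = length(zs)), ],
                 rep(zs, each = nrow(xy)))
    frac <- water_fraction
  } else {
    vol_one <- 4 / 3 * pi * sphere_radius^3
    n_sph <- max(1L, round(water_fraction * prod(box) / vol_one))
    per_dim <- ceiling(n_sph^(1 / 3))
    centers <- as.matrix(expand.grid(
      x = (seq_len(per_dim) - 0.5) * box[1] / per_dim,
      y = (seq_len(per_dim) - 0.5) * box[2] / per_dim,
      z = (seq_len(per_dim) - 0.5) * box[3] / per_dim))[seq_len(n_sph), , drop = FALSE]
    r_in <- sphere_radius - water_radius
    if (r_in <= 0) abort("sphere_radius must exceed water_radius")
    u <- matrix(rnorm(3L * n_water_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * r_in * runif(n_water_points)^(1 / 3)
    pts <- centers[sample.int(n_sph, n_water_points, replace = TRUE), , drop = FALSE] + u
    pts <- pts %% matrix(box, n_water_points, 3, byrow = TRUE)
    frac <- n_sph * vol_one / prod(box)
  }
  np <- nrow(pts)
  coords <- array(NA_real_, c(1L, np, 3L))
  coords[1, , ] <- pts
  top <- tibble::tibble(index = seq_len(np) - 1L,
                        molecule_id = seq_len(np) - 1L,
                        molecule_type = "WAT", role = "OW")
  list(trajectory = md_trajectory(coords, box, NA_real_, times = 0),
       topology = top,
       truth = list(water_fraction = frac, geometry = geometry,
                    water_radius = water_radius, seed = seed))
}

#' Synthetic elastic scan with a dynamical-transition break
#'
#' Debye–Waller-style elastic fractions `exp(-q^2 <u^2>(T) / 3)` averaged
#' over a q set, with a harmonic mean-squared displacement `<u^2>` growing
#' piecewise-linearly in temperature and changing slope at `T_break` (the
#' `<u^2>` construction is synthetic scaffolding, not a claim about any
#' particular instrument). Additive Gaussian noise, then normalization to
#' the lowest temperature.
#'
#' @param temperatures Temperature grid, K (increasing).
#' @param u2_slope_low,u2_slope_high Slopes of `<u^2>` (Angstrom^2/K) below
#'   and above the break (>= 0).
#' @param T_break Break temperature, K (inside the grid).
#' @param q_set q values averaged over, 1/Angstrom.
#' @param noise Additive noise s.d. on the normalized intensity.
#' @param seed Integer seed.
#' @return An `elastic_scan` tibble (`temperature`, `intensity`) with a
#'   `truth` attribute.
#' @export
gen_elastic_scan <- function(temperatures, u2_slope_low, u2_slope_high,
                             T_break, q_set = c(0.5, 1.0, 1.5), noise = 0,
                             seed = 1L) {
  if (u2_slope_low < 0 || u2_slope_high < 0) abort("slopes must be non-negative")
  if (T_break <= min(temperatures) || T_break >= max(temperatures)) {
    abort("T_break must lie inside the temperature grid")
  }
  set.seed(seed)
  u2 <- ifelse(temperatures <= T_break, u2_slope_low * temperatures,
               u2_slope_low * T_break + u2_slope_high * (temperatures - T_break))
  inten <- vapply(u2, function(u) mean(exp(-q_set^2 * u / 3)), numeric(1))
  inten <- inten + noise * rnorm(length(inten))
  ord <- order(temperatures)
  scan <- tibble::tibble(temperature = temperatures[ord],
                         intensity = inten[ord] / inten[ord][1L])
  structure(scan, class = c("elastic_scan", class(scan)),
            truth = list(T_break = T_break, u2_slope_low = u2_slope_low,
                         u2_slope_high = u2_slope_high, q_set = q_set,
                         noise = noise, seed = seed))
}
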