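#' Neutron scattering length density from an isotopic composition
#'
#' Computes \eqn{\rho = \sum_i b_i / V_{mol}} from bound coherent scattering
#' lengths (H, D, C, O; H and D distinguished) and the bulk mass density.
#'
#' @param formula Named numeric vector of atom counts per molecule, e.g.
#'   `c(H = 2, O = 1)` for light water or `c(C = 2, D = 4, O = 1)` for a
#'   perdeuterated ethylene-oxide monomer.
#' @param density Mass density in g/cm^3 (> 0).
#' @return The scattering length density in 1/Angstrom^2 (typically of
#'   order 1e-6).
#' @examples
#' sld_from_composition(c(H = 2, O = 1), 0.9982)   # light water, ~ -0.56e-6
#' sld_from_composition(c(D = 2, O = 1), 1.107)    # heavy water, ~  6.36e-6
#' @export
sld_from_composition <- function(formula, density) {
  if (density <= 0) abort("density must be positive")
  unknown <- setdiff(names(formula), names(hydro_constants$coherent_b))
  if (length(unknown)) abort(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")))
  b_sum <- sum(formula * hydro_constants$coherent_b[names(formula)]) * 1e-5  # fm -> Angstrom
  mass <- sum(formula * hydro_constants$atomic_mass[names(formula)])        # g/mol
  vol <- mass / (density * 0.602214076)                                     # Angstrom^3/molecule
  b_sum / vol
}

#' Determine the contrast match point from a solvent-composition series
#'
#' At the zero-average-contrast (ZAC) composition the mean polymer contrast
#' vanishes and the scattered intensity passes through a minimum; because
#' the intensity is quadratic in the contrast, the square root of the
#' intensity is linear in the D2O fraction up to a sign. The fit therefore
#' unfolds the sign: every split of the (fraction-ordered) series into a
#' leading negative-sign and trailing positive-sign block is tried, a
#' weighted line is fitted to the signed `sqrt(I)`, and the split with the
#' smallest residual sum of squares wins. The match point is the root of
#' that line.
#'
#' @param data Tibble with columns `fraction` (D2O volume fraction,
#'   increasing), `intensity` (>= 0) and optionally `err` (1-sigma on the
#'   intensity); at least 3 rows spanning the minimum.
#' @return Object of class `match_point_fit` with `f_match`, `slope`,
#'   `intercept`, `sse` and the chosen sign vector. Has [tidy()]/[glance()]
#'   methods.
#' @export
match_point <- function(data) {
  stopifnot(all(c("fraction", "intensity") %in% names(data)))
  df <- data[order(data$fraction), ]
  n <- nrow(df)
  if (n < 3L) abort("need at least 3 solvent fractions")
  if (any(df$intensity < 0)) abort("intensities must be non-negative")
  root_i <- sqrt(df$intensity)
  w <- if ("err" %in% names(df) && !all(is.na(df$err))) {
    # err on sqrt(I) = err_I / (2 sqrt(I)); guard the minimum point
    se <- df$err / (2 * pmax(root_i, 1e-12))
    1 / se^2
  } else rep(1, n)
  best <- NULL
  for (k in 0:n) {
    s <- c(rep(-1, k), rep(1, n - k))
    fit <- lm(s * root_i ~ df$fraction, weights = w)
    sse <- sum(w * fit$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, fit = fit, signs = s)
    }
  }
  slope <- coef(best$fit)[[2L]]
  if (!is.finite(slope) || abs(slope) < 1e-12 * max(abs(root_i), 1)) {
    abort("degenerate fit: no sign assignment gives a decreasing-then-increasing sqrt(I)")
  }
  structure(list(f_match = -coef(best$fit)[[1L]] / slope,
                 slope = slope, intercept = coef(best$fit)[[1L]],
                 sse = best$sse, signs = best$signs, fit = best$fit,
                 data = df),
            class = "match_point_fit")
}

#' @export
print.match_point_fit <- function(x, ...) {
  cat(sprintf("<match_point_fit> f_match = %.4f (D2O volume fraction)\n", x$f_match))
  invisible(x)
}

#' Excluded-volume polymer chain form factor
#'
#' Form factor of a chain with excluded-volume statistics,
#' \deqn{P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma(1/2\nu, U)
#'            - \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U),}
#' with \eqn{U = q^2 R_g^2 (2\nu+1)(2\nu+2)/6} and \eqn{\gamma} the lower
#' incomplete gamma function (evaluated as the regularized
#' `pgamma * gamma`). The excluded-volume parameter \eqn{\nu} is 1/3 for a
#' collapsed chain, 1/2 for an ideal Gaussian coil (where P reduces to the
#' Debye function), and 3/5 for a fully swollen chain; the high-q Porod
#' exponent is \eqn{m = 1/\nu}. The printed formula is 0/0 at U = 0, so for
#' U below 1e-4 the Taylor expansion `1 - q^2 Rg^2 / 3` (i.e.
#' `1 - 2U/((2v+1)(2v+2))`) is used, making `P(0) = 1` exact.
#'
#' @param q Momentum transfer, 1/Angstrom (>= 0); vectorized.
#' @param Rg Radius of gyration, Angstrom (> 0).
#' @param v Excluded-volume parameter, in (0.2, 1).
#' @return `P(q)`, dimensionless, in (0, 1].
#' @export
excluded_volume_form_factor <- function(q, Rg, v) {
  if (Rg <= 0) abort("Rg must be positive")
  if (v <= 0.2 || v >= 1) abort("v must lie in (0.2, 1)")
  if (any(q < 0)) abort("q must be non-negative")
  U <- q^2 * Rg^2 * (2 * v + 1) * (2 * v + 2) / 6
  P <- numeric(length(U))
  small <- U < 1e-4
  P[small] <- 1 - 2 * U[small] / ((2 * v + 1) * (2 * v + 2))
  if (any(!small)) {
    Ub <- U[!small]
    a1 <- 1 / (2 * v); a2 <- 1 / v
    g1 <- gamma(a1) * pgamma(Ub, a1)
    g2 <- gamma(a2) * pgamma(Ub, a2)
    P[!small] <- g1 / (v * Ub^a1) - g2 / (v * Ub^a2)
  }
  P
}

#' Contrast-variation model for an h/d polymer pair in an H2O/D2O solvent
#'
#' Bundles the scattering length densities, volume fractions, chain number
#' density and volume, and the single-chain form factor needed by the
#' zero-average-contrast forward model. Invariants enforced:
#' `phi_PEG = phi_dPEG + phi_hPEG`, `phi_S = phi_H2O + phi_D2O`, and
#' `phi_PEG + phi_S = 1`.
#'
#' @param rho_d,rho_h SLDs of the deuterated and hydrogenous polymer
#'   (1/Angstrom^2).
#' @param rho_s Solvent SLD (1/Angstrom^2); for an H2O/D2O mixture it is
#'   volume-fraction linear in the two pure-solvent SLDs.
#' @param phi_dPEG,phi_hPEG,phi_H2O,phi_D2O Volume fractions in `[0, 1]`
#'   summing to 1.
#' @param n_PEG Chain number density (1/Angstrom^3).
#' @param v_PEG Chain volume (Angstrom^3).
#' @param Rg,v Single-chain form-factor parameters
#'   ([excluded_volume_form_factor()]).
#' @param P_I Inter-chain form-factor component: a function of q (or a
#'   constant), entering the total form factor as
#'   `P_T = P_S + phi_PEG * P_I`; defaults to 0 (dilute limit).
#' @return An object of class `contrast_model`.
#' @export
contrast_model <- function(rho_d, rho_h, rho_s, phi_dPEG, phi_hPEG,
                           phi_H2O, phi_D2O, n_PEG, v_PEG, Rg, v,
                           P_I = NULL) {
  phis <- c(phi_dPEG, phi_hPEG, phi_H2O, phi_D2O)
  if (any(phis < 0 | phis > 1)) abort("volume fractions must lie in [0, 1]")
  if (abs(sum(phis) - 1) > 1e-9) abort("volume fractions must sum to 1")
  phi_PEG <- phi_dPEG + phi_hPEG
  if (phi_PEG <= 0) abort("polymer volume fraction must be positive")
  if (is.null(P_I)) P_I <- function(q) rep(0, length(q))
  if (is.numeric(P_I)) { p0 <- P_I; P_I <- function(q) rep(p0, length(q)) }
  structure(list(rho_d = rho_d, rho_h = rho_h, rho_s = rho_s,
                 phi_dPEG = phi_dPEG, phi_hPEG = phi_hPEG,
                 phi_H2O = phi_H2O, phi_D2O = phi_D2O,
                 phi_PEG = phi_PEG, phi_S = phi_H2O + phi_D2O,
                 n_PEG = n_PEG, v_PEG = v_PEG, Rg = Rg, v = v, P_I = P_I),
            class = "contrast_model")
}

#' Zero-average-contrast scattered intensity
#'
#' Forward model for the contrast-variation intensity of a mixed
#' h-polymer/d-polymer solution:
#' \deqn{\frac{d\Sigma}{d\Omega}(q) =
#'   (\rho_d-\rho_s)^2 \frac{\phi_d\phi_h}{\phi_{P}^2} n v P_S(q)
#'   + \left(\frac{\rho_d\phi_d + \rho_h\phi_h}{\phi_{P}} - \rho_s\right)^2
#'     n \phi_{P} v P_T(q),}
#' with \eqn{P_T = P_S + \phi_P P_I}. When the solvent SLD equals the
#' composition-weighted polymer SLD the second (average-contrast) term
#' vanishes exactly and only single-chain scattering survives — the
#' zero-average-contrast condition that lets the single-chain form factor
#' be measured without dilution.
#'
#' @param model A [contrast_model].
#' @param q Momentum transfer values, 1/Angstrom.
#' @return Tibble with columns `q`, `intensity`, and the two components
#'   `single_chain` and `average_contrast`.
#' @export
zac_intensity <- function(model, q) {
  m <- model
  P_S <- excluded_volume_form_factor(q, m$Rg, m$v)
  P_T <- P_S + m$phi_PEG * m$P_I(q)
  rho_bar <- (m$rho_d * m$phi_dPEG + m$rho_h * m$phi_hPEG) / m$phi_PEG
  term1 <- (m$rho_d - m$rho_s)^2 * (m$phi_dPEG * m$phi_hPEG / m$phi_PEG^2) *
    m$n_PEG * m$v_PEG * P_S
  term2 <- (rho_bar - m$rho_s)^2 * m$n_PEG * m$phi_PEG * m$v_PEG * P_T
  tibble::tibble(q = q, intensity = term1 + term2,
                 single_chain = term1, average_contrast = term2)
}

#' Fit the excluded-volume form factor to a SANS curve
#'
#' Weighted nonlinear least squares of
#' `scale * P(q; Rg, v) + background` to a reduced 1-D SANS curve, by
#' Levenberg–Marquardt with multi-start over the excluded-volume parameter
#' (initial v of 0.4, 0.5 and 0.6) and a Guinier-based starting Rg. `v` can
#' be frozen at a theoretical value (1/2 ideal coil, 3/5 swollen chain).
#' Instrument resolution smearing is not modelled and enters as a
#' systematic.
#'
#' @param data Tibble with columns `q`, `intensity` and `err` (> 0); the q
#'   range should cover `q Rg ~ 1`.
#' @param v_fixed Optional fixed excluded-volume parameter; default free.
#' @return Object of class `sans_fit` with `Rg`, `v`, `scale`,
#'   `background`, standard errors, `porod_exponent = 1/v`, `sse` and the
#'   underlying `nls` object. Has [tidy()]/[glance()] methods.
#' @export
fit_sans <- function(data, v_fixed = NULL) {
  stopifnot(all(c("q", "intensity") %in% names(data)))
  df <- tibble::tibble(q = data$q, intensity = data$intensity,
                       err = if ("err" %in% names(data)) data$err else rep(1, nrow(data)))
  if (any(df$err <= 0)) abort("err must be positive for weighted fitting")
  w <- 1 / df$err^2
  bkg0 <- max(min(df$intensity), 0)
  i0 <- max(df$intensity) - bkg0
  # Guinier start: log(I - bkg) ~ -q^2 Rg^2 / 3 on the low-q third
  lowq <- df[df$q <= stats::quantile(df$q, 1 / 3), ]
  rg0 <- tryCatch({
    gl <- lm(log(pmax(lowq$intensity - bkg0, i0 * 1e-6)) ~ I(lowq$q^2))
    sqrt(max(-3 * coef(gl)[[2L]], 1e-4))
  }, error = function(e) 1 / stats::median(df$q))
  starts <- if (is.null(v_fixed)) c(0.4, 0.5, 0.6) else v_fixed
  fits <- purrr::map(starts, function(v0) {
    tryCatch({
      if (is.null(v_fixed)) {
        minpack.lm::nlsLM(
          intensity ~ scale * excluded_volume_form_factor(q, Rg, v) + bkg,
          data = df,
          start = list(scale = i0, Rg = rg0, v = v0, bkg = bkg0),
          lower = c(scale = 0, Rg = 1e-3, v = 0.21, bkg = 0),
          upper = c(scale = Inf, Rg = Inf, v = 0.99, bkg = Inf),
          weights = w, control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          intensity ~ scale * excluded_volume_form_factor(q, Rg, v0) + bkg,
          data = df,
          start = list(scale = i0, Rg = rg0, bkg = bkg0),
          lower = c(scale = 0, Rg = 1e-3, bkg = 0),
          upper = c(scale = Inf, Rg = Inf, bkg = Inf),
          weights = w, control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) e)
  })
  ok <- fits[vapply(fits, inherits, logical(1), "nls")]
  if (!length(ok)) {
    abort(paste0("SANS fit failed for every start: ",
                 paste(vapply(fits, conditionMessage, character(1)), collapse = " | ")))
  }
  best <- ok[[which.min(vapply(ok, stats::deviance, numeric(1)))]]
  est <- coef(best)
  se <- sqrt(diag(vcov(best)))
  vhat <- if (is.null(v_fixed)) est[["v"]] else v_fixed
  v_se <- if (is.null(v_fixed)) se[["v"]] else NA_real_
  structure(list(Rg = est[["Rg"]], v = vhat, scale = est[["scale"]],
                 background = est[["bkg"]],
                 Rg_se = se[["Rg"]], v_se = v_se, scale_se = se[["scale"]],
                 background_se = se[["bkg"]],
                 porod_exponent = 1 / vhat,
                 sse = stats::deviance(best), fit = best, data = df),
            class = "sans_fit")
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("<sans_fit> Rg = %.3g A  v = %.3g (m = %.3g)  scale = %.3g  bkg = %.3g\n",
              x$Rg, x$v, x$porod_exponent, x$scale, x$background))
  invisible(x)
}

#' Radius of gyration of an excluded-volume chain from segment statistics
#'
#' `Rg^2 = b^2 n^(2v) / ((2v+1)(2v+2))` for statistical segment length `b`,
#' degree of polymerization `n` and excluded-volume parameter `v`.
#'
#' @param b Statistical segment length, Angstrom.
#' @param n Degree of polymerization.
#' @param v Excluded-volume parameter.
#' @return Rg in Angstrom.
#' @export
rg_from_segments <- function(b, n, v) {
  sqrt(b^2 * n^(2 * v) / ((2 * v + 1) * (2 * v + 2)))
}
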