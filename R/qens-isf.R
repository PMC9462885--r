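#' Fourier-transform a QENS spectrum to the intermediate scattering function
#'
#' Computes the time-domain intermediate scattering function from a measured
#' dynamic structure factor by the symmetrized (cosine) transform
#' \deqn{F_s(q,t) = \int S(q,\Delta E)\cos(\Delta E\, t/\hbar)\, d\Delta E,}
#' evaluated by the trapezoid rule on the measured energy window, and
#' deconvolves the instrument resolution by time-domain division
#' \eqn{F(q,t) = F_s(q,t)/F_{res}(q,t)}. The result is normalized so
#' \eqn{F(q,0) = 1}. Detailed-balance asymmetry is ignored (classical
#' \eqn{\hbar\omega \ll k_B T} regime). Times where the resolution transform
#' has decayed below 1% of its \eqn{t=0} value are dropped — beyond them the
#' division only amplifies noise; the dropped times are recorded in the
#' `dropped` attribute.
#'
#' @param sample Spectrum tibble (`q`, `dE`, `S`, ...) — one or more q
#'   groups.
#' @param resolution Resolution-function spectrum on the same dE grid; its q
#'   groups must match the sample's (a single q group is recycled to all).
#' @param times Time grid in ps (t >= 0).
#' @return A tibble with columns `q`, `t` (ps), `F` and `F_err` (the
#'   sample's `err` column propagated through the transform and the
#'   resolution division), one row per retained time point, plus a
#'   `dropped` attribute naming the (q, t) pairs removed by the resolution
#'   cutoff. Use `1/F_err^2` as [fit_kww()] weights when the spectra carry
#'   uncertainties.
#' @export
isf_from_spectrum <- function(sample, resolution, times) {
  stopifnot(all(times >= 0))
  hbar <- hydro_constants$hbar
  res_qs <- unique(resolution$q)
  out <- purrr::map_dfr(unique(sample$q), function(qv) {
    s <- sample[sample$q == qv, ]
    r <- if (length(res_qs) == 1L) resolution else resolution[resolution$q == qv, ]
    if (!nrow(r)) abort(sprintf("no resolution group at q=%g", qv))
    if (nrow(r) != nrow(s) || any(abs(r$dE - s$dE) > 1e-9)) {
      abort(sprintf("sample and resolution dE grids differ at q=%g", qv))
    }
    cosT <- function(S, t) vapply(t, function(ti) trapz(s$dE, S * cos(s$dE * ti / hbar)),
                                  numeric(1))
    f_res0 <- trapz(r$dE, r$S)
    if (!is.finite(f_res0) || f_res0 <= 0) abort(sprintf("resolution integral not positive at q=%g", qv))
    f_s <- cosT(s$S, times)
    f_r <- cosT(r$S, times)
    keep <- abs(f_r) >= 0.01 * f_res0
    if (!any(keep)) {
      abort(sprintf("q=%g: all time points beyond the resolution limit", qv))
    }
    f0 <- trapz(s$dE, s$S) / f_res0  # ratio at t = 0
    # first-order error propagation through the trapezoid transform: the
    # division by the decaying resolution transform amplifies noise at
    # large t, which the per-point error records
    tw <- trap_weights(s$dE)
    f_err <- vapply(times, function(ti) {
      sqrt(sum((tw * s$err * cos(s$dE * ti / hbar))^2))
    }, numeric(1)) / (abs(f_r) * abs(f0))
    tibble::tibble(q = qv, t = times, F = (f_s / f_r) / f0, F_err = f_err,
                   retained = keep)
  })
  dropped <- out[!out$retained, c("q", "t")]
  out <- out[out$retained, c("q", "t", "F", "F_err")]
  attr(out, "dropped") <- dropped
  out
}

trap_weights <- function(x) {
  n <- length(x)
  c(diff(x)[1L] / 2, (x[3:n] - x[1:(n - 2L)]) / 2, diff(x)[n - 1L] / 2)
}

#' Fit a stretched-exponential (KWW) relaxation to an ISF curve
#'
#' Fits \eqn{F(q,t) = A \exp[-(t/\tau)^\beta]} by weighted nonlinear least
#' squares (Levenberg–Marquardt via \pkg{minpack.lm}), with a multi-start
#' strategy over the stretching exponent (initial \eqn{\beta} of 0.3, 0.6
#' and 0.9, best fit by residual sum of squares). A is the amplitude of the
#' relaxing fraction, \eqn{\tau} the characteristic time, and \eqn{\beta}
#' the stretching exponent, bounded to `beta_bounds`. The Gamma-weighted
#' mean relaxation time \eqn{\langle\tau\rangle = (\tau/\beta)\Gamma(1/\beta)}
#' is reported alongside the bare \eqn{\tau} — downstream q-scaling uses the
#' mean.
#'
#' @param curve Tibble with columns `t` (ps) and `F`; at least 6 points with
#'   `F` inside `[-0.2, 1.2]`.
#' @param beta_bounds Length-2 bounds on beta, default `c(0.1, 1)`.
#' @param weights Optional per-point weights for the least squares.
#' @return An object of class `kww_fit`: list with `A`, `tau` (ps), `beta`,
#'   their standard errors, `mean_tau` (ps) with a delta-method standard
#'   error, `sse`, and the underlying `nls` object. Has [tidy()]/[glance()]
#'   methods.
#' @export
fit_kww <- function(curve, beta_bounds = c(0.1, 1), weights = NULL) {
  df <- tibble::tibble(t = curve$t, F = curve$F)
  if (nrow(df) < 6L) abort("need at least 6 points to fit a KWW curve")
  if (any(df$F < -0.2 | df$F > 1.2)) abort("F values outside [-0.2, 1.2]; not a normalized ISF")
  if (is.null(weights)) weights <- rep(1, nrow(df))
  a0 <- max(df$F)
  pos <- df$t > 0
  tau0 <- suppressWarnings(
    stats::approx(df$F[pos], df$t[pos], xout = a0 / exp(1), ties = mean)$y)
  if (is.na(tau0)) tau0 <- stats::median(df$t[pos])
  fits <- purrr::map(c(0.3, 0.6, 0.9), function(b0) {
    b0 <- min(max(b0, beta_bounds[1] + 1e-3), beta_bounds[2] - 1e-3)
    tryCatch(
      minpack.lm::nlsLM(F ~ A * exp(-(t / tau)^beta), data = df,
                        start = list(A = a0, tau = tau0, beta = b0),
                        lower = c(A = 0, tau = 1e-12, beta = beta_bounds[1]),
                        upper = c(A = 2, tau = Inf, beta = beta_bounds[2]),
                        weights = weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  })
  ok <- fits[vapply(fits, inherits, logical(1), "nls")]
  if (!length(ok)) {
    abort(paste0("KWW fit failed for every start: ",
                 paste(vapply(fits, conditionMessage, character(1)), collapse = " | ")))
  }
  best <- ok[[which.min(vapply(ok, stats::deviance, numeric(1)))]]
  est <- coef(best)
  se <- sqrt(diag(vcov(best)))
  mt <- kww_mean_tau(est[["tau"]], est[["beta"]])
  # delta method on (tau, beta): d<tau>/dtau = <tau>/tau;
  # d<tau>/dbeta = -<tau>/beta - (<tau>/beta^2) * digamma(1/beta)
  V <- vcov(best)[c("tau", "beta"), c("tau", "beta")]
  grad <- c(mt / est[["tau"]],
            -mt / est[["beta"]] - (mt / est[["beta"]]^2) * digamma(1 / est[["beta"]]))
  mt_se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(A = est[["A"]], tau = est[["tau"]], beta = est[["beta"]],
                 A_se = se[["A"]], tau_se = se[["tau"]], beta_se = se[["beta"]],
                 mean_tau = mt, mean_tau_se = mt_se,
                 sse = stats::deviance(best), fit = best, data = df),
            class = "kww_fit")
}

#' Gamma-weighted mean relaxation time of a KWW decay
#'
#' @param tau KWW characteristic time.
#' @param beta Stretching exponent in (0, 1].
#' @return `(tau / beta) * gamma(1 / beta)`.
#' @export
kww_mean_tau <- function(tau, beta) (tau / beta) * gamma(1 / beta)

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("<kww_fit> A = %.4g (%.2g)  tau = %.4g ps (%.2g)  beta = %.4g (%.2g)  <tau> = %.4g ps\n",
              x$A, x$A_se, x$tau, x$tau_se, x$beta, x$beta_se, x$mean_tau))
  invisible(x)
}

#' Power-law scaling of relaxation time with momentum transfer
#'
#' Ordinary least squares of `log(tau)` on `log(q)`. For sub-diffusive
#' hydration water the relaxation time follows \eqn{\tau \propto q^{-m}}
#' with m near 2.65 at room temperature; the fitted slope is negative and
#' its magnitude is reported separately as `exponent_magnitude`.
#'
#' @param scaling Tibble with columns `q` (1/Angstrom) and `mean_tau` (ps),
#'   all positive, at least 3 rows.
#' @return Object of class `q_power_fit`: `exponent` (signed slope),
#'   `exponent_magnitude`, `prefactor` (tau at q = 1), `stderr` of the
#'   slope, and the `lm` fit. Has [tidy()]/[glance()] methods.
#' @export
fit_q_power <- function(scaling) {
  stopifnot(all(c("q", "mean_tau") %in% names(scaling)))
  if (nrow(scaling) < 3L) abort("need at least 3 (q, tau) pairs")
  if (any(scaling$q <= 0) || any(scaling$mean_tau <= 0)) {
    abort("q and mean_tau must be positive for log-log regression")
  }
  fit <- lm(log(mean_tau) ~ log(q), data = scaling)
  slope <- coef(fit)[[2L]]
  structure(list(exponent = slope, exponent_magnitude = abs(slope),
                 prefactor = exp(coef(fit)[[1L]]),
                 stderr = suppressWarnings(summary(fit)$coefficients[2L, 2L]),
                 fit = fit, data = scaling),
            class = "q_power_fit")
}

#' Spectrum-to-scaling pipeline
#'
#' Convenience wrapper chaining the three reduction steps: Fourier
#' transformation of each q group ([isf_from_spectrum()]), per-q KWW
#' fitting ([fit_kww()], inverse-variance weighted via the propagated ISF
#' errors when the spectra carry uncertainties), and log–log regression of
#' the mean relaxation time on q ([fit_q_power()]).
#'
#' @inheritParams isf_from_spectrum
#' @param beta_bounds Bounds on the stretching exponent for every KWW fit.
#' @return A list with `isf` (tibble), `kww` (tibble of per-q tidy fits)
#'   and `scaling` (the [fit_q_power()] object).
#' @export
qens_q_scaling <- function(sample, resolution, times, beta_bounds = c(0.1, 1)) {
  isf <- isf_from_spectrum(sample, resolution, times)
  per_q <- isf |>
    dplyr::group_by(.data$q) |>
    dplyr::group_split()
  fits <- purrr::map(per_q, function(cv) {
    w <- if (all(cv$F_err == 0)) NULL else 1 / pmax(cv$F_err, max(cv$F_err) * 1e-6)^2
    fit_kww(cv, beta_bounds = beta_bounds, weights = w)
  })
  kww <- purrr::map2_dfr(per_q, fits, function(cv, f) {
    tibble::tibble(q = cv$q[1L], A = f$A, tau = f$tau, beta = f$beta,
                   mean_tau = f$mean_tau, mean_tau_se = f$mean_tau_se)
  })
  list(isf = isf, kww = kww, scaling = fit_q_power(kww))
}

#' @export
print.q_power_fit <- function(x, ...) {
  cat(sprintf("<q_power_fit> tau ~ q^%.3f (se %.3f), prefactor %.4g ps\n",
              x$exponent, x$stderr, x$prefactor))
  invisible(x)
}
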