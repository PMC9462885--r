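#' Arrhenius and super-Arrhenius (VFT) parameter objects
#'
#' Containers for the two relaxation laws
#' \deqn{\tau = \tau_0 \exp(E_A / k_B T)} (Arrhenius, strong liquid) and
#' \deqn{\tau = \tau_0 \exp(K T_0 / (T - T_0))} (super-Arrhenius /
#' Vogel–Fulcher–Tammann, fragile liquid), with times in ns, activation
#' energy in meV, and temperatures in K. `T0` is the relaxation-time
#' divergence temperature and `K` the fragility constant; both laws can be
#' built directly from published parameters or produced by
#' [fit_arrhenius()] / [fit_super_arrhenius()]. When no covariance is
#' available (hand-built parameters) the uncertainties are treated as
#' independent in propagation.
#'
#' @param tau0 Prefactor in ns (> 0).
#' @param EA Activation energy in meV.
#' @param K Fragility constant (> 0 for a physical fragile liquid).
#' @param T0 Divergence temperature in K (fixed, never fitted).
#' @param tau0_se,EA_se,K_se Optional standard errors.
#' @param cov_log Optional 2x2 covariance of `(log(tau0), K)` or
#'   `(log(tau0), EA)` from a fit, used for first-order propagation.
#' @return An object of class `arrhenius_params` or `vft_params`.
#' @export
arrhenius_params <- function(tau0, EA, tau0_se = NA_real_, EA_se = NA_real_,
                             cov_log = NULL) {
  if (tau0 <= 0) abort("tau0 must be positive")
  structure(list(tau0 = tau0, EA = EA, tau0_se = tau0_se, EA_se = EA_se,
                 cov_log = cov_log),
            class = "arrhenius_params")
}

#' @rdname arrhenius_params
#' @export
vft_params <- function(tau0, K, T0, tau0_se = NA_real_, K_se = NA_real_,
                       cov_log = NULL) {
  if (tau0 <= 0) abort("tau0 must be positive")
  if (T0 <= 0) abort("T0 must be positive")
  structure(list(tau0 = tau0, K = K, T0 = T0, tau0_se = tau0_se, K_se = K_se,
                 cov_log = cov_log),
            class = "vft_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("<arrhenius> tau0 = %.4g ns  EA = %.4g meV\n", x$tau0, x$EA))
  invisible(x)
}

#' @export
print.vft_params <- function(x, ...) {
  cat(sprintf("<super-arrhenius> tau0 = %.4g ns  K = %.4g  T0 = %g K\n",
              x$tau0, x$K, x$T0))
  invisible(x)
}

ln_weights <- function(tau, err) {
  if (is.null(err) || all(is.na(err))) rep(1, length(tau)) else (tau / err)^2
}

#' Fit the Arrhenius law to relaxation times
#'
#' Weighted linear regression of `log(tau)` on `1/(kB T)` — fitting in log
#' space is exact under multiplicative noise and reproducible. The slope is
#' the activation energy in meV (via the Boltzmann constant in
#' [hydro_constants]); the intercept is `log(tau0)`.
#'
#' @param data Tibble with columns `temperature` (K), `tau` (ns) and
#'   optionally `err` (ns, used as 1-sigma weights).
#' @return An [arrhenius_params] object carrying fit standard errors and the
#'   log-space covariance.
#' @export
fit_arrhenius <- function(data) {
  stopifnot(all(c("temperature", "tau") %in% names(data)))
  if (nrow(data) < 2L) abort("need at least 2 points")
  if (any(data$tau <= 0)) abort("tau must be positive")
  if (length(unique(data$temperature)) < 2L) abort("singular design: all temperatures equal")
  x <- 1 / (hydro_constants$kB * data$temperature)
  w <- ln_weights(data$tau, if ("err" %in% names(data)) data$err else NULL)
  fit <- lm(log(data$tau) ~ x, weights = w)
  V <- safe_vcov(fit)
  arrhenius_params(tau0 = exp(coef(fit)[[1L]]), EA = coef(fit)[[2L]],
                   tau0_se = exp(coef(fit)[[1L]]) * sqrt(V[1L, 1L]),
                   EA_se = sqrt(V[2L, 2L]), cov_log = V)
}

#' Fit the super-Arrhenius (VFT) law with a fixed divergence temperature
#'
#' Weighted linear regression of `log(tau)` on `T0/(T - T0)`: the slope is
#' the fragility constant K and the intercept `log(tau0)`. T0 is a fixed
#' input, never fitted — the experimental protocol is to compare literature
#' divergence temperatures (e.g. 124, 136 and 176 K for water) on the same
#' data, and a joint three-parameter fit is ill-conditioned on a handful of
#' temperatures.
#'
#' @inheritParams fit_arrhenius
#' @param T0 Divergence temperature in K; every data temperature must
#'   exceed it.
#' @return A [vft_params] object.
#' @export
fit_super_arrhenius <- function(data, T0) {
  stopifnot(all(c("temperature", "tau") %in% names(data)))
  if (nrow(data) < 2L) abort("need at least 2 points")
  bad <- data$temperature[data$temperature <= T0]
  if (length(bad)) {
    abort(sprintf("temperature %g K is not above T0 = %g K", bad[1L], T0))
  }
  if (any(data$tau <= 0)) abort("tau must be positive")
  x <- T0 / (data$temperature - T0)
  w <- ln_weights(data$tau, if ("err" %in% names(data)) data$err else NULL)
  fit <- lm(log(data$tau) ~ x, weights = w)
  V <- safe_vcov(fit)
  vft_params(tau0 = exp(coef(fit)[[1L]]), K = coef(fit)[[2L]], T0 = T0,
             tau0_se = exp(coef(fit)[[1L]]) * sqrt(V[1L, 1L]),
             K_se = sqrt(V[2L, 2L]), cov_log = V)
}

safe_vcov <- function(fit) {
  V <- tryCatch(suppressWarnings(vcov(fit)),
                error = function(e) matrix(NA_real_, 2, 2))
  V[!is.finite(V)] <- 0  # saturated 2-point fits have no residual dof
  V
}

#' Evaluate a relaxation law at given temperatures
#'
#' Direct evaluation of the Arrhenius or VFT law, with first-order
#' uncertainty propagation from the parameter covariance (or from
#' independent standard errors when only those are available). This is how
#' relaxation times measured at accessible temperatures are extrapolated
#' into the supercooled regime where the instrument window cannot reach.
#'
#' @param params An [arrhenius_params] or [vft_params] object.
#' @param temperature Temperatures in K (each must exceed `T0` for the VFT
#'   law).
#' @return A tibble with columns `temperature`, `tau` (ns) and `tau_se`.
#' @export
evaluate_tau <- function(params, temperature) UseMethod("evaluate_tau")

#' @export
evaluate_tau.arrhenius_params <- function(params, temperature) {
  x <- 1 / (hydro_constants$kB * temperature)
  eval_log_linear(params$tau0, params$EA, params$tau0_se, params$EA_se,
                  params$cov_log, x, temperature)
}

#' @export
evaluate_tau.vft_params <- function(params, temperature) {
  if (any(temperature <= params$T0)) {
    abort(sprintf("temperature must exceed T0 = %g K", params$T0))
  }
  x <- params$T0 / (temperature - params$T0)
  eval_log_linear(params$tau0, params$K, params$tau0_se, params$K_se,
                  params$cov_log, x, temperature)
}

eval_log_linear <- function(tau0, slope, tau0_se, slope_se, cov_log, x, temperature) {
  tau <- tau0 * exp(slope * x)
  if (!is.null(cov_log)) {
    vlog <- cov_log[1, 1] + x^2 * cov_log[2, 2] + 2 * x * cov_log[1, 2]
  } else {
    vlog <- ifelse(is.na(tau0_se), 0, (tau0_se / tau0)^2) +
      x^2 * ifelse(is.na(slope_se), 0, slope_se^2)
  }
  tibble::tibble(temperature = temperature, tau = tau, tau_se = tau * sqrt(vlog))
}

#' Locate the fragile-to-strong crossover temperature
#'
#' Finds the temperature where an Arrhenius branch and a super-Arrhenius
#' branch predict the same relaxation time, by bisection on the difference
#' of the two log-laws to 0.01 K. This is the crossover temperature of the
#' fragile-to-strong scenario for supercooled water.
#'
#' @param arr An [arrhenius_params] object.
#' @param vft A [vft_params] object.
#' @param bracket Length-2 temperature interval (K) on which the
#'   log-difference changes sign; both ends must exceed `vft$T0`.
#' @return The crossover temperature in K.
#' @export
crossover_temperature <- function(arr, vft, bracket) {
  stopifnot(length(bracket) == 2L)
  g <- function(Tv) {
    log(arr$tau0) + arr$EA / (hydro_constants$kB * Tv) -
      (log(vft$tau0) + vft$K * vft$T0 / (Tv - vft$T0))
  }
  lo <- min(bracket); hi <- max(bracket)
  if (lo <= vft$T0) abort("bracket must lie above the VFT divergence temperature")
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    abort("log-difference of the two laws does not change sign on the bracket")
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) return(mid)
    if (glo * gm < 0) { hi <- mid } else { lo <- mid; glo <- gm }
  }
  (lo + hi) / 2
}
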