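#' Broom-style tidiers for fitted objects
#'
#' All fit objects in the package ([fit_kww()], [fit_arrhenius()],
#' [fit_super_arrhenius()], [fit_q_power()], [fit_sans()], [match_point()],
#' [detect_onset()]) have `tidy()` methods returning one row per parameter
#' (`term`, `estimate`, `std.error`) and `glance()` methods returning a
#' one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name hydroshell-tidiers
NULL

tidy_rows <- function(terms, est, se) {
  tibble::tibble(term = terms, estimate = unname(est), std.error = unname(se))
}

#' @rdname hydroshell-tidiers
#' @export
tidy.kww_fit <- function(x, ...) {
  tidy_rows(c("A", "tau", "beta", "mean_tau"),
            c(x$A, x$tau, x$beta, x$mean_tau),
            c(x$A_se, x$tau_se, x$beta_se, x$mean_tau_se))
}

#' @rdname hydroshell-tidiers
#' @export
glance.kww_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = nrow(x$data), mean_tau = x$mean_tau)
}

#' @rdname hydroshell-tidiers
#' @export
tidy.arrhenius_params <- function(x, ...) {
  tidy_rows(c("tau0", "EA"), c(x$tau0, x$EA), c(x$tau0_se, x$EA_se))
}

#' @rdname hydroshell-tidiers
#' @export
glance.arrhenius_params <- function(x, ...) {
  tibble::tibble(tau0 = x$tau0, EA = x$EA)
}

#' @rdname hydroshell-tidiers
#' @export
tidy.vft_params <- function(x, ...) {
  tidy_rows(c("tau0", "K", "T0"), c(x$tau0, x$K, x$T0),
            c(x$tau0_se, x$K_se, NA_real_))
}

#' @rdname hydroshell-tidiers
#' @export
glance.vft_params <- function(x, ...) {
  tibble::tibble(tau0 = x$tau0, K = x$K, T0 = x$T0)
}

#' @rdname hydroshell-tidiers
#' @export
tidy.q_power_fit <- function(x, ...) {
  tidy_rows(c("exponent", "prefactor"), c(x$exponent, x$prefactor),
            c(x$stderr, NA_real_))
}

#' @rdname hydroshell-tidiers
#' @export
glance.q_power_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent,
                 exponent_magnitude = x$exponent_magnitude,
                 stderr = x$stderr, n = nrow(x$data))
}

#' @rdname hydroshell-tidiers
#' @export
tidy.sans_fit <- function(x, ...) {
  tidy_rows(c("Rg", "v", "scale", "background"),
            c(x$Rg, x$v, x$scale, x$background),
            c(x$Rg_se, x$v_se, x$scale_se, x$background_se))
}

#' @rdname hydroshell-tidiers
#' @export
glance.sans_fit <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, v = x$v, porod_exponent = x$porod_exponent,
                 sse = x$sse, n = nrow(x$data))
}

#' @rdname hydroshell-tidiers
#' @export
tidy.match_point_fit <- function(x, ...) {
  tidy_rows(c("f_match", "slope", "intercept"),
            c(x$f_match, x$slope, x$intercept),
            rep(NA_real_, 3))
}

#' @rdname hydroshell-tidiers
#' @export
glance.match_point_fit <- function(x, ...) {
  tibble::tibble(f_match = x$f_match, sse = x$sse, n = nrow(x$data))
}

#' @rdname hydroshell-tidiers
#' @export
tidy.onset_fit <- function(x, ...) {
  tidy_rows(c("t_onset", "slope_low", "slope_high", "intercept"),
            c(x$t_onset, x$slope_low, x$slope_high, x$intercept),
            rep(NA_real_, 4))
}

#' @rdname hydroshell-tidiers
#' @export
glance.onset_fit <- function(x, ...) {
  tibble::tibble(t_onset = x$t_onset, sse = x$sse, n = nrow(x$data))
}
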