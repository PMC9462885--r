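#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: elastic
#' scans (with the fitted onset overlaid when supplied), ISF curves with
#' their KWW fits, SANS curves with the form-factor fit, hydrogen-bond
#' correlation functions, and volume-distribution functions.
#'
#' @param object The object to plot.
#' @param onset Optional [detect_onset()] result overlaid as the two-branch
#'   fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hydroshell-plots
NULL

#' @rdname hydroshell-plots
#' @export
autoplot.elastic_scan <- function(object, onset = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (K)", y = "Summed elastic intensity (norm.)")
  if (!is.null(onset)) {
    tb <- onset$t_onset
    grid <- tibble::tibble(temperature = seq(min(object$temperature),
                                             max(object$temperature), length.out = 200))
    grid$intensity <- onset$intercept +
      onset$slope_low * pmin(grid$temperature - tb, 0) +
      onset$slope_high * pmax(grid$temperature - tb, 0)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = tb, linetype = "dashed")
  }
  p
}

#' @rdname hydroshell-plots
#' @param isf ISF tibble (`q`, `t`, `F`) as returned by
#'   [isf_from_spectrum()] or [incoherent_isf()].
#' @export
plot_isf <- function(isf, ...) {
  ggplot2::ggplot(isf, ggplot2::aes(x = .data$t, y = .data$F,
                                    colour = factor(.data$q))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t (ps)", y = "F(q, t)", colour = "q (1/Å)")
}

#' @rdname hydroshell-plots
#' @export
autoplot.kww_fit <- function(object, ...) {
  grid <- tibble::tibble(t = exp(seq(log(max(min(object$data$t[object$data$t > 0]), 1e-3)),
                                     log(max(object$data$t)), length.out = 200)))
  grid$F <- object$A * exp(-(grid$t / object$tau)^object$beta)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$F)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t (ps)", y = "F(q, t)",
                  subtitle = sprintf("A = %.3g, tau = %.3g ps, beta = %.3g",
                                     object$A, object$tau, object$beta))
}

#' @rdname hydroshell-plots
#' @export
autoplot.sans_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(q = exp(seq(log(min(df$q)), log(max(df$q)), length.out = 300)))
  grid$intensity <- object$scale *
    excluded_volume_form_factor(grid$q, object$Rg, object$v) + object$background
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/Å)", y = "I(q)",
                  subtitle = sprintf("Rg = %.3g Å, v = %.3g (m = %.3g)",
                                     object$Rg, object$v, object$porod_exponent))
}

#' @rdname hydroshell-plots
#' @param correlation Tibble (`t`, `C`, `S`) from [correlation_functions()].
#' @export
plot_correlation <- function(correlation, ...) {
  long <- tidyr::pivot_longer(correlation, c("C", "S"),
                              names_to = "kind", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = exp(-1), linetype = "dotted") +
    ggplot2::labs(x = "t (ps)", y = "correlation",
                  colour = NULL)
}

#' @rdname hydroshell-plots
#' @export
autoplot.volume_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$V)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$V - .data$se,
                                          ymax = .data$V + .data$se)) +
    ggplot2::labs(x = "r (Å)", y = "V(r)")
}

#' @rdname hydroshell-plots
#' @export
autoplot.rdf_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}
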