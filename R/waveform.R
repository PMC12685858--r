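#' Pulsatile inflow waveform
#'
#' A strictly positive periodic inlet flow-rate waveform built from a small
#' number of Fourier harmonics:
#' \deqn{Q(t) = \bar{Q}\,\big(1 + s \sum_h a_h \sin(2\pi h t/T + \phi_h)\big)}
#' The zero-mean harmonic sum guarantees that the time average over one
#' period equals `mean_flow` exactly.  When `pulsatility_index` is given
#' (default 1, a typical arterial value), the scale `s` is set so that
#' `(Qmax - Qmin)/mean = pulsatility_index`; because the harmonic sum has
#' zero mean, any pulsatility index <= 1 yields a strictly positive waveform.
#'
#' @param mean_flow Time-averaged flow rate in m^3/s (> 0).
#' @param period Cardiac period in seconds (default 0.8 s, ~75 bpm).
#' @param harmonic_amplitudes Dimensionless amplitudes `a_h` of harmonics
#'   1..H (before pulsatility scaling).
#' @param harmonic_phases Phases `phi_h` in radians, one per harmonic.
#' @param pulsatility_index Target `(Qmax - Qmin)/mean`, or `NULL` to use the
#'   amplitudes as given.
#' @return A `pulsatile_waveform` object.
#' @examples
#' wf <- pulsatile_waveform(5e-6)
#' range(waveform_flow(wf, seq(0, 0.8, length.out = 200)))
#' @export
pulsatile_waveform <- function(mean_flow, period = 0.8,
                               harmonic_amplitudes = c(0.45, 0.12),
                               harmonic_phases = c(0, -pi / 2),
                               pulsatility_index = 1) {
  check_positive_scalar(mean_flow, "mean_flow")
  check_positive_scalar(period, "period")
  if (length(harmonic_amplitudes) != length(harmonic_phases)) {
    abort("harmonic_amplitudes and harmonic_phases must have equal length.",
          class = "emboflow_domain_error")
  }
  scale <- 1
  if (!is.null(pulsatility_index)) {
    check_positive_scalar(pulsatility_index, "pulsatility_index")
    tt <- seq(0, period, length.out = 4097L)[-4097L]
    base <- harmonic_sum(tt, period, harmonic_amplitudes, harmonic_phases)
    rng <- max(base) - min(base)
    if (rng <= 0) {
      abort("Harmonic amplitudes are all zero; cannot scale to a pulsatility index.",
            class = "emboflow_domain_error")
    }
    scale <- pulsatility_index / rng
  }
  wf <- structure(list(mean_flow = mean_flow, period = period,
                       harmonic_amplitudes = harmonic_amplitudes,
                       harmonic_phases = harmonic_phases, scale = scale),
                  class = "pulsatile_waveform")
  tt <- seq(0, period, length.out = 4097L)[-4097L]
  if (min(waveform_flow(wf, tt)) <= 0) {
    abort("Waveform is not strictly positive over the period; reduce amplitudes or pulsatility_index.",
          class = "emboflow_domain_error")
  }
  wf
}

harmonic_sum <- function(t, period, amplitudes, phases) {
  out <- numeric(length(t))
  for (h in seq_along(amplitudes)) {
    out <- out + amplitudes[h] * sin(2 * pi * h * t / period + phases[h])
  }
  out
}

#' Evaluate a waveform
#'
#' @param waveform A [pulsatile_waveform()].
#' @param t Times in seconds (vectorised).
#' @return Flow rates in m^3/s.
#' @export
waveform_flow <- function(waveform, t) {
  stopifnot(inherits(waveform, "pulsatile_waveform"))
  waveform$mean_flow *
    (1 + waveform$scale * harmonic_sum(t, waveform$period,
                                       waveform$harmonic_amplitudes,
                                       waveform$harmonic_phases))
}

#' Rescale a waveform's mean flow
#'
#' Multiplies the whole waveform by `factor`, preserving its shape (and hence
#' its pulsatility index).
#'
#' @param waveform A [pulsatile_waveform()].
#' @param factor Positive scale factor.
#' @return A `pulsatile_waveform`.
#' @export
scale_waveform <- function(waveform, factor) {
  check_positive_scalar(factor, "factor")
  waveform$mean_flow <- waveform$mean_flow * factor
  waveform
}

#' @exportS3Method base::print
print.pulsatile_waveform <- function(x, ...) {
  tt <- seq(0, x$period, length.out = 513L)[-513L]
  q <- waveform_flow(x, tt)
  cat(sprintf("<pulsatile_waveform> mean %.3g cm^3/s, period %g s, PI %.2f (%d harmonics)\n",
              1e6 * x$mean_flow, x$period,
              (max(q) - min(q)) / x$mean_flow,
              length(x$harmonic_amplitudes)))
  invisible(x)
}

#' @export
autoplot.pulsatile_waveform <- function(object, n = 256, ...) {
  tt <- seq(0, object$period, length.out = n)
  df <- tibble::tibble(time = tt, flow_cm3s = 1e6 * waveform_flow(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$flow_cm3s)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = expression(inlet~flow~(cm^3/s)),
                  title = "Pulsatile inlet waveform") +
    ggplot2::theme_minimal()
}
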