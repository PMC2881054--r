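#' Synthesize a pump waveform
#'
#' Builds periodic pressure and flow time series for the two pump
#' configurations. The dual-ventricle pulsatile (WAK) pump ejects with a
#' half-sinusoid systole per channel and drives blood and dialysate in
#' counter-phase (180 degrees apart), which maximizes the instantaneous
#' trans-membrane pressure; its cycle-mean flow equals
#' `frequency x stroke_volume` exactly (the discrete ejection profile is
#' normalized so the trapezoidal cycle mean is exact). The
#' roller/centrifugal configuration produces a low-ripple, quasi-steady
#' series. The ejection shape is a stylization: measured waveforms have
#' sharper peaks, so the peak flow is exposed as a separate scaling knob
#' while the cycle mean is preserved.
#'
#' @param pump `"WAK"` or `"roller_centrifugal"`.
#' @param frequency pump rate, cycles/min (typical: 110 for the WAK
#'   pulsatile pump, 13 for the roller pump).
#' @param stroke_volume displaced volume per cycle, cm^3.
#' @param pressure_means named list of mean port pressures in mmHg
#'   (`P_b_in`, `P_b_out`, `P_d_in`, `P_d_out`).
#' @param pressure_amplitude peak pressure excursion around the mean,
#'   mmHg.
#' @param peak_flow optional peak flow (ml/min) of the ejection profile;
#'   when given, the profile is a sharpened power of the half-sinusoid
#'   with this peak and the same cycle mean.
#' @param ripple relative flow/pressure ripple of the roller pump.
#' @param n_cycles,samples_per_cycle time-grid resolution.
#' @return object of class `pump_waveform`: `time` (s), a data frame
#'   `series` with per-port pressures (mmHg) and flows (ml/min), and the
#'   pump descriptor.
#' @export
synthesize_waveform <- function(pump = c("WAK", "roller_centrifugal"),
                                frequency = if (pump == "WAK") 110 else 13,
                                stroke_volume = if (pump == "WAK") 0.8 else 8,
                                pressure_means = list(
                                  P_b_in = 24, P_b_out = 21,
                                  P_d_in = -24, P_d_out = -31
                                ),
                                pressure_amplitude = 15,
                                peak_flow = NULL,
                                ripple = 0.05,
                                n_cycles = 5, samples_per_cycle = 200) {
  pump <- match.arg(pump)
  if (frequency <= 0) stop("frequency must be positive")
  f_hz <- frequency / 60
  period <- 1 / f_hz
  n <- n_cycles * samples_per_cycle
  t <- seq(0, n_cycles * period, length.out = n + 1)[-(n + 1)]
  phase <- 2 * pi * f_hz * t
  mean_flow <- frequency * stroke_volume # ml/min

  if (pump == "WAK") {
    sharpen <- 1
    if (!is.null(peak_flow) && mean_flow > 0 && peak_flow > mean_flow * pi) {
      # raise the half-sinusoid to a power until peak/mean matches
      base <- pmax(sin(phase), 0)
      target_mean <- mean_flow / peak_flow # normalized shape mean needed
      sharpen <- stats::uniroot(
        function(p) mean(base^p) - target_mean,
        interval = c(1, 50)
      )$root
    }
    shape_b <- pmax(sin(phase), 0)^sharpen
    shape_d <- pmax(sin(phase + pi), 0)^sharpen
    # normalize so the discrete cycle mean is exactly frequency x stroke
    q_b <- if (mean(shape_b) > 0) shape_b * mean_flow / mean(shape_b) else shape_b
    q_d <- if (mean(shape_d) > 0) shape_d * mean_flow / mean(shape_d) else shape_d
    p_mod_b <- sin(phase)
    p_mod_d <- sin(phase + pi)
  } else {
    q_b <- mean_flow * (1 + ripple * sin(phase))
    q_d <- mean_flow * (1 + ripple * sin(phase + pi / 3))
    p_mod_b <- ripple * sin(phase)
    p_mod_d <- ripple * sin(phase + pi / 3)
  }

  series <- data.frame(
    P_b_in = pressure_means$P_b_in + pressure_amplitude * p_mod_b,
    P_b_out = pressure_means$P_b_out + pressure_amplitude * p_mod_b,
    P_d_in = pressure_means$P_d_in + pressure_amplitude * p_mod_d,
    P_d_out = pressure_means$P_d_out + pressure_amplitude * p_mod_d,
    Q_b_in = q_b, Q_b_out = q_b,
    Q_d_in = q_d, Q_d_out = q_d
  )
  structure(
    list(
      time = t, series = series,
      descriptor = list(
        pump = pump, frequency = frequency, stroke_volume = stroke_volume,
        phase_offset_deg = if (pump == "WAK") 180 else 0,
        samples_per_cycle = samples_per_cycle, n_cycles = n_cycles
      )
    ),
    class = "pump_waveform"
  )
}

#' @export
print.pump_waveform <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf(
    "%s pump waveform: %g cycles/min, stroke %g cm^3, %d cycles x %d samples\n",
    d$pump, d$frequency, d$stroke_volume, d$n_cycles, d$samples_per_cycle
  ))
  m <- time_mean(x)
  cat(sprintf(
    "  cycle means: Q_b %.1f ml/min, P_b_in %.1f mmHg, P_d_out %.1f mmHg\n",
    m[["Q_b_in"]], m[["P_b_in"]], m[["P_d_out"]]
  ))
  invisible(x)
}

#' @export
plot.pump_waveform <- function(x, what = c("pressure", "flow"), ...) {
  what <- match.arg(what)
  s <- x$series
  if (what == "pressure") {
    graphics::matplot(x$time, s[, c("P_b_in", "P_b_out", "P_d_in", "P_d_out")],
      type = "l", lty = 1, xlab = "time (s)", ylab = "pressure (mmHg)",
      main = paste(x$descriptor$pump, "port pressures"), ...
    )
    graphics::legend("topright",
      legend = c("P_b_in", "P_b_out", "P_d_in", "P_d_out"),
      col = 1:4, lty = 1, cex = 0.8
    )
  } else {
    graphics::matplot(x$time, s[, c("Q_b_in", "Q_d_in")],
      type = "l", lty = 1, xlab = "time (s)", ylab = "flow (ml/min)",
      main = paste(x$descriptor$pump, "channel flows"), ...
    )
    graphics::legend("topright",
      legend = c("blood", "dialysate"),
      col = 1:2, lty = 1, cex = 0.8
    )
  }
  invisible(x)
}

#' Cycle-averaged port values of a waveform
#'
#' Averages each port series over an integer number of pump cycles; a
#' trailing partial cycle is dropped with a warning, since averaging over
#' incomplete cycles biases the mean of a periodic signal.
#'
#' @param waveform a [synthesize_waveform()] result.
#' @return named numeric vector of mean pressures (mmHg) and flows
#'   (ml/min).
#' @export
time_mean <- function(waveform) {
  stopifnot(inherits(waveform, "pump_waveform"))
  d <- waveform$descriptor
  n <- length(waveform$time)
  spc <- d$samples_per_cycle
  full <- (n %/% spc) * spc
  if (full < spc) stop("need at least one full cycle to average")
  if (full < n) {
    warning("non-integer cycle coverage; averaging over ", full %/% spc,
      " complete cycle(s)")
  }
  colMeans(waveform$series[seq_len(full), , drop = FALSE])
}

#' Quasi-steadiness check for pulsatile operation
#'
#' Computes the momentum and mass Womersley numbers of the lumen,
#' shell and membrane at a pulsation frequency and applies the
#' quasi-steady criterion: when the momentum Womersley number is below
#' one, the velocity field follows the instantaneous driving pressures
#' and the device can be simulated at the cycle-mean boundary values.
#' (The mass-transfer Womersley number is typically large, which means
#' the concentration field cannot follow the pulsation at all and
#' settles to the steady field of the mean flow - the same practical
#' conclusion.)
#'
#' @param geometry,fluid device description.
#' @param solute a [solute_properties()] object.
#' @param frequency pulsation frequency, Hz.
#' @param Q_b,Q_d,UF operating point (ml/min) for the underlying
#'   dimensionless numbers.
#' @return list with the `alpha` values per region, the criterion
#'   `quasi_steady` (momentum alpha of the lumen < 1) and a verdict
#'   string.
#' @export
quasi_steady_check <- function(geometry, fluid, solute, frequency,
                               Q_b = 100, Q_d = 100, UF = 20) {
  dn <- dimensionless_numbers(
    geometry, fluid, solute,
    list(Q_b = Q_b, Q_d = Q_d, UF = UF, f = frequency)
  )
  alpha <- c(
    blood_momentum = dn$blood$alpha_momentum,
    blood_mass = dn$blood$alpha_mass,
    dialysate_momentum = dn$dialysate$alpha_momentum,
    membrane_momentum = dn$membrane$alpha_momentum,
    membrane_mass = dn$membrane$alpha_mass
  )
  qs <- alpha[["blood_momentum"]] < 1
  list(
    alpha = alpha,
    quasi_steady = qs,
    verdict = if (qs) {
      "quasi-steady: simulate at cycle-mean boundary values"
    } else {
      "not quasi-steady: momentum Womersley number exceeds 1"
    }
  )
}
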