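#' Unit conversions between bench-report units and SI
#'
#' Dialyzer bench data are conventionally reported in mmHg (pressures),
#' ml/min (flows), ml/hr/mmHg (ultrafiltration coefficient) and mg/dL
#' (concentrations). All solver internals work in SI. These helpers are the
#' single source of truth for the conversion factors; 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

# Pa per mmHg
.MMHG_PA <- 133.322
# m^3/s per ml/min
.MLMIN_M3S <- 1e-6 / 60
# m^3/s per ml/hr
.MLHR_M3S <- 1e-6 / 3600

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * .MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / .MMHG_PA

#' @rdname units
#' @export
mlmin_to_m3s <- function(x) x * .MLMIN_M3S

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x / .MLMIN_M3S

#' Convert an ultrafiltration coefficient to a hydraulic permeability
#'
#' The device-level ultrafiltration coefficient \eqn{K_{UF}} (ml/hr/mmHg)
#' and the membrane hydraulic permeability \eqn{L_p} (m/s/Pa) are related
#' through the total membrane area \eqn{A}: \eqn{UF = L_p A \cdot TMP}, i.e.
#' \eqn{L_p = K_{UF} / A} after unit conversion.
#'
#' @param kuf ultrafiltration coefficient, ml/hr/mmHg.
#' @param lp hydraulic permeability, m/s/Pa.
#' @param area total membrane area, m^2.
#' @return `lp_from_kuf()`: hydraulic permeability in m/s/Pa;
#'   `kuf_from_lp()`: ultrafiltration coefficient in ml/hr/mmHg.
#' @examples
#' lp_from_kuf(21.6, area = 0.6)
#' kuf_from_lp(lp_from_kuf(21.6, 0.6), 0.6)
#' @export
lp_from_kuf <- function(kuf, area) {
  stopifnot(area > 0)
  kuf * .MLHR_M3S / .MMHG_PA / area
}

#' @rdname lp_from_kuf
#' @export
kuf_from_lp <- function(lp, area) {
  stopifnot(area > 0)
  lp * area / .MLHR_M3S * .MMHG_PA
}
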