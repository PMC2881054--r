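#' Hollow-fiber dialyzer geometry
#'
#' Describes the Krogh-cylinder unit used to model a uniform fiber bundle:
#' a single fiber lumen (radius `R1`), the porous membrane annulus
#' (`R1`..`R2`) and the surrounding dialysate shell annulus (`R2`..`R3`),
#' replicated `n_fibers` times. The configured total membrane area `A` is
#' kept as the device truth (manufacturers quote a rounded nominal area);
#' it is validated against the surface areas the radii imply rather than
#' recomputed, because the Starling device law `UF = Lp * A * TMP` and the
#' membrane Peclet estimate use the nominal area.
#'
#' @param n_fibers number of hollow fibers in the bundle.
#' @param R1 lumen (inner membrane) radius, m.
#' @param R2 outer membrane radius, m.
#' @param R3 outer radius of the Krogh shell annulus, m.
#' @param L fiber length, m.
#' @param A total membrane area, m^2 (nominal).
#' @param shell_id inner diameter of the dialyzer housing, m.
#' @return an object of class `dialyzer_geometry` with derived membrane
#'   thickness `h = R2 - R1`.
#' @seealso [m60_geometry()] for the Multiflow M60 defaults.
#' @export
dialyzer_geometry <- function(n_fibers, R1, R2, R3, L, A, shell_id = NA_real_) {
  stopifnot(
    n_fibers > 0, R1 > 0, L > 0, A > 0,
    R1 < R2, R2 < R3
  )
  # nominal area must be bracketed by the inner/outer fiber surface areas
  # (with 5% slack for rounding of the nominal value)
  a_in <- 2 * pi * R1 * L * n_fibers
  a_out <- 2 * pi * R2 * L * n_fibers
  if (A < 0.95 * a_in || A > 1.05 * a_out) {
    stop(sprintf(
      "configured membrane area %.3g m^2 is not within 5%% of the surface area range [%.3g, %.3g] m^2 implied by the radii",
      A, a_in, a_out
    ))
  }
  structure(
    list(
      n_fibers = as.integer(n_fibers), R1 = R1, R2 = R2, R3 = R3,
      h = R2 - R1, L = L, A = A, shell_id = shell_id
    ),
    class = "dialyzer_geometry"
  )
}

#' @export
print.dialyzer_geometry <- function(x, ...) {
  cat("Hollow-fiber dialyzer geometry\n")
  cat(sprintf("  fibers: %d,  L = %.3g m,  area = %.3g m^2\n", x$n_fibers, x$L, x$A))
  cat(sprintf(
    "  R1 = %.4g um, R2 = %.4g um, R3 = %.4g um (membrane h = %.3g um)\n",
    x$R1 * 1e6, x$R2 * 1e6, x$R3 * 1e6, x$h * 1e6
  ))
  invisible(x)
}

#' Working-fluid properties
#'
#' @param density mass density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return object of class `fluid_properties` with derived kinematic
#'   viscosity `nu = viscosity / density`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(
    list(density = density, viscosity = viscosity, nu = viscosity / density),
    class = "fluid_properties"
  )
}

#' Isotonic-saline blood substitute
#'
#' Newtonian aqueous fluid used in the bench characterization and in all
#' simulations: density 1000 kg/m^3, viscosity 0.001 Pa s.
#' @return a [fluid_properties()] object.
#' @export
saline_properties <- function() fluid_properties(1000, 1e-3)

#' Membrane transport properties
#'
#' The porous membrane is characterized by its hydraulic permeability
#' \eqn{L_p} (Starling's law, trans-membrane velocity per unit pressure
#' difference) and the solute reflection coefficient \eqn{\sigma}. The
#' Darcy permeability used by the Brinkman momentum source term is tied to
#' \eqn{L_p} through `k = Lp * viscosity * h`, so the integrated radial
#' Darcy resistance of the membrane reproduces Starling's law exactly.
#' The convective retardation factor is \eqn{\lambda = 1 - \sigma} inside
#' the membrane and 1 elsewhere. For small solutes (urea, creatinine) the
#' default is \eqn{\sigma = 0}: the membrane does not reject them, and
#' solvent drag contributes fully to their transport.
#'
#' @param Lp hydraulic permeability, m/s/Pa.
#' @param sigma reflection coefficient in `[0, 1]`.
#' @param delta_pi trans-membrane osmotic pressure difference, Pa.
#'   Zero by default (protein-free fluids).
#' @param axial_resistance_factor multiplier on the Darcy resistance
#'   applied to the *axial* velocity in the membrane. The large default
#'   forbids an axial short-circuit flow through the porous annulus.
#' @return object of class `membrane_properties`.
#' @export
membrane_properties <- function(Lp, sigma = 0, delta_pi = 0,
                                axial_resistance_factor = 1e4) {
  stopifnot(Lp >= 0, sigma >= 0, sigma <= 1, axial_resistance_factor >= 1)
  structure(
    list(
      Lp = Lp, sigma = sigma, lambda = 1 - sigma, delta_pi = delta_pi,
      axial_resistance_factor = axial_resistance_factor
    ),
    class = "membrane_properties"
  )
}

#' Darcy permeability consistent with a hydraulic permeability
#'
#' @param membrane a [membrane_properties()] object.
#' @param fluid a [fluid_properties()] object.
#' @param geometry a [dialyzer_geometry()] object (supplies membrane
#'   thickness `h`).
#' @return Darcy permeability `k = Lp * viscosity * h` in m^2.
#' @export
darcy_permeability <- function(membrane, fluid, geometry) {
  membrane$Lp * fluid$viscosity * geometry$h
}

#' Solute transport properties
#'
#' @param name solute label.
#' @param D_free diffusivity in the free-flow (blood and dialysate)
#'   regions, m^2/s. The two sides are assumed identical for aqueous
#'   fluids.
#' @param D_membrane effective diffusivity within the membrane, m^2/s;
#'   must not exceed `D_free`.
#' @return object of class `solute_properties`.
#' @export
solute_properties <- function(name, D_free, D_membrane) {
  stopifnot(D_free > 0, D_membrane > 0, D_membrane <= D_free)
  structure(
    list(name = name, D_free = D_free, D_membrane = D_membrane),
    class = "solute_properties"
  )
}

#' Reference small-solute properties
#'
#' Literature diffusivities for the two marker solutes of standard
#' dialysis adequacy work. Free-flow values are aqueous-solution
#' diffusivities; membrane values are effective diffusivities in a
#' high-flux AN69 membrane, of the magnitude recovered by
#' [calibrate_diffusivities()] from the bench data.
#'
#' @return `urea_properties()`, `creatinine_properties()`: a
#'   [solute_properties()] object; `default_solutes()`: a named list of
#'   both.
#' @export
urea_properties <- function() solute_properties("urea", 1.5e-9, 1.3e-10)

#' @rdname urea_properties
#' @export
creatinine_properties <- function() solute_properties("creatinine", 1.3e-9, 1.0e-10)

#' @rdname urea_properties
#' @export
default_solutes <- function() {
  list(urea = urea_properties(), creatinine = creatinine_properties())
}

#' Multiflow M60 dialyzer defaults
#'
#' Geometry of the Multiflow 60 AN69 HF dialyzer (about 4400 fibers of
#' 120 um inner radius, 50 um membrane thickness and 15 cm length; nominal
#' membrane area 0.6 m^2; 33 mm housing bore) together with the
#' isotonic-saline fluid used on both sides of the membrane. The Krogh
#' shell radius of 225 um makes the annular shell cross-section consistent
#' with a uniform fiber packing.
#'
#' @return a list with elements `geometry` ([dialyzer_geometry()]) and
#'   `fluid` ([fluid_properties()]).
#' @examples
#' m60 <- build_default_m60()
#' m60$geometry$h # 50 um
#' @export
build_default_m60 <- function() {
  list(geometry = m60_geometry(), fluid = saline_properties())
}

#' @rdname build_default_m60
#' @export
m60_geometry <- function() {
  dialyzer_geometry(
    n_fibers = 4400,
    R1 = 120e-6, R2 = 170e-6, R3 = 225e-6,
    L = 0.15, A = 0.6, shell_id = 33e-3
  )
}
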