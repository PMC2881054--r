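#' Trans-membrane pressure of an operating case
#'
#' `TMP = (P_b_in + P_b_out)/2 - (P_d_in + P_d_out)/2`, the difference of
#' the mean compartment pressures; positive TMP drives filtration from
#' blood to dialysate.
#'
#' @param case a `dialyzer_cases` data frame (any number of rows).
#' @return TMP in mmHg, one value per row.
#' @export
tmp <- function(case) {
  (case$P_b_in + case$P_b_out) / 2 - (case$P_d_in + case$P_d_out) / 2
}

#' Ultrafiltration coefficient of an operating case
#'
#' `K_UF = 60 * UF / TMP` with UF in ml/min and TMP in mmHg, i.e. the
#' ultrafiltration flow per unit trans-membrane pressure in the
#' conventional ml/hr/mmHg.
#'
#' @param case a `dialyzer_cases` data frame.
#' @return K_UF in ml/hr/mmHg per row; zero UF yields zero.
#' @export
kuf <- function(case) {
  tm <- tmp(case)
  if (any(tm == 0 & case$UF != 0)) {
    stop("K_UF undefined: TMP = 0 with non-zero UF")
  }
  ifelse(case$UF == 0, 0, 60 * case$UF / tm)
}

#' Generalized solute clearance
#'
#' `K = (Q_b_in * C_b_in - Q_b_out * C_b_out) / C_b_in`. At low
#' ultrafiltration (`Q_b_in` close to `Q_b_out`) this reduces to the
#' conventional `Q_b (C_in - C_out)/C_in`; at the large relative
#' ultrafiltration of wearable devices (UF up to 30-50% of blood flow)
#' the flow-weighted form is the meaningful one.
#'
#' @param case one-row `dialyzer_cases` data frame.
#' @param concentrations a `dialyzer_concentrations` table (or a one-row
#'   subset of one).
#' @param solute solute name to look up when `concentrations` has
#'   multiple rows.
#' @return clearance in ml/min.
#' @export
clearance <- function(case, concentrations, solute = NULL) {
  stopifnot(nrow(case) == 1)
  conc <- if (nrow(concentrations) == 1) {
    concentrations
  } else {
    get_concentrations(concentrations, case$case_id, solute)
  }
  if (conc$C_b_in <= 0) stop("clearance undefined: blood inlet concentration is zero")
  (case$Q_b_in * conc$C_b_in - case$Q_b_out * conc$C_b_out) / conc$C_b_in
}

#' Dimensionless numbers of the flow and mass transfer
#'
#' Reynolds, Peclet and Womersley numbers per region. Free-flow regions
#' use the mean axial velocity with reference length `d = 2 R1` (lumen)
#' or `R3 - R2` (shell annulus); Womersley numbers use the half-length
#' `d/2` (so the lumen uses its radius) with angular frequency
#' `2 pi f`: \eqn{\alpha = (d/2)\sqrt{2\pi f/\nu}} for momentum and the
#' same with the solute diffusivity for mass. The membrane uses the
#' ultrafiltration velocity `UF/A`, its thickness `h`, and the membrane
#' diffusivity.
#'
#' @param geometry,fluid device description.
#' @param solute a [solute_properties()] object.
#' @param operating_point list with `Q_b`, `Q_d`, `UF` (ml/min) and `f`
#'   (pulsation frequency, Hz).
#' @return nested list `blood` / `dialysate` / `membrane`, each with
#'   `Re`, `Pe`, `alpha_momentum`, `alpha_mass`.
#' @examples
#' dimensionless_numbers(
#'   m60_geometry(), saline_properties(), urea_properties(),
#'   list(Q_b = 100, Q_d = 100, UF = 20, f = 2)
#' )
#' @export
dimensionless_numbers <- function(geometry, fluid, solute, operating_point) {
  op <- operating_point
  stopifnot(all(c("Q_b", "Q_d", "UF", "f") %in% names(op)), op$f >= 0)
  nu <- fluid$nu
  omega <- 2 * pi * op$f
  nf <- geometry$n_fibers

  one_region <- function(u, d, D) {
    list(
      Re = u * d / nu,
      Pe = u * d / D,
      alpha_momentum = (d / 2) * sqrt(omega / nu),
      alpha_mass = (d / 2) * sqrt(omega / D)
    )
  }
  u_b <- mlmin_to_m3s(op$Q_b) / (nf * pi * geometry$R1^2)
  u_d <- mlmin_to_m3s(op$Q_d) / (nf * pi * (geometry$R3^2 - geometry$R2^2))
  v_m <- mlmin_to_m3s(op$UF) / geometry$A

  list(
    blood = one_region(u_b, 2 * geometry$R1, solute$D_free),
    dialysate = one_region(u_d, geometry$R3 - geometry$R2, solute$D_free),
    membrane = list(
      Re = v_m * geometry$h / nu,
      Pe = v_m * geometry$h / solute$D_membrane,
      alpha_momentum = (geometry$h / 2) * sqrt(omega / nu),
      alpha_mass = (geometry$h / 2) * sqrt(omega / solute$D_membrane)
    )
  )
}

#' Quadratic fit of ultrafiltration against trans-membrane pressure
#'
#' Least-squares second-order polynomial `UF = a TMP^2 + b TMP + c` over
#' a set of operating cases, with the coefficient of determination. Bench
#' UF-TMP characteristics are mildly but systematically nonlinear over
#' wide TMP ranges, and a quadratic captures the whole range well.
#'
#' @param cases a `dialyzer_cases` data frame with at least 4 rows of
#'   distinct TMP.
#' @return object of class `uf_tmp_fit` with fields `a`, `b`, `c`,
#'   `r_squared`, and the fitted model.
#' @export
fit_uf_tmp <- function(cases) {
  tm <- tmp(cases)
  uf <- cases$UF
  keep <- is.finite(tm) & is.finite(uf)
  tm <- tm[keep]; uf <- uf[keep]
  if (length(unique(tm)) < 4) {
    stop("need at least 4 cases with distinct TMP for a quadratic fit")
  }
  fit <- stats::lm(uf ~ tm + I(tm^2))
  co <- stats::coef(fit)
  structure(
    list(
      a = unname(co[3]), b = unname(co[2]), c = unname(co[1]),
      r_squared = summary(fit)$r.squared,
      model = fit, TMP = tm, UF = uf
    ),
    class = "uf_tmp_fit"
  )
}

#' @export
print.uf_tmp_fit <- function(x, ...) {
  cat(sprintf(
    "UF = %.4g TMP^2 + %.4g TMP + %.4g  (R^2 = %.4f, n = %d)\n",
    x$a, x$b, x$c, x$r_squared, length(x$TMP)
  ))
  invisible(x)
}

#' @export
plot.uf_tmp_fit <- function(x, ...) {
  graphics::plot(x$TMP, x$UF,
    xlab = "TMP (mmHg)", ylab = "UF (ml/min)",
    main = "Ultrafiltration vs trans-membrane pressure", ...
  )
  tt <- seq(min(x$TMP), max(x$TMP), length.out = 200)
  graphics::lines(tt, x$a * tt^2 + x$b * tt + x$c, col = "red3", lwd = 2)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Overall convective fraction of the trans-membrane transfer
#'
#' Ratio of the integrated convective (solvent-drag) wall flux to the
#' integrated total wall flux of a solute.
#'
#' @param decomposition a [flux_decomposition()] result.
#' @return dimensionless fraction.
#' @export
convective_fraction <- function(decomposition) {
  if (!is.finite(decomposition$total_transfer) ||
    abs(decomposition$total_transfer) < 1e-300) {
    stop("total trans-membrane transfer is zero; fraction undefined")
  }
  decomposition$convective_fraction
}
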