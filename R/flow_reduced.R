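#' Flow boundary conditions for the counter-current solvers
#'
#' The solvers impose the measured quantities the bench rig controls:
#' inlet flows and outlet pressures of both channels. Blood enters the
#' lumen at `z = 0`; dialysate enters the shell at `z = L` and flows
#' counter-current. Positive trans-membrane velocity is filtration from
#' blood to dialysate.
#'
#' @param Q_b_in blood inlet flow, ml/min (whole device).
#' @param Q_d_in dialysate inlet flow, ml/min (whole device).
#' @param P_b_out blood outlet pressure at `z = L`, mmHg.
#' @param P_d_out dialysate outlet pressure at `z = 0`, mmHg.
#' @return object of class `flow_bc`.
#' @export
flow_bc <- function(Q_b_in, Q_d_in, P_b_out, P_d_out) {
  stopifnot(
    is.finite(Q_b_in), is.finite(Q_d_in),
    is.finite(P_b_out), is.finite(P_d_out),
    Q_b_in >= 0, Q_d_in >= 0
  )
  structure(
    list(
      Q_b_in = Q_b_in, Q_d_in = Q_d_in,
      P_b_out = P_b_out, P_d_out = P_d_out
    ),
    class = "flow_bc"
  )
}

#' @rdname flow_bc
#' @param case a one-row `dialyzer_cases` data frame; its inlet flows and
#'   outlet pressures become the boundary conditions.
#' @export
case_flow_bc <- function(case) {
  flow_bc(
    Q_b_in = case$Q_b_in, Q_d_in = case$Q_d_in,
    P_b_out = case$P_b_out, P_d_out = case$P_d_out
  )
}

# Poiseuille conductance factors q = -(Phi/mu) dP/dz per fiber unit.
# Lumen: circular tube of radius R1.
.phi_lumen <- function(geometry) pi * geometry$R1^4 / 8

# Shell: annulus R2..R3, no slip at R2, zero shear at R3 (symmetry of the
# periodic fiber array). Axial velocity u = (G/mu) f(r) with
# f(r) = (R2^2 - r^2)/4 + (R3^2/2) ln(r/R2) for unit pressure gradient G;
# Phi = int 2 pi r f(r) dr over [R2, R3], in closed form.
.phi_shell <- function(geometry) {
  R2 <- geometry$R2; R3 <- geometry$R3
  t1 <- 2 * pi * ((R2^2 * R3^2 / 8 - R3^4 / 16) - (R2^4 / 8 - R2^4 / 16))
  t2 <- pi * R3^2 * ((R3^2 / 2 * log(R3 / R2) - R3^2 / 4) - (-R2^2 / 4))
  t1 + t2
}

# Radius of the equivalent Starling surface implied by the nominal area
.r_area <- function(geometry) {
  geometry$A / (2 * pi * geometry$L * geometry$n_fibers)
}

#' Reduced 1-D counter-current flow model
#'
#' Axially resolved two-channel model of the Krogh unit: lumen and shell
#' carry fully developed Poiseuille flow with local conductance, coupled
#' by Starling leakage `v_w = Lp * (P_b - P_d - sigma * delta_pi)` through
#' the membrane. The resulting linear two-point boundary-value problem is
#' discretized with midpoint (trapezoidal) coupling and solved directly.
#' This model serves as an independent cross-check and initializer for
#' [solve_flow()] and as the fast inner model of the calibration loops;
#' in the low-Reynolds, long-thin-fiber limit the two agree closely.
#'
#' @param geometry a [dialyzer_geometry()] object.
#' @param fluid a [fluid_properties()] object.
#' @param membrane a [membrane_properties()] object.
#' @param bc a [flow_bc()] object.
#' @param n number of axial grid nodes.
#' @return object of class `reduced_flow`: axial profiles of channel
#'   pressures (mmHg), whole-device channel flows (ml/min; dialysate flow
#'   reported positive toward `z = 0`), trans-membrane velocity `v_w`
#'   (m/s), plus device `UF` (ml/min) and model port pressures.
#' @export
solve_flow_reduced <- function(geometry, fluid, membrane, bc, n = 201) {
  stopifnot(inherits(bc, "flow_bc"), n >= 3)
  nf <- geometry$n_fibers
  mu <- fluid$viscosity
  Rb <- mu / .phi_lumen(geometry)
  Rd <- mu / .phi_shell(geometry)
  w <- 2 * pi * .r_area(geometry) * membrane$Lp # leakage conductance per length
  osm <- membrane$sigma * membrane$delta_pi

  L <- geometry$L
  z <- seq(0, L, length.out = n)
  dz <- L / (n - 1)

  qb_in <- mlmin_to_m3s(bc$Q_b_in) / nf
  qd_in <- mlmin_to_m3s(bc$Q_d_in) / nf
  pb_out <- mmhg_to_pa(bc$P_b_out)
  pd_out <- mmhg_to_pa(bc$P_d_out)

  # unknowns: [P_b, q_b, P_d, q_d] each length n (SI, per fiber);
  # q_d is the signed axial flux (negative: flow toward z = 0)
  iPb <- function(i) i
  iQb <- function(i) n + i
  iPd <- function(i) 2 * n + i
  iQd <- function(i) 3 * n + i

  ii <- jj <- xx <- numeric(0)
  rhs <- numeric(4 * n)
  eq <- 0
  add <- function(r, cols, vals) {
    ii <<- c(ii, rep(r, length(cols))); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }
  im <- seq_len(n - 1)
  # momentum, blood: P_b[i+1] - P_b[i] + dz * Rb * mean(q_b) = 0
  for (i in im) {
    eq <- eq + 1
    add(eq, c(iPb(i + 1), iPb(i), iQb(i), iQb(i + 1)),
        c(1, -1, dz * Rb / 2, dz * Rb / 2))
  }
  # continuity, blood: q_b[i+1] - q_b[i] + dz * w * mean(P_b - P_d) = -dz*w*osm... sign:
  # dq_b/dz = -w * (P_b - P_d - osm)
  for (i in im) {
    eq <- eq + 1
    add(eq, c(iQb(i + 1), iQb(i), iPb(i), iPb(i + 1), iPd(i), iPd(i + 1)),
        c(1, -1, dz * w / 2, dz * w / 2, -dz * w / 2, -dz * w / 2))
    rhs[eq] <- dz * w * osm
  }
  # momentum, dialysate
  for (i in im) {
    eq <- eq + 1
    add(eq, c(iPd(i + 1), iPd(i), iQd(i), iQd(i + 1)),
        c(1, -1, dz * Rd / 2, dz * Rd / 2))
  }
  # continuity, dialysate: dq_d/dz = +w * (P_b - P_d - osm)
  for (i in im) {
    eq <- eq + 1
    add(eq, c(iQd(i + 1), iQd(i), iPb(i), iPb(i + 1), iPd(i), iPd(i + 1)),
        c(1, -1, -dz * w / 2, -dz * w / 2, dz * w / 2, dz * w / 2))
    rhs[eq] <- -dz * w * osm
  }
  # boundary conditions
  eq <- eq + 1; add(eq, iQb(1), 1); rhs[eq] <- qb_in
  eq <- eq + 1; add(eq, iPb(n), 1); rhs[eq] <- pb_out
  eq <- eq + 1; add(eq, iQd(n), 1); rhs[eq] <- -qd_in
  eq <- eq + 1; add(eq, iPd(1), 1); rhs[eq] <- pd_out

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(4 * n, 4 * n))
  sol <- tryCatch(
    .solve_equilibrated(A, rhs),
    error = function(e) stop("reduced flow BVP solve failed: ", conditionMessage(e))
  )
  P_b <- sol[iPb(seq_len(n))]; q_b <- sol[iQb(seq_len(n))]
  P_d <- sol[iPd(seq_len(n))]; q_d <- sol[iQd(seq_len(n))]
  v_w <- membrane$Lp * (P_b - P_d - osm)
  UF <- m3s_to_mlmin((q_b[1] - q_b[n]) * nf)

  structure(
    list(
      z = z,
      P_b = pa_to_mmhg(P_b), P_d = pa_to_mmhg(P_d),
      Q_b = m3s_to_mlmin(q_b * nf), Q_d = m3s_to_mlmin(-q_d * nf),
      v_w = v_w, UF = UF,
      ports = list(
        P_b_in = pa_to_mmhg(P_b[1]), P_b_out = pa_to_mmhg(P_b[n]),
        P_d_in = pa_to_mmhg(P_d[n]), P_d_out = pa_to_mmhg(P_d[1]),
        Q_b_in = m3s_to_mlmin(q_b[1] * nf), Q_b_out = m3s_to_mlmin(q_b[n] * nf),
        Q_d_in = m3s_to_mlmin(-q_d[n] * nf), Q_d_out = m3s_to_mlmin(-q_d[1] * nf)
      ),
      TMP = pa_to_mmhg((P_b[1] + P_b[n]) / 2 - (P_d[1] + P_d[n]) / 2),
      geometry = geometry, membrane = membrane, bc = bc
    ),
    class = "reduced_flow"
  )
}

#' @export
print.reduced_flow <- function(x, ...) {
  cat("Reduced 1-D counter-current flow solution\n")
  cat(sprintf(
    "  UF = %.3f ml/min, model TMP = %.2f mmHg\n  ports: P_b %.1f -> %.1f mmHg, P_d %.1f -> %.1f mmHg\n",
    x$UF, x$TMP, x$ports$P_b_in, x$ports$P_b_out, x$ports$P_d_in, x$ports$P_d_out
  ))
  invisible(x)
}

#' Starling trans-membrane filtration velocity
#'
#' `v = Lp * (P_b - P_d - sigma * delta_pi)`, the local filtration
#' velocity across the membrane (positive from blood to dialysate),
#' referenced to the nominal membrane surface.
#'
#' @param P_b blood-side pressure, mmHg.
#' @param P_d dialysate-side pressure at the same axial position, mmHg.
#' @param membrane a [membrane_properties()] object.
#' @return velocity in m/s (vectorized over the pressures).
#' @examples
#' m <- membrane_properties(Lp = lp_from_kuf(20, 0.6))
#' starling_velocity(50, 0, m) # 20 ml/hr/mmHg * 50 mmHg over 0.6 m^2
#' @export
starling_velocity <- function(P_b, P_d, membrane) {
  membrane$Lp * (mmhg_to_pa(P_b) - mmhg_to_pa(P_d) -
    membrane$sigma * membrane$delta_pi)
}
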