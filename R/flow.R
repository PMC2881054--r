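#' Options for the axisymmetric flow solver
#'
#' @param tol relative residual tolerance on discrete continuity.
#' @param inertia include convective inertia (full Navier-Stokes) through
#'   Picard iteration; the default Stokes-Brinkman treatment is justified
#'   at the lumen Reynolds number of about 0.5 typical of these devices.
#' @param max_outer Picard iteration budget when `inertia = TRUE`.
#' @param picard_tol relative change in velocity at which the Picard loop
#'   is declared converged.
#' @param outer_boundary condition at `r = R3`: `"symmetry"` (zero radial
#'   flow and zero shear; the Krogh-cylinder convention for a periodic
#'   fiber array) or `"no_slip"`.
#' @return a list of class `flow_options`.
#' @export
flow_options <- function(tol = 1e-8, inertia = FALSE, max_outer = 200,
                         picard_tol = 1e-6,
                         outer_boundary = c("symmetry", "no_slip")) {
  outer_boundary <- match.arg(outer_boundary)
  stopifnot(tol > 0, max_outer >= 1)
  structure(
    list(
      tol = tol, inertia = inertia, max_outer = max_outer,
      picard_tol = picard_tol, outer_boundary = outer_boundary
    ),
    class = "flow_options"
  )
}

#' Solve the steady axisymmetric Stokes-Brinkman flow of the Krogh unit
#'
#' Monolithic finite-volume solve of continuity and momentum on a
#' staggered (MAC) grid over lumen, porous membrane and shell. The
#' membrane carries a Darcy resistance `mu/k` on the radial velocity with
#' `k = Lp * mu * h`, so its integrated resistance reproduces Starling's
#' law; axial flow inside the membrane is suppressed by an anisotropically
#' larger axial resistance. Boundary conditions: fully developed velocity
#' profiles at the blood inlet (`z = 0`) and the counter-current dialysate
#' inlet (`z = L`), prescribed pressures at the two outlets, symmetry at
#' the axis and (by default) at `r = R3`. With `inertia = TRUE` the
#' convective terms are added as a Picard source updated from the previous
#' iterate.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param fluid a [fluid_properties()] object.
#' @param membrane a [membrane_properties()] object.
#' @param bc a [flow_bc()] object.
#' @param options a [flow_options()] list.
#' @param geometry the dialyzer geometry; defaults to the one the mesh
#'   was built for.
#' @return object of class `flow_field`: staggered velocity components
#'   (m/s), cell pressures (Pa), trans-membrane velocity profile `v_w(z)`
#'   at the membrane mid-surface, axial whole-device flow profiles `Q_b`,
#'   `Q_d` (ml/min), model port pressures (mmHg), net `UF` (ml/min) and
#'   the continuity residual.
#' @export
solve_flow <- function(mesh, fluid, membrane, bc, options = flow_options(),
                       geometry = mesh$geometry) {
  stopifnot(inherits(mesh, "dialyzer_mesh"), inherits(bc, "flow_bc"))
  if (membrane$Lp < 0) stop("membrane Lp must be non-negative")

  sys <- .flow_system(mesh, fluid, membrane, bc, options, geometry)
  x <- .solve_equilibrated(sys$A, sys$rhs)

  if (options$inertia) {
    rho <- fluid$density
    for (it in seq_len(options$max_outer)) {
      f <- .unpack_flow(x, mesh)
      src <- .inertia_source(f, mesh, rho)
      x_new <- .solve_equilibrated(sys$A, sys$rhs + src)
      delta <- max(abs(x_new - x)) / max(abs(x), 1e-300)
      x <- x_new
      if (delta < options$picard_tol) break
    }
    if (delta >= options$picard_tol) {
      stop(sprintf(
        "flow solver did not converge: Picard change %.3g after %d iterations",
        delta, options$max_outer
      ))
    }
  }

  f <- .unpack_flow(x, mesh)
  .finish_flow(f, mesh, fluid, membrane, bc, options, geometry)
}

# ---- assembly -------------------------------------------------------------

# unknown layout: u (Nz+1 x Nr, z-faces by radial rows), then
# v (Nz x Nr+1, cell columns by radial faces), then P (Nz x Nr)
.flow_index <- function(mesh) {
  Nz <- mesh$Nz; Nr <- mesh$Nr
  nu <- (Nz + 1) * Nr
  nv <- Nz * (Nr + 1)
  list(
    iu = function(i, j) (j - 1) * (Nz + 1) + i + 1, # i in 0..Nz
    iv = function(i, jf) nu + (jf - 1) * Nz + i, # jf in 1..Nr+1
    ip = function(i, j) nu + nv + (j - 1) * Nz + i,
    nu = nu, nv = nv, np = Nz * Nr, ntot = nu + nv + Nz * Nr
  )
}

.flow_system <- function(mesh, fluid, membrane, bc, options, geometry) {
  Nz <- mesh$Nz; Nr <- mesh$Nr
  mu <- fluid$viscosity
  rc <- mesh$rc; rf <- mesh$rf; dr <- mesh$dr
  dz <- mesh$dz[1]
  idx <- .flow_index(mesh)
  iu <- idx$iu; iv <- idx$iv; ip <- idx$ip

  lum <- which(mesh$region == 1L)
  mem <- which(mesh$region == 2L)
  sh <- which(mesh$region == 3L)
  R1 <- geometry$R1; R2 <- geometry$R2

  # Lp = 0 is a sealed membrane: cap the Darcy permeability from below so
  # the drag stays finite while leaving no appreciable leakage
  k_darcy <- max(
    darcy_permeability(membrane, fluid, geometry),
    1e-20 * fluid$viscosity * geometry$h
  )
  beta_r_unit <- mu / k_darcy
  beta_z_unit <- beta_r_unit * membrane$axial_resistance_factor

  qb_in <- mlmin_to_m3s(bc$Q_b_in) / geometry$n_fibers
  qd_in <- mlmin_to_m3s(bc$Q_d_in) / geometry$n_fibers
  pb_out <- mmhg_to_pa(bc$P_b_out)
  pd_out <- mmhg_to_pa(bc$P_d_out)

  # discrete fully developed inlet profiles, normalized to the exact flow
  u_in_lum <- 1 - (rc[lum] / R1)^2
  u_in_lum <- u_in_lum * qb_in / sum(u_in_lum * mesh$A_row[lum])
  fsh <- (R2^2 - rc[sh]^2) / 4 + (geometry$R3^2 / 2) * log(rc[sh] / R2)
  if (options$outer_boundary == "no_slip") {
    # annular Poiseuille with no slip on both walls
    R3 <- geometry$R3
    cln <- (R3^2 - R2^2) / log(R3 / R2)
    fsh <- (R2^2 - rc[sh]^2) / 4 + cln / 4 * log(rc[sh] / R2)
  }
  u_in_sh <- -fsh * qd_in / sum(fsh * mesh$A_row[sh])

  trip_i <- vector("list", 2000); trip_j <- vector("list", 2000)
  trip_x <- vector("list", 2000); nt <- 0
  rhs <- numeric(idx$ntot)
  push <- function(r, c, v) {
    nt <<- nt + 1
    trip_i[[nt]] <<- r; trip_j[[nt]] <<- c; trip_x[[nt]] <<- v
  }

  ## ---- u-momentum / u Dirichlet ----
  # gradient distance at each interior radial face; across the free-flow /
  # membrane interfaces the drag-dominated membrane velocity is flat and
  # near zero, so the shear layer sits on the free side: take the distance
  # from the free cell center to the interface itself
  dist_face <- c(NA, rc[-1] - rc[-Nr], NA) # dist_face[jf], jf = 2..Nr
  dist_face[mesh$face_R1] <- R1 - rc[mesh$face_R1 - 1]
  dist_face[mesh$face_R2] <- rc[mesh$face_R2] - R2
  for (j in seq_len(Nr)) {
    reg <- mesh$region[j]
    # radial diffusion geometry for row j: faces rf[j], rf[j+1]
    a_lo <- if (j > 1) mu * rf[j] / (dist_face[j] * rc[j] * dr[j]) else 0
    a_hi <- if (j < Nr) mu * rf[j + 1] / (dist_face[j + 1] * rc[j] * dr[j]) else 0
    wall_hi <- 0
    if (j == Nr && options$outer_boundary == "no_slip") {
      wall_hi <- mu * rf[j + 1] / ((rf[j + 1] - rc[j]) * rc[j] * dr[j])
    }
    beta <- if (reg == 2L) beta_z_unit else 0

    for (i in 0:Nz) {
      row <- iu(i, j)
      if (i == 0 && reg != 3L) { # blood/membrane Dirichlet at z = 0
        push(row, row, 1)
        rhs[row] <- if (reg == 1L) u_in_lum[match(j, lum)] else 0
        next
      }
      if (i == Nz && reg != 1L) { # dialysate/membrane Dirichlet at z = L
        push(row, row, 1)
        rhs[row] <- if (reg == 3L) u_in_sh[match(j, sh)] else 0
        next
      }
      diag <- -(a_lo + a_hi + wall_hi) - beta
      if (j > 1) push(row, iu(i, j - 1), a_lo)
      if (j < Nr) push(row, iu(i, j + 1), a_hi)
      if (i >= 1 && i <= Nz - 1) {
        # interior face: axial diffusion + pressure gradient between cells
        ax <- mu / dz^2
        push(row, iu(i - 1, j), ax)
        push(row, iu(i + 1, j), ax)
        diag <- diag - 2 * ax
        push(row, ip(i, j), 1 / dz)
        push(row, ip(i + 1, j), -1 / dz)
      } else if (i == Nz) { # lumen outflow face (pressure BC)
        push(row, ip(Nz, j), 2 / dz)
        rhs[row] <- rhs[row] + 2 * pb_out / dz
        ax <- mu / dz^2
        push(row, iu(i - 1, j), ax); diag <- diag - ax
      } else { # i == 0, shell outflow face (pressure BC)
        push(row, ip(1, j), -2 / dz)
        rhs[row] <- rhs[row] - 2 * pd_out / dz
        ax <- mu / dz^2
        push(row, iu(i + 1, j), ax); diag <- diag - ax
      }
      push(row, row, diag)
    }
  }

  ## ---- v-momentum / v Dirichlet ----
  # membrane fraction of the interval (rc[jf-1], rc[jf]) for Darcy drag
  for (jf in seq_len(Nr + 1)) {
    if (jf == 1 || jf == Nr + 1) {
      for (i in seq_len(Nz)) {
        row <- iv(i, jf)
        push(row, row, 1) # v = 0 at axis and at R3
      }
      next
    }
    jlo <- jf - 1; jhi <- jf # adjacent rows
    gap <- rc[jhi] - rc[jlo]
    overlap <- max(0, min(R2, rc[jhi]) - max(R1, rc[jlo]))
    beta <- beta_r_unit * overlap / gap
    # (1/r) d(rv)/dr evaluated in the two adjacent cells, then d/dr between
    c_lo1 <- rf[jlo] / (dr[jlo] * rc[jlo]) # weight of v(jf-1) in D_lo
    c_lo2 <- rf[jf] / (dr[jlo] * rc[jlo]) # weight of v(jf)
    c_hi1 <- rf[jf] / (dr[jhi] * rc[jhi])
    c_hi2 <- rf[jf + 1] / (dr[jhi] * rc[jhi])
    ax <- mu / dz^2
    for (i in seq_len(Nz)) {
      row <- iv(i, jf)
      diag <- -mu * (c_hi1 + c_lo2) / gap - beta
      # jf = 2 lower neighbor is the axis Dirichlet node (v = 0); harmless
      push(row, iv(i, jf - 1), mu * c_lo1 / gap)
      push(row, iv(i, jf + 1), mu * c_hi2 / gap)
      n_ax <- 0
      if (i > 1) { push(row, iv(i - 1, jf), ax); n_ax <- n_ax + 1 }
      if (i < Nz) { push(row, iv(i + 1, jf), ax); n_ax <- n_ax + 1 }
      diag <- diag - n_ax * ax
      push(row, ip(i, jlo), 1 / gap)
      push(row, ip(i, jhi), -1 / gap)
      push(row, row, diag)
    }
  }

  ## ---- continuity per cell ----
  two_pi_dz <- 2 * pi * dz
  for (j in seq_len(Nr)) {
    Az <- mesh$A_row[j]
    for (i in seq_len(Nz)) {
      row <- ip(i, j)
      push(row, iu(i, j), Az)
      push(row, iu(i - 1, j), -Az)
      push(row, iv(i, j + 1), two_pi_dz * rf[j + 1])
      push(row, iv(i, j), -two_pi_dz * rf[j])
    }
  }

  A <- Matrix::sparseMatrix(
    i = unlist(trip_i[seq_len(nt)]),
    j = unlist(trip_j[seq_len(nt)]),
    x = unlist(trip_x[seq_len(nt)]),
    dims = c(idx$ntot, idx$ntot)
  )
  list(A = A, rhs = rhs, idx = idx)
}

.unpack_flow <- function(x, mesh) {
  Nz <- mesh$Nz; Nr <- mesh$Nr
  nu <- (Nz + 1) * Nr; nv <- Nz * (Nr + 1)
  list(
    u = matrix(x[seq_len(nu)], nrow = Nz + 1, ncol = Nr),
    v = matrix(x[nu + seq_len(nv)], nrow = Nz, ncol = Nr + 1),
    P = matrix(x[nu + nv + seq_len(Nz * Nr)], nrow = Nz, ncol = Nr)
  )
}

# Picard convective source -rho (u du/dz + v du/dr) etc., evaluated from
# the previous iterate with upwind axial differences; returned on the
# RHS ordering of the monolithic system.
.inertia_source <- function(f, mesh, rho) {
  Nz <- mesh$Nz; Nr <- mesh$Nr
  idx <- .flow_index(mesh)
  src <- numeric(idx$ntot)
  dz <- mesh$dz[1]
  rc <- mesh$rc; rf <- mesh$rf
  u <- f$u; v <- f$v

  # u nodes (interior axial faces only)
  for (j in seq_len(Nr)) {
    for (i in 1:(Nz - 1)) {
      ui <- u[i + 1, j] # u[i,j] with i in 0..Nz maps to row i+1
      dudz <- if (ui >= 0) (ui - u[i, j]) / dz else (u[i + 2, j] - ui) / dz
      vloc <- (v[i, j] + v[i, j + 1] + v[min(i + 1, Nz), j] + v[min(i + 1, Nz), j + 1]) / 4
      if (j > 1 && j < Nr) {
        dudr <- if (vloc >= 0) {
          (ui - u[i + 1, j - 1]) / (rc[j] - rc[j - 1])
        } else {
          (u[i + 1, j + 1] - ui) / (rc[j + 1] - rc[j])
        }
      } else dudr <- 0
      src[idx$iu(i, j)] <- rho * (ui * dudz + vloc * dudr)
    }
  }
  # v nodes
  for (jf in 2:Nr) {
    for (i in seq_len(Nz)) {
      vi <- v[i, jf]
      uloc <- (u[i, jf - 1] + u[i + 1, jf - 1] + u[i, jf] + u[i + 1, jf]) / 4
      dvdz <- if (i > 1 && i < Nz) {
        if (uloc >= 0) (vi - v[i - 1, jf]) / dz else (v[i + 1, jf] - vi) / dz
      } else 0
      dvdr <- if (vi >= 0) {
        (vi - v[i, jf - 1]) / (rf[jf] - rf[jf - 1])
      } else {
        (v[i, jf + 1] - vi) / (rf[jf + 1] - rf[jf])
      }
      src[idx$iv(i, jf)] <- rho * (uloc * dvdz + vi * dvdr)
    }
  }
  src
}

.finish_flow <- function(f, mesh, fluid, membrane, bc, options, geometry) {
  Nz <- mesh$Nz; Nr <- mesh$Nr
  nf <- geometry$n_fibers
  lum <- which(mesh$region == 1L)
  sh <- which(mesh$region == 3L)
  dz <- mesh$dz[1]

  # continuity residual, relative to the inlet flow per cell scale
  div <- (f$u[2:(Nz + 1), , drop = FALSE] - f$u[1:Nz, , drop = FALSE]) *
    matrix(mesh$A_row, Nz, Nr, byrow = TRUE) +
    2 * pi * dz * (f$v[, 2:(Nr + 1), drop = FALSE] *
      matrix(mesh$rf[-1], Nz, Nr, byrow = TRUE) -
      f$v[, 1:Nr, drop = FALSE] * matrix(mesh$rf[-(Nr + 1)], Nz, Nr, byrow = TRUE))
  qscale <- mlmin_to_m3s(max(bc$Q_b_in, bc$Q_d_in, 1)) / nf
  resid <- max(abs(div)) / qscale

  Q_b <- m3s_to_mlmin(nf * as.numeric(f$u[, lum, drop = FALSE] %*% mesh$A_row[lum]))
  Q_d <- m3s_to_mlmin(-nf * as.numeric(f$u[, sh, drop = FALSE] %*% mesh$A_row[sh]))
  v_w <- f$v[, mesh$face_mid]

  # extrapolate lumen/shell area-weighted mean pressures to the ports
  pmean <- function(cols, i) {
    sum(f$P[i, cols] * mesh$A_row[cols]) / sum(mesh$A_row[cols])
  }
  pb <- vapply(seq_len(Nz), function(i) pmean(lum, i), 0)
  pd <- vapply(seq_len(Nz), function(i) pmean(sh, i), 0)
  extrap0 <- function(p) p[1] + (p[1] - p[2]) / 2
  extrapL <- function(p) p[Nz] + (p[Nz] - p[Nz - 1]) / 2

  structure(
    list(
      mesh = mesh, u = f$u, v = f$v, P = f$P,
      v_w = v_w, z_w = mesh$zc,
      Q_b = Q_b, Q_d = Q_d,
      UF = Q_b[1] - Q_b[Nz + 1],
      P_b_profile = pa_to_mmhg(pb), P_d_profile = pa_to_mmhg(pd),
      ports = list(
        P_b_in = pa_to_mmhg(extrap0(pb)), P_b_out = pa_to_mmhg(extrapL(pb)),
        P_d_in = pa_to_mmhg(extrapL(pd)), P_d_out = pa_to_mmhg(extrap0(pd)),
        Q_b_in = Q_b[1], Q_b_out = Q_b[Nz + 1],
        Q_d_in = Q_d[Nz + 1], Q_d_out = Q_d[1]
      ),
      residual = resid, converged = is.finite(resid) && resid < 1e-6,
      fluid = fluid, membrane = membrane, bc = bc, options = options,
      geometry = geometry
    ),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Axisymmetric Stokes-Brinkman flow field\n")
  cat(sprintf(
    "  mesh %d x %d, continuity residual %.2e\n  UF = %.3f ml/min, Q_b %.2f -> %.2f ml/min, Q_d %.2f <- %.2f ml/min\n",
    x$mesh$Nz, x$mesh$Nr, x$residual, x$UF,
    x$ports$Q_b_in, x$ports$Q_b_out, x$ports$Q_d_out, x$ports$Q_d_in
  ))
  cat(sprintf(
    "  model ports: P_b %.2f -> %.2f mmHg, P_d %.2f -> %.2f mmHg (TMP %.2f)\n",
    x$ports$P_b_in, x$ports$P_b_out, x$ports$P_d_in, x$ports$P_d_out,
    (x$ports$P_b_in + x$ports$P_b_out) / 2 - (x$ports$P_d_in + x$ports$P_d_out) / 2
  ))
  invisible(x)
}

#' Export a flow field as a delimited text grid
#'
#' Writes one row per pressure cell with the cell-center coordinates, the
#' interpolated velocity components and the pressure, in SI units.
#'
#' @param field a [solve_flow()] result.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
export_flow_field <- function(field, path) {
  mesh <- field$mesh
  Nz <- mesh$Nz; Nr <- mesh$Nr
  u_c <- (field$u[1:Nz, , drop = FALSE] + field$u[2:(Nz + 1), , drop = FALSE]) / 2
  v_c <- (field$v[, 1:Nr, drop = FALSE] + field$v[, 2:(Nr + 1), drop = FALSE]) / 2
  out <- data.frame(
    z = rep(mesh$zc, Nr), r = rep(mesh$rc, each = Nz),
    region = rep(c("lumen", "membrane", "shell")[mesh$region], each = Nz),
    u = as.numeric(u_c), v = as.numeric(v_c), P = as.numeric(field$P)
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Net ultrafiltration of a converged flow field
#'
#' Integrates the trans-membrane velocity along the fiber,
#' `UF = n_fibers * integral of 2 pi r v_w(z) dz` at the membrane
#' mid-surface, and cross-checks it against the blood-side flow deficit
#' `Q_b(0) - Q_b(L)`; the two must agree to 0.1% for a converged field.
#' Forward- and backfiltration contributions (positive and negative parts
#' of the integral) are reported separately.
#'
#' @param field a [solve_flow()] result.
#' @param geometry dialyzer geometry; defaults to the field's.
#' @return net UF in ml/min, with attributes `forward`, `backward`
#'   (ml/min) and `check` (the blood-side flow deficit).
#' @export
ultrafiltration_rate <- function(field, geometry = field$geometry) {
  if (!isTRUE(field$converged)) {
    stop("flow field is not converged (residual ", format(field$residual), ")")
  }
  mesh <- field$mesh
  r_mid <- mesh$rf[mesh$face_mid]
  seg <- geometry$n_fibers * 2 * pi * r_mid * field$v_w * mesh$dz
  uf <- m3s_to_mlmin(sum(seg))
  check <- field$Q_b[1] - field$Q_b[length(field$Q_b)]
  scale <- max(abs(field$ports$Q_b_in), abs(uf), 1e-6)
  if (abs(uf - check) > 1e-3 * scale) {
    warning(sprintf(
      "membrane-integral UF (%.4f) and blood-side deficit (%.4f) differ by more than 0.1%%",
      uf, check
    ))
  }
  structure(uf,
    forward = m3s_to_mlmin(sum(pmax(seg, 0))),
    backward = m3s_to_mlmin(sum(pmin(seg, 0))),
    check = check
  )
}
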