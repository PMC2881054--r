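# shared fixtures: device, fluid, and a small mesh that keeps unit tests
# quick while staying within a few percent of the production resolution
m60 <- m60_geometry()
saline <- saline_properties()

small_mesh <- function(Nz = 80, nr = c(14, 6, 10)) {
  build_mesh(m60, Nz = Nz, nr_lumen = nr[1], nr_membrane = nr[2], nr_shell = nr[3])
}

# Poiseuille pressure drop of the lumen at device flow Q (ml/min), mmHg
poiseuille_drop <- function(Q, geometry = m60, fluid = saline) {
  pa_to_mmhg(
    8 * fluid$viscosity * geometry$L * mlmin_to_m3s(Q) /
      geometry$n_fibers / (pi * geometry$R1^4)
  )
}

# max-norm error of the pure-diffusion solute solve against the annulus
# closed form, with Dirichlet rings pinned at fixed physical radii
annulus_error <- function(nr, r_pin = c(60e-6, 215e-6),
                          D_free = 1.5e-9, D_mem = 1.3e-10) {
  msh <- build_mesh(m60, Nz = 8, nr_lumen = nr[1], nr_membrane = nr[2],
    nr_shell = nr[3])
  f <- solve_flow(msh, saline, membrane_properties(Lp = 0), flow_bc(0, 0, 5, 5))
  sp <- solute_properties("tracer", D_free, D_mem)
  cf <- solve_solute(f, sp, membrane_properties(Lp = 0), solute_bc(0, 0),
    radial_dirichlet = c(1, 0), dirichlet_radii = r_pin)
  r_in_eff <- max(msh$rc[msh$rc <= r_pin[1]])
  r_out_eff <- min(msh$rc[msh$rc >= r_pin[2]])
  free <- msh$rc > r_in_eff & msh$rc < r_out_eff
  exact <- annulus_profile(msh$rc[free], r_in_eff, r_out_eff, 1, 0,
    m60, D_free, D_mem)
  max(abs(cf$C[4, free] - exact))
}

# closed-form steady diffusion across the three-layer annulus with fixed
# concentrations at radii r_in and r_out: C = a_i + b_i ln r per layer,
# flux per unit length W = 2 pi dC / sum(ln(r_hi/r_lo)/D_layer)
annulus_profile <- function(r, r_in, r_out, C_in, C_out, geometry, D_free, D_mem) {
  edges <- c(r_in, geometry$R1, geometry$R2, r_out)
  D <- c(D_free, D_mem, D_free)
  res <- log(edges[-1] / edges[-4]) / D
  Wtot <- (C_in - C_out) / sum(res) # flux scale (per 2 pi)
  # concentration at layer boundaries
  Cb <- C_in - cumsum(c(0, res)) * Wtot
  vapply(r, function(ri) {
    k <- findInterval(ri, edges, rightmost.closed = TRUE)
    k <- min(max(k, 1), 3)
    Cb[k] - Wtot * log(ri / edges[k]) / D[k]
  }, 0)
}
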