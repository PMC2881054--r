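#' Build a structured mesh for the Krogh-cylinder unit
#'
#' Tensor-product finite-volume mesh over the axisymmetric three-region
#' domain: fiber lumen (`0..R1`), porous membrane (`R1..R2`) and dialysate
#' shell (`R2..R3`), by the fiber length `0..L`. Radial faces cluster
#' toward the membrane edges (where velocity and concentration gradients
#' are steepest) through a fixed tanh stretching map evaluated on a
#' uniform parameter grid, so refined meshes nest the coarse faces
#' exactly. The region interfaces at `R1` and `R2` always coincide with
#' faces, and the membrane has an even cell count so a face lies on the
#' membrane mid-surface (where trans-membrane fluxes are reported).
#'
#' @param geometry a [dialyzer_geometry()] object.
#' @param Nz axial cell count.
#' @param nr_lumen,nr_membrane,nr_shell radial cell counts per region;
#'   `nr_membrane` must be even.
#' @param beta stretching strength of the tanh clustering map (0 =
#'   uniform).
#' @return object of class `dialyzer_mesh`: face/center coordinates,
#'   per-row region tags and precomputed face areas.
#' @export
build_mesh <- function(geometry, Nz = 200, nr_lumen = 24, nr_membrane = 8,
                       nr_shell = 16, beta = 1.5) {
  if (Nz < 4) stop("Nz = ", Nz, " is insufficient axial resolution (need >= 4)")
  if (nr_lumen < 3 || nr_membrane < 2 || nr_shell < 3) {
    stop("radial resolution too small for the three regions (need >= 3/2/3 cells)")
  }
  if (nr_membrane %% 2 != 0) stop("nr_membrane must be even")

  # clustering maps on [0,1]; xi is uniform so refinement nests faces
  at_end <- function(xi, b) if (b > 0) 1 - tanh(b * (1 - xi)) / tanh(b) else xi
  at_start <- function(xi, b) if (b > 0) tanh(b * xi) / tanh(b) else xi

  R1 <- geometry$R1; R2 <- geometry$R2; R3 <- geometry$R3
  rf_lum <- R1 * at_end(seq(0, 1, length.out = nr_lumen + 1), beta)
  rf_mem <- R1 + (R2 - R1) * seq(0, 1, length.out = nr_membrane + 1)
  rf_sh <- R2 + (R3 - R2) * at_start(seq(0, 1, length.out = nr_shell + 1), beta)
  rf <- c(rf_lum, rf_mem[-1], rf_sh[-1])
  zf <- seq(0, geometry$L, length.out = Nz + 1)

  Nr <- nr_lumen + nr_membrane + nr_shell
  region <- rep(c(1L, 2L, 3L), c(nr_lumen, nr_membrane, nr_shell))
  structure(
    list(
      Nz = as.integer(Nz), Nr = as.integer(Nr),
      nr = c(lumen = nr_lumen, membrane = nr_membrane, shell = nr_shell),
      zf = zf, zc = (zf[-1] + zf[-(Nz + 1)]) / 2, dz = diff(zf),
      rf = rf, rc = (rf[-1] + rf[-(Nr + 1)]) / 2, dr = diff(rf),
      region = region,
      # 1-based indices into rf: rf[face_R1] == R1 etc.
      face_R1 = nr_lumen + 1L,
      face_R2 = nr_lumen + nr_membrane + 1L,
      face_mid = nr_lumen + nr_membrane %/% 2 + 1L,
      # annular cross-section area of each radial row, and face radii
      A_row = pi * (rf[-1]^2 - rf[-(Nr + 1)]^2),
      geometry = geometry
    ),
    class = "dialyzer_mesh"
  )
}

#' @export
print.dialyzer_mesh <- function(x, ...) {
  cat(sprintf(
    "Krogh-unit mesh: %d x %d cells (lumen %d, membrane %d, shell %d radial rows)\n",
    x$Nz, x$Nr, x$nr[1], x$nr[2], x$nr[3]
  ))
  invisible(x)
}

#' @export
format.dialyzer_mesh <- function(x, ...) {
  sprintf("<dialyzer_mesh %d x %d>", x$Nz, x$Nr)
}
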