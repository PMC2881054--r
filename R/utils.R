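# Solve A x = b after row/column max-equilibration. The flow systems mix
# pressures (Pa) with per-fiber fluxes (m^3/s), spanning ~20 orders of
# magnitude in coefficient size; equilibration keeps the sparse LU well
# conditioned. One step of iterative refinement tightens the residual.
.solve_equilibrated <- function(A, b) {
  n <- nrow(A)
  T <- as(A, "TsparseMatrix")
  ax <- abs(T@x)
  rmax <- numeric(n)
  agg <- vapply(split(ax, T@i), max, 0)
  rmax[as.integer(names(agg)) + 1L] <- agg
  rmax[rmax == 0] <- 1
  ax2 <- ax / rmax[T@i + 1L]
  cmax <- numeric(n)
  agg <- vapply(split(ax2, T@j), max, 0)
  cmax[as.integer(names(agg)) + 1L] <- agg
  cmax[cmax == 0] <- 1
  As <- Matrix::sparseMatrix(
    i = T@i + 1L, j = T@j + 1L,
    x = T@x / (rmax[T@i + 1L] * cmax[T@j + 1L]), dims = c(n, n)
  )
  bs <- b / rmax
  lu <- Matrix::lu(As)
  y <- Matrix::solve(lu, bs)
  # one refinement step in the scaled system
  r <- bs - as.numeric(As %*% y)
  y <- as.numeric(y) + as.numeric(Matrix::solve(lu, r))
  y / cmax
}

# zero-intercept and with-intercept coefficient of determination
.r_squared <- function(y, yhat, intercept = TRUE) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  1 - ss_res / ss_tot
}

# linear interpolation helper clamped to range ends
.interp <- function(x, xp, yp) {
  stats::approx(xp, yp, xout = pmin(pmax(x, min(xp)), max(xp)), rule = 2)$y
}
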