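test_that("impermeable membrane decouples the channels into Poiseuille flow", {
  m0 <- membrane_properties(Lp = 0)
  bc <- flow_bc(52, 34, 27, 2)
  r <- solve_flow_reduced(m60, saline, m0, bc)
  expect_equal(r$UF, 0, tolerance = 1e-10)
  expect_equal(max(abs(r$Q_b - 52)), 0, tolerance = 1e-9)
  expect_equal(max(abs(r$Q_d - 34)), 0, tolerance = 1e-9)
  # linear pressure profiles with the closed-form lumen drop
  expect_equal(r$ports$P_b_in - r$ports$P_b_out, poiseuille_drop(52),
    tolerance = 1e-8)
  expect_equal(max(abs(diff(diff(r$P_b)))), 0, tolerance = 1e-10)
})

test_that("shell conductance factor matches numerical quadrature", {
  # independent oracle: integrate the annular velocity profile directly
  R2 <- m60$R2; R3 <- m60$R3
  f <- function(r) (R2^2 - r^2) / 4 + (R3^2 / 2) * log(r / R2)
  phi_num <- stats::integrate(function(r) 2 * pi * r * f(r), R2, R3,
    rel.tol = 1e-12)$value
  expect_equal(hfdialyzer:::.phi_shell(m60), phi_num, tolerance = 1e-9)
})

test_that("swapping the outlet pressures negates the leakage field", {
  m <- membrane_properties(Lp = 5e-11)
  a <- solve_flow_reduced(m60, saline, m, flow_bc(0, 0, 30, -10))
  b <- solve_flow_reduced(m60, saline, m, flow_bc(0, 0, -10, 30))
  # by linearity: equal outlet pressures give zero leakage, so the
  # response to (p, q) is exactly the negative of the response to (q, p)
  expect_equal(a$v_w, -b$v_w, tolerance = 1e-8)
  expect_equal(a$UF, -b$UF, tolerance = 1e-8)
})

test_that("reduced model reproduces measured WAK/roller operating points", {
  cases <- bench_cases()
  for (id in c("23", "32")) {
    cs <- get_case(cases, id)
    lp <- lp_from_kuf(60 * cs$UF / tmp(cs), m60$A)
    r <- solve_flow_reduced(m60, saline, membrane_properties(Lp = lp),
      case_flow_bc(cs))
    # UF within 10% of measured when Lp comes straight from K_UF/A
    expect_equal(r$UF, cs$UF, tolerance = 0.1)
    # model TMP within 2.5 mmHg of the four-port estimate
    expect_lt(abs(r$TMP - tmp(cs)), 2.5)
  }
})

test_that("computed UF is linear in Lp across two decades (zero intercept)", {
  bc <- flow_bc(50, 38, 21, -31)
  lps <- 10^seq(-12, -10, length.out = 9)
  ufs <- vapply(lps, function(l) {
    solve_flow_reduced(m60, saline, membrane_properties(Lp = l), bc)$UF
  }, 0)
  slope <- sum(ufs * lps) / sum(lps^2)
  r2 <- 1 - sum((ufs - slope * lps)^2) / sum(ufs^2)
  expect_gt(r2, 0.999)
})
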