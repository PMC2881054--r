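test_that("sealed membrane reproduces the Poiseuille closed form within 1%", {
  msh <- small_mesh(Nz = 80, nr = c(16, 6, 10))
  f <- solve_flow(msh, saline, membrane_properties(Lp = 0), flow_bc(52, 34, 27, 2))
  expect_true(f$converged)
  expect_lt(abs(f$UF), 1e-6)
  drop <- f$ports$P_b_in - f$ports$P_b_out
  expect_equal(drop, poiseuille_drop(52), tolerance = 0.01)
})

test_that("Starling velocity follows Lp (P_b - P_d - sigma dpi)", {
  m <- membrane_properties(Lp = lp_from_kuf(20, 0.6))
  # 20 ml/hr/mmHg at 50 mmHg over 0.6 m^2 -> 1000 ml/hr -> 4.63e-7 m/s
  expect_equal(starling_velocity(50, 0, m), 4.6296e-7, tolerance = 1e-4)
  expect_equal(starling_velocity(25, 25, m), 0)
  m1 <- membrane_properties(Lp = 1e-10, sigma = 1, delta_pi = mmhg_to_pa(50))
  expect_equal(starling_velocity(50, 0, m1), 0, tolerance = 1e-15)
})

test_that("zero driving pressure difference yields no filtration", {
  msh <- small_mesh(Nz = 40, nr = c(10, 4, 8))
  f <- solve_flow(msh, saline, membrane_properties(Lp = 5e-11), flow_bc(0, 0, 10, 10))
  expect_lt(max(abs(f$v_w)), 1e-12)
  expect_lt(abs(f$UF), 1e-9)
})

test_that("converged fields conserve volume globally and at the membrane", {
  msh <- small_mesh()
  cs <- get_case(bench_cases(), 32)
  f <- solve_flow(msh, saline, membrane_properties(Lp = 6.85e-11), case_flow_bc(cs))
  expect_true(f$converged)
  imb <- abs(f$ports$Q_b_in - f$ports$Q_b_out - f$UF) / f$ports$Q_b_in
  expect_lt(imb, 1e-3)
  uf <- ultrafiltration_rate(f)
  expect_equal(as.numeric(uf), attr(uf, "check"), tolerance = 1e-3)
  expect_equal(attr(uf, "forward") + attr(uf, "backward"), as.numeric(uf),
    tolerance = 1e-9)
})

test_that("trans-membrane flow integral splits forward and backfiltration", {
  # antisymmetric v_w about mid-length must integrate to zero net flow
  msh <- small_mesh(Nz = 40, nr = c(10, 4, 8))
  f <- solve_flow(msh, saline, membrane_properties(Lp = 0), flow_bc(10, 10, 5, 5))
  f$v_w <- 1e-7 * sin(2 * pi * (msh$zc / m60$L - 0.5)) # odd about L/2
  f$Q_b <- rep(f$Q_b[1], length(f$Q_b)) # consistent zero net deficit
  uf <- ultrafiltration_rate(f)
  expect_equal(as.numeric(uf), 0, tolerance = 1e-10)
  expect_gt(attr(uf, "forward"), 0)
  expect_lt(attr(uf, "backward"), 0)
  expect_equal(attr(uf, "forward"), -attr(uf, "backward"), tolerance = 1e-9)
})

test_that("2-D solver and 1-D reduced model agree on UF within 5%", {
  msh <- small_mesh()
  for (id in c("23", "31", "32")) {
    cs <- get_case(bench_cases(), id)
    cal <- calibrate_lp(cs)
    m <- membrane_properties(Lp = cal$estimate)
    f2 <- solve_flow(msh, saline, m, case_flow_bc(cs))
    r1 <- solve_flow_reduced(m60, saline, m, case_flow_bc(cs))
    expect_equal(f2$UF, r1$UF, tolerance = 0.05)
  }
})

test_that("WAK suction roughly doubles the TMP of the roller operating point", {
  cases <- bench_cases()
  c23 <- get_case(cases, 23); c32 <- get_case(cases, 32)
  # measured-port contrast
  expect_equal(tmp(c32) / tmp(c23), 1.85, tolerance = 0.03)
  # model contrast at calibrated permeabilities: about twofold
  m23 <- membrane_properties(Lp = calibrate_lp(c23)$estimate)
  m32 <- membrane_properties(Lp = calibrate_lp(c32)$estimate)
  r23 <- solve_flow_reduced(m60, saline, m23, case_flow_bc(c23))
  r32 <- solve_flow_reduced(m60, saline, m32, case_flow_bc(c32))
  expect_gt(r32$TMP / r23$TMP, 1.75)
  expect_lt(r32$TMP / r23$TMP, 2.25)
})

test_that("flow fields export as a readable delimited grid", {
  msh <- small_mesh(Nz = 20, nr = c(6, 2, 4))
  f <- solve_flow(msh, saline, membrane_properties(Lp = 5e-11), flow_bc(20, 20, 10, 0))
  p <- tempfile(fileext = ".csv")
  export_flow_field(f, p)
  g <- utils::read.csv(p)
  expect_equal(nrow(g), msh$Nz * msh$Nr)
  expect_setequal(names(g), c("z", "r", "region", "u", "v", "P"))
  expect_true(all(g$region %in% c("lumen", "membrane", "shell")))
})

test_that("optional inertia changes the creeping-flow solution only marginally", {
  msh <- small_mesh(Nz = 40, nr = c(10, 4, 8))
  bc <- flow_bc(52, 34, 27, 2)
  m <- membrane_properties(Lp = 5e-11)
  f_stokes <- solve_flow(msh, saline, m, bc)
  f_ns <- solve_flow(msh, saline, m, bc, flow_options(inertia = TRUE, max_outer = 30))
  expect_equal(f_ns$UF, f_stokes$UF, tolerance = 0.02)
})
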