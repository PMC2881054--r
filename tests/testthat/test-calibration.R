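test_that("noise-free synthetic cases return the true permeability", {
  truth <- ground_truth(Lp = 5e-11)
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 3)
  g <- generate_case(truth, list(Q_b_in = 50, Q_d_in = 38, P_b_out = 21,
    P_d_out = -31), nz)
  cal <- calibrate_lp(g$case)
  expect_equal(cal$estimate, 5e-11, tolerance = 0.005)
  expect_lt(abs(cal$residual), 0.05)
  expect_true(cal$estimate >= cal$bracket[1] && cal$estimate <= cal$bracket[2])
})

test_that("zero measured UF drives the permeability to the sealed limit", {
  cs <- get_case(bench_cases(), 50) # UF = 0 at TMP = 45 mmHg
  cal <- calibrate_lp(cs)
  expect_equal(cal$estimate, cal$bracket[1])
  expect_lt(abs(cal$residual), 0.05)
})

test_that("UF opposing the model TMP has no Starling-consistent solution", {
  cs <- get_case(bench_cases(), 41) # porcine: UF = -2 at positive TMP
  expect_error(calibrate_lp(cs), "achievable range")
})

test_that("calibrated permeability is consistent with K_UF via the device law", {
  cs <- get_case(bench_cases(), 31)
  cal <- calibrate_lp(cs)
  expect_equal(kuf_from_lp(cal$estimate, m60$A), 23, tolerance = 0.15)
})

test_that("full-engine calibration reproduces measured UF with the 2-D solver", {
  cs <- get_case(bench_cases(), 32)
  msh <- small_mesh()
  cal <- calibrate_lp(cs, engine = "full", mesh = msh)
  f <- solve_flow(msh, saline, membrane_properties(Lp = cal$estimate),
    case_flow_bc(cs))
  expect_equal(f$UF, cs$UF, tolerance = 0.05 / cs$UF)
})

test_that("diffusivity fit recovers the transfer physics of synthetic data", {
  truth <- ground_truth(
    Lp = 5e-11,
    solutes = list(urea = solute_properties("urea", 1.5e-9, 1.3e-10))
  )
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 3)
  g <- generate_case(truth, list(Q_b_in = 50, Q_d_in = 38, P_b_out = 21,
    P_d_out = -31), nz, solutes = TRUE, inlet_concentrations = c(urea = 100))
  cal <- calibrate_lp(g$case)
  fit <- suppressWarnings(
    calibrate_diffusivities(g$case, g$concentrations, Lp = cal$estimate)
  )
  # the outlet concentrations (the identifiable quantity) are recovered
  expect_equal(unname(fit$model_outlets[1]), g$concentrations$C_b_out,
    tolerance = 0.02)
  expect_equal(unname(fit$model_outlets[2]), g$concentrations$C_d_out,
    tolerance = 0.02)
  # conservation ties the outlets to a single transfer scalar, so the
  # individual diffusivities trade off along a ridge; the membrane
  # leg dominates the series resistance and is recovered loosely
  expect_equal(fit$solute$D_membrane, 1.3e-10, tolerance = 0.35)
})

test_that("no-transfer data push the membrane diffusivity to the lower edge", {
  truth <- ground_truth(Lp = 5e-11)
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 3)
  g <- generate_case(truth, list(Q_b_in = 50, Q_d_in = 38, P_b_out = 21,
    P_d_out = -31), nz)
  conc <- data.frame(case_id = g$case$case_id, solute = "urea",
    C_b_in = 100, C_b_out = 100, C_d_in = 0, C_d_out = 0,
    stringsAsFactors = FALSE)
  cal <- calibrate_lp(g$case)
  expect_warning(
    fit <- calibrate_diffusivities(g$case, conc, Lp = cal$estimate),
    "bracket edge"
  )
  expect_equal(fit$solute$D_membrane, fit$brackets$membrane[1], tolerance = 0.05)
})

test_that("recovery studies are deterministic under a fixed seed", {
  truth <- ground_truth(Lp = 5e-11)
  a <- recovery_study(truth, n_cases = 6, noise = noise_model(seed = 42))
  b <- recovery_study(truth, n_cases = 6, noise = noise_model(seed = 42))
  expect_identical(a$table, b$table)
  expect_identical(a$rmse, b$rmse)
})

test_that("noise-free recovery has vanishing bias", {
  truth <- ground_truth(Lp = 5e-11)
  rs <- recovery_study(truth, n_cases = 6,
    noise = noise_model(0, 0, 0, quantize = FALSE, seed = 5))
  expect_lt(abs(rs$bias), 0.005)
  expect_lt(rs$rmse, 0.005)
})
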