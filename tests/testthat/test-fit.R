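# a compact bench subset keeps the fitted-model tests quick
fit_cases <- function() {
  cases <- bench_cases()
  cases[as.character(cases$case_id) %in% c("21", "22", "23", "24", "25", "32"), ]
}

test_that("dialyzer_fit calibrates cases and fits the reference solute", {
  fit <- suppressWarnings(
    dialyzer_fit(fit_cases(), bench_concentrations(), solutes = "urea")
  )
  expect_s3_class(fit, "dialyzer_fit")
  cal <- fit$calibration
  expect_true(all(cal$status == "ok"))
  # calibrated cases reproduce their own UF to tolerance by construction
  expect_true(all(abs(cal$residual) <= fit$tol))
  # coefficient access
  co <- coef(fit)
  expect_true("Lp.23" %in% names(co))
  expect_true("urea.D_free" %in% names(co))
  expect_equal(unname(co["urea.D_membrane"]), 1.3e-10, tolerance = 0.25)
  r <- residuals(fit)
  expect_equal(length(r), nrow(cal))
  # printed summaries render
  expect_output(print(fit), "dialyzer model fit")
  expect_output(print(summary(fit)), "Diffusivity fits")
})

test_that("predict runs the forward model and reports transport metrics", {
  fit <- suppressWarnings(
    dialyzer_fit(fit_cases(), bench_concentrations(), solutes = "urea")
  )
  msh <- small_mesh(Nz = 100, nr = c(16, 6, 12))
  pr <- predict(fit, case_ids = "23", mesh = msh)
  expect_equal(pr$UF, 6, tolerance = 0.05)
  expect_equal(pr$clearance, 30, tolerance = 2 / 30)
  expect_true(pr$convective_fraction > 0 && pr$convective_fraction < 1)
  expect_error(predict(fit, case_ids = "62"), "not in the fit")
})

test_that("plot and simulate methods operate on the fitted object", {
  fit <- suppressWarnings(
    dialyzer_fit(fit_cases(), bench_concentrations(), solutes = "urea")
  )
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  plot(fit, which = "uf_tmp")
  plot(fit, which = "kuf_lp")
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)

  sim <- simulate(fit, n_cases = 3)
  expect_equal(nrow(sim$cases), 3)
  # the simulated truth uses the fitted permeability
  expect_equal(sim$truth_parameters$value[sim$truth_parameters$parameter == "Lp"],
    unname(stats::median(fit$calibration$Lp, na.rm = TRUE)))
})
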