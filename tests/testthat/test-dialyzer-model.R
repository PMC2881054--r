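test_that("M60 defaults carry the documented geometry", {
  d <- build_default_m60()
  g <- d$geometry
  expect_equal(g$h, g$R2 - g$R1)
  expect_equal(g$h, 50e-6)
  expect_equal(g$A, 0.6)
  expect_equal(g$n_fibers, 4400L)
  expect_equal(g$L, 0.15)
  # the nominal area exceeds the inner-surface area (0.497 m^2) but lies
  # within the inner..outer surface band the validator accepts
  expect_equal(2 * pi * g$R1 * g$L * g$n_fibers, 0.4976, tolerance = 1e-3)
  expect_lt(2 * pi * g$R1 * g$L * g$n_fibers, g$A)
  expect_gt(2 * pi * g$R2 * g$L * g$n_fibers, g$A)
  expect_equal(d$fluid$nu, 1e-6)
})

test_that("geometry validation rejects inconsistent inputs", {
  expect_error(
    dialyzer_geometry(4400, 170e-6, 120e-6, 225e-6, 0.15, 0.6),
    "R1 < R2"
  )
  expect_error(
    dialyzer_geometry(4400, 120e-6, 170e-6, 225e-6, 0.15, 6.0),
    "not within 5%"
  )
  expect_error(membrane_properties(Lp = -1), "Lp")
  expect_error(solute_properties("x", 1e-9, 2e-9), "D_membrane")
})

test_that("the packaged case table loads, validates and re-serializes byte-identically", {
  cases <- bench_cases()
  expect_s3_class(cases, "dialyzer_cases")
  expect_equal(nrow(cases), 29)
  expect_true(all(cases$pump_type %in% c("WAK", "roller_centrifugal")))
  c23 <- get_case(cases, 23)
  expect_equal(c23$Q_b_in, 52)
  expect_equal(c23$P_b_in, 32)

  src <- system.file("extdata", "bench_cases.csv", package = "hfdialyzer")
  out <- tempfile(fileext = ".csv")
  write_case_table(cases, out)
  expect_identical(readBin(out, "raw", file.size(out)),
    readBin(src, "raw", file.size(src)))
})

test_that("case-table schema violations are reported precisely", {
  cases <- bench_cases()
  f <- tempfile(fileext = ".csv")

  # missing column
  x <- as.data.frame(cases); x$P_b_in <- NULL
  utils::write.csv(x, f, row.names = FALSE)
  expect_error(load_case_table(f), "P_b_in")

  # non-numeric cell names the row
  x <- as.data.frame(cases); x$Q_b_in[3] <- "forty"
  utils::write.csv(x, f, row.names = FALSE, quote = FALSE)
  expect_error(load_case_table(f), "forty")

  # empty table: warning, zero rows
  utils::write.csv(as.data.frame(cases)[0, ], f, row.names = FALSE)
  expect_warning(empty <- load_case_table(f), "no rows")
  expect_equal(nrow(empty), 0)
})

test_that("mass-balance diagnostic reproduces the table rounding residuals", {
  cases <- bench_cases()
  rep <- mass_balance_report(cases)
  get <- function(id) rep$imbalance[rep$case_id == id]
  expect_equal(get("32"), -1) # 50 - 34 - 17
  expect_equal(get("23"), +1) # 52 - 45 - 6
  # an exactly balanced synthetic row
  x <- get_case(cases, 23)
  x$Q_b_out <- x$Q_b_in - x$UF
  expect_equal(mass_balance_report(x)$imbalance, 0)
})

test_that("concentration table loads and joins per case and solute", {
  conc <- bench_concentrations()
  expect_s3_class(conc, "dialyzer_concentrations")
  row <- get_concentrations(conc, 23, "urea")
  expect_equal(row$C_b_out, 56)
  expect_equal(row$C_d_out, 88)
  expect_equal(row$C_d_in, 0)
  expect_error(get_concentrations(conc, 99, "urea"), "no concentrations")
})
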