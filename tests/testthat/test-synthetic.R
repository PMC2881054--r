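truth <- ground_truth(Lp = 5e-11)
op <- list(Q_b_in = 50, Q_d_in = 38, P_b_out = 21, P_d_out = -31)

test_that("generation is deterministic under a fixed seed", {
  a <- generate_case(truth, op, noise_model(seed = 9))
  b <- generate_case(truth, op, noise_model(seed = 9))
  expect_identical(a$case, b$case)
  ta <- generate_table(truth, 4, noise_model(seed = 9))
  tb <- generate_table(truth, 4, noise_model(seed = 9))
  expect_identical(ta$cases, tb$cases)
})

test_that("noise-free cases satisfy exact blood-side volume conservation", {
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 1)
  g <- generate_case(truth, op, nz)
  expect_equal(g$case$Q_b_in - g$case$Q_b_out, g$case$UF, tolerance = 1e-10)
  expect_identical(g$case$Q_b_in, g$truth_case$Q_b_in)
  # out-of-envelope operating points are rejected
  expect_error(
    generate_case(truth, list(Q_b_in = 500, Q_d_in = 38, P_b_out = 21,
      P_d_out = -31), nz),
    "envelope"
  )
})

test_that("emitted flow noise matches the configured fraction", {
  qs <- vapply(1:200, function(s) {
    generate_case(truth, op, noise_model(seed = s))$case$Q_b_in
  }, 0)
  cv <- stats::sd(qs) / mean(qs)
  expect_equal(cv, 0.085, tolerance = 0.15)
})

test_that("generated tables round-trip through the file dialect", {
  dir <- tempfile()
  tab <- generate_table(truth, 5, noise_model(seed = 4), solutes = TRUE,
    inlet_concentrations = c(urea = 118, creatinine = 4.5), dir = dir)
  expect_equal(nrow(tab$cases), 5)
  reread <- load_case_table(tab$paths$cases)
  expect_equal(as.data.frame(reread), as.data.frame(tab$cases),
    tolerance = 1e-12)
  # truth sidecar re-reads bit-identically
  tp <- utils::read.csv(tab$paths$truth, stringsAsFactors = FALSE)
  expect_identical(as.numeric(tp$value), tab$truth_parameters$value)
  # concentrations present for both solutes
  expect_equal(nrow(tab$concentrations), 10)
  expect_true(all(tab$concentrations$C_d_in == 0))
})

test_that("the envelope spans the pulsatile-pump TMP range", {
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 21)
  tab <- generate_table(truth, 24, nz)
  tm <- tmp(tab$truth_cases)
  expect_lt(min(tm), 35)
  expect_gt(max(tm), 50)
  expect_gt(min(tm), 20)
  expect_lt(max(tm), 70)
})

test_that("the generator itself obeys Starling: UF through the origin in TMP", {
  nz <- noise_model(0, 0, 0, quantize = FALSE, seed = 13)
  tab <- generate_table(truth, 16, nz)
  tm <- tmp(tab$truth_cases)
  uf <- tab$truth_cases$UF
  slope <- sum(uf * tm) / sum(tm^2)
  r2 <- 1 - sum((uf - slope * tm)^2) / sum(uf^2)
  expect_gt(r2, 0.999)
  # slope equals Lp * A in bench units
  expect_equal(slope, kuf_from_lp(truth$Lp, m60$A) / 60, tolerance = 0.02)
})
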