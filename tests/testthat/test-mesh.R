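test_that("default mesh resolves the three regions with interfaces on faces", {
  msh <- build_mesh(m60)
  expect_gte(msh$Nz * msh$Nr, 9600)
  expect_true(any(abs(msh$rf - m60$R1) < 1e-15))
  expect_true(any(abs(msh$rf - m60$R2) < 1e-15))
  expect_equal(msh$rf[msh$face_R1], m60$R1)
  expect_equal(msh$rf[msh$face_R2], m60$R2)
  # mid-membrane face exists
  expect_equal(msh$rf[msh$face_mid], (m60$R1 + m60$R2) / 2, tolerance = 1e-12)
  expect_true(all(diff(msh$rf) > 0))
  expect_true(all(diff(msh$zf) > 0))
})

test_that("degenerate resolutions are rejected", {
  expect_error(build_mesh(m60, Nz = 1), "axial resolution")
  expect_error(build_mesh(m60, nr_lumen = 1), "radial resolution")
  expect_error(build_mesh(m60, nr_membrane = 5), "even")
})

test_that("refined meshes nest the coarse faces", {
  coarse <- build_mesh(m60, Nz = 40, nr_lumen = 8, nr_membrane = 4, nr_shell = 6)
  fine <- build_mesh(m60, Nz = 80, nr_lumen = 16, nr_membrane = 8, nr_shell = 12)
  for (rf in coarse$rf) expect_true(min(abs(fine$rf - rf)) < 1e-12 * m60$R3)
  for (zf in coarse$zf) expect_true(min(abs(fine$zf - zf)) < 1e-12 * m60$L)
})
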