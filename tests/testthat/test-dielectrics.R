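test_that("penetration depth matches the closed form and its lossless limit", {
  expect_equal(penetration_depth(complex_permittivity(50, 0), 1e9), Inf)
  expect_rel(penetration_depth(complex_permittivity(50, 20), 1.28e9),
             oracle$penetration_depth, 1e-12)
  expect_error(penetration_depth(complex_permittivity(50, 20), -1), "f > 0")
  expect_error(complex_permittivity(50, -1), ">= 0")
})

test_that("penetration depth agrees with the low-loss Taylor limit within 1%", {
  c_l <- physical_constants()$c_light
  set.seed(13)
  for (i in 1:50) {
    ep <- runif(1, 2, 80)
    tand <- runif(1, 1e-5, 0.01)
    f <- 10^runif(1, 8, 10)
    es <- ep * tand
    lam0 <- c_l / f
    taylor <- lam0 * sqrt(ep) / (2 * pi * es)
    expect_rel(penetration_depth(complex_permittivity(ep, es), f),
               taylor, 0.01)
  }
})

test_that("penetration depth decreases in frequency and in loss", {
  eps <- complex_permittivity(50, 10)
  f <- 10^seq(8, 10, length.out = 40)
  expect_true(all(diff(penetration_depth(eps, f)) < 0))
  es <- seq(1, 40, length.out = 40)
  dp <- penetration_depth(complex_permittivity(50, es), 1.28e9)
  expect_true(all(diff(dp) < 0))
})

test_that("single-shell permittivity reproduces its algebraic limits", {
  em <- complex_permittivity(6)
  ei <- complex_permittivity(60)
  # vanishing membrane: eps_P = eps_i
  no_shell <- shelled_cell(7.5e-6, 0, em, ei)
  expect_lt(Mod(single_shell_permittivity(no_shell) - ei) / Mod(ei), 1e-12)
  # homogeneous sphere: eps_mem = eps_i
  hom <- shelled_cell(7.5e-6, 10e-9, ei, ei)
  expect_lt(Mod(single_shell_permittivity(hom) - ei) / Mod(ei), 1e-12)
  cell <- shelled_cell(7.5e-6, 10e-9, em, ei)
  expect_rel(Re(single_shell_permittivity(cell)),
             oracle$single_shell_eps, 1e-12)
  expect_error(shelled_cell(7.5e-6, 8e-6, em, ei), "d < R")
})

test_that("single-shell permittivity decreases with membrane thickness", {
  em <- complex_permittivity(6)
  ei <- complex_permittivity(60)
  ds <- seq(1e-9, 3.7e-6, length.out = 30)
  vals <- vapply(ds, function(d) {
    Re(single_shell_permittivity(shelled_cell(7.5e-6, d, em, ei)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # and tracks the brute-force definition at every point
  brute <- vapply(ds, function(d) {
    Re(brute_single_shell(6 + 0i, 60 + 0i, 7.5e-6, d))
  }, numeric(1))
  expect_equal(vals, brute, tolerance = 1e-12)
})

test_that("effective-medium mixing hits its endpoints and interpolates", {
  ei <- complex_permittivity(59.15)
  eh <- complex_permittivity(1)
  expect_equal(effective_medium_mixture(ei, eh, 0), as.complex(eh))
  expect_equal(effective_medium_mixture(ei, eh, 1), as.complex(ei))
  expect_rel(Re(effective_medium_mixture(ei, eh, 0.3)),
             oracle$mg_mixture, 1e-12)
  expect_error(effective_medium_mixture(ei, eh, 1.2), "\\[0, 1\\]")
  # interpolation bounds for real permittivities at any phi
  set.seed(17)
  for (i in 1:30) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); phi <- runif(1)
    ee <- Re(effective_medium_mixture(complex_permittivity(a),
                                      complex_permittivity(b), phi))
    expect_gte(ee, min(a, b) - 1e-12)
    expect_lte(ee, max(a, b) + 1e-12)
  }
  # linear rule for sensitivity analysis
  expect_equal(
    Re(effective_medium_mixture(ei, eh, 0.25, rule = "linear")),
    0.25 * 59.15 + 0.75 * 1
  )
})

test_that("dispersion regimes partition frequency with half-open bands", {
  expect_equal(as.character(dispersion_regime(500)$regime), "EDL_DOMINATED")
  expect_equal(as.character(dispersion_regime(50e6)$regime),
               "MEMBRANE_CHARGING")
  expect_equal(as.character(dispersion_regime(1.28e9)$regime),
               "CYTOPLASM_SENSITIVE")
  # boundaries belong to the higher band
  bounds <- dispersion_regime(c(1e3, 1e6, 1e8))
  expect_equal(as.character(bounds$regime),
               c("MEMBRANE_POLARIZATION", "MEMBRANE_CHARGING",
                 "CYTOPLASM_SENSITIVE"))
  # every frequency maps to exactly one band covering it
  f <- 10^seq(-1, 11, length.out = 200)
  reg <- dispersion_regime(f)
  expect_true(all(f >= reg$f_low_hz & f < reg$f_high_hz))
  expect_error(dispersion_regime(0), "f > 0")
})

test_that("cell circuit elements validate positivity", {
  el <- cell_circuit_elements(1e-12, 1e-9, 1e4, 1e5, 1e-13)
  expect_s3_class(el, "cell_circuit_elements")
  expect_error(cell_circuit_elements(-1e-12, 1e-9, 1e4, 1e5, 1e-13), "> 0")
})
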