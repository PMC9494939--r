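test_that("Guinier low-q tail matches adaptive quadrature of its integrand", {
  curve <- simulate_curve(unified_model(G = 1, Rg = 150, B = 0, P = 2.5,
                                        background = 0),
                          q_grid_default())
  low <- guinier_low_q_tail(curve)
  expect_equal(low$Rg, 150, tolerance = 1e-6)
  expect_equal(low$G, 1, tolerance = 1e-6)
  oracle <- stats::integrate(function(q) 1e-8 * exp(-q^2 * 150^2 / 3) * q^2,
                             0, 7.5e-3, rel.tol = 1e-12)$value
  expect_equal(low$tail, oracle, tolerance = 1e-3)
})

test_that("Guinier tail limits: vanishing window and flat intensity", {
  # q_min -> 0: the missing integral vanishes
  qsmall <- q_grid_default(n = 80, q_min = 1e-5, q_max = 0.264)
  c1 <- saxs_curve(qsmall, exp(-qsmall^2 * 150^2 / 3) + 1e-12)
  expect_lt(guinier_low_q_tail(c1)$tail, 1e-8 * (1e-5)^3)

  # Rg -> 0: tail -> G q_min^3 / 3 (flat-intensity limit)
  q <- q_grid_default()
  c2 <- saxs_curve(q, 2 * exp(-q^2 * 5^2 / 3))
  expect_equal(guinier_low_q_tail(c2)$tail, 2e-8 * (7.5e-3)^3 / 3,
               tolerance = 1e-3)
})

test_that("an aggregation upturn at low q attaches a warning", {
  q <- q_grid_default()
  clean <- saxs_curve(q, exp(-q^2 * 150^2 / 3) + 1e-12)
  expect_length(guinier_low_q_tail(clean)$warnings, 0)
  upturn <- saxs_curve(q, exp(-q^2 * 150^2 / 3) + 5e-7 * q^(-2.5))
  expect_match(guinier_low_q_tail(upturn)$warnings, "aggregation",
               all = FALSE)
})

test_that("Porod tail is exact on a q^-4 curve and scales as 1/q_max", {
  K <- 3e-7  # cm^-1 A^-4
  q1 <- q_grid_default(q_max = 0.264)
  tail1 <- porod_high_q_tail(saxs_curve(q1, K * q1^(-4)))
  expect_equal(tail1$K_p, K, tolerance = 1e-12)
  expect_equal(tail1$tail, K * 1e-8 / 0.264, tolerance = 1e-12)
  expect_length(tail1$warnings, 0)

  q2 <- q_grid_default(q_max = 2 * 0.264)
  tail2 <- porod_high_q_tail(saxs_curve(q2, K * q2^(-4)))
  expect_equal(tail2$tail, tail1$tail / 2, tolerance = 1e-12)
})

test_that("a mass-fractal tail still yields K_p but with a slope warning", {
  q <- q_grid_default()
  res <- porod_high_q_tail(saxs_curve(q, 1e-8 * q^(-2.5)))
  expect_gt(res$K_p, 0)
  expect_match(res$warnings, "slope", all = FALSE)
  expect_error(porod_high_q_tail(saxs_curve(q, rep(-1e-12, length(q)))),
               class = "saxshell_invariant_error")
})

test_that("the invariant of a flat curve is c q_max^3 / 3", {
  q <- q_grid_default(n = 4000, q_min = 1e-6, q_max = 0.264)
  inv <- saxs_invariant(saxs_curve(q, rep(2, length(q))),
                        low_tail = 2e-8 * (1e-6)^3 / 3, high_tail = 0)
  expect_equal(inv$q_total, 2e-8 * 0.264^3 / 3, tolerance = 1e-5)
})

test_that("the invariant is linear in the intensity scale", {
  curve <- simulate_curve(mk_model(), q_grid_default())
  inv1 <- saxs_invariant(curve)
  scaled <- saxs_curve(curve$q, curve$intensity * 3.7)
  inv2 <- saxs_invariant(scaled)
  expect_equal(inv2$q_measured, 3.7 * inv1$q_measured, tolerance = 1e-9)
  expect_equal(inv2$q_low_tail, 3.7 * inv1$q_low_tail, tolerance = 1e-6)
  expect_equal(inv2$q_high_tail, 3.7 * inv1$q_high_tail, tolerance = 1e-9)
  expect_equal(inv2$q_total, 3.7 * inv1$q_total, tolerance = 1e-6)
  expect_identical(inv1$q_total, inv1$q_measured + inv1$q_low_tail +
                     inv1$q_high_tail)
})

test_that("dilute-sphere invariant matches the closed two-phase form and needs the Porod tail", {
  R <- 100; drho <- 5.03e-6; phi <- 0.0067
  prof <- mk_sphere(R, drho, phi)
  q <- exp(seq(log(1e-4), log(2), length.out = 8000))
  curve <- saxs_curve(q, layered_sphere_intensity(q, prof))
  inv <- saxs_invariant(curve, low_tail = 0)
  closed <- 2 * pi^2 * drho^2 * phi * (1 - phi)
  expect_equal(inv$q_total, closed, tolerance = 0.01)
  # omitting the high-q tail correction biases the invariant low
  inv_no_tail <- saxs_invariant(curve, low_tail = 0, high_tail = 0)
  expect_lt(inv_no_tail$q_total, inv$q_total)
})

test_that("negative excursions are clipped with a reported fraction, gross negatives error", {
  q <- q_grid_default()
  I <- 1e-8 * q^(-4)
  I[c(3, 10)] <- -1e-12
  expect_warning(inv <- saxs_invariant(saxs_curve(q, I), low_tail = 0),
                 "clipped")
  expect_equal(inv$clipped_fraction, 2 / length(q))
  bad <- saxs_curve(q, I - 1, uncertainty = rep(1e-3, length(q)))
  expect_error(suppressWarnings(saxs_invariant(bad, low_tail = 0)),
               class = "saxshell_invariant_error")
})

test_that("X-ray SLDs agree with independent electron counting for common substances", {
  # independent oracle: own Z / molar-mass table and arithmetic
  oracle <- function(z, m, d) 2.8179403e-5 * 6.022141e23 * d * z / m * 1e-24
  cases <- list(
    water      = list(f = "H2O",       d = 1.0,   z = 10,  m = 18.015),
    cellulose  = list(f = "C6H10O5",   d = 1.5,   z = 86,  m = 162.141),
    decane     = list(f = "C10H22",    d = 0.73,  z = 82,  m = 142.285),
    hexadecane = list(f = "C16H34",    d = 0.773, z = 130, m = 226.446),
    ethanol    = list(f = "C2H6O",     d = 0.789, z = 26,  m = 46.069),
    glycerol   = list(f = "C3H8O3",    d = 1.261, z = 50,  m = 92.094),
    salt       = list(f = "NaCl",      d = 2.165, z = 28,  m = 58.44),
    silica     = list(f = "SiO2",      d = 2.65,  z = 30,  m = 60.083),
    sucrose    = list(f = "C12H22O11", d = 1.587, z = 182, m = 342.297),
    toluene    = list(f = "C7H8",      d = 0.867, z = 50,  m = 92.141))
  for (cs in cases)
    expect_equal(xray_sld(cs$f, cs$d), oracle(cs$z, cs$m, cs$d),
                 tolerance = 1e-3)
  # frozen reference values: computed SLDs differ from the conventional
  # stated pair (1.45e-5 / 9.47e-6) used by default in the analysis
  expect_equal(xray_sld("H2O", 1.0), 9.4199e-6, tolerance = 1e-4)
  expect_equal(xray_sld("C6H10O5", 1.5), 1.35014e-5, tolerance = 1e-4)
  expect_error(xray_sld("H2O", 0), class = "saxshell_parameter_error")
  expect_error(xray_sld("Xx2O", 1), class = "saxshell_parameter_error")
})

test_that("material() computes or accepts an SLD", {
  m1 <- material("cellulose", "C6H10O5", 1.5)
  expect_equal(m1$sld, xray_sld("C6H10O5", 1.5))
  m2 <- material("water", sld = 9.47e-6)
  expect_identical(m2$sld, 9.47e-6)
  expect_error(material("nothing"), class = "saxshell_parameter_error")
})

test_that("1 wt% cellulose at densities 1.5/1.0 gives a 0.0067 volume fraction", {
  expect_identical(signif(wt_to_volume_fraction(0.01, 1.5, 1.0), 2), 0.0067)
})

test_that("the modified-invariant composition has its algebraic limits", {
  drho <- 5e-6; phi_tot <- 0.0067
  q_max_allowed <- 2 * pi^2 * drho^2 * phi_tot
  mid <- phi_from_invariant(q_max_allowed * 0.5, drho, phi_tot)
  expect_equal(mid$phi_cell, 0.5, tolerance = 1e-12)
  expect_equal(mid$f, 2 * phi_tot, tolerance = 1e-12)
  zero <- phi_from_invariant(0, drho, phi_tot)
  expect_identical(zero$phi_cell, 1)
  expect_equal(zero$f, phi_tot, tolerance = 1e-15)
  over <- phi_from_invariant(q_max_allowed * 1.5, drho, phi_tot)
  expect_identical(over$flag, "out_of_range")
  expect_lt(over$phi_cell_raw, 0)
  expect_identical(over$phi_cell, 0)
})

test_that("the published invariant maps to phi_cell = 0.450, not the printed 18%", {
  drho <- 1.45e-5 - 9.47e-6
  est <- phi_from_invariant(1.84e-4, drho, 0.0067, units = "cm^-1 A^-3")
  # frozen independent arithmetic: 1 - 1.84e-12 / (2 pi^2 drho^2 0.0067)
  expect_equal(est$phi_cell, 0.4501081169, tolerance = 1e-10)
  expect_identical(est$flag, "ok")
  # the printed column (18%) is not reproduced by the formula as stated
  expect_gt(abs(est$pct_cellulose - 18), 20)
})

test_that("composition round trip is exact and monotone in Q", {
  drho <- 5.03e-6; phi_tot <- 0.0067
  for (phi in seq(0.05, 0.95, by = 0.15)) {
    q <- 2 * pi^2 * drho^2 * phi_tot * (1 - phi)
    est <- phi_from_invariant(q, drho, phi_tot)
    expect_equal(est$phi_cell, phi, tolerance = 1e-12)
    expect_lt(abs(est$f * est$phi_cell - phi_tot), 1e-12)
  }
  qs <- seq(0, 2 * pi^2 * drho^2 * phi_tot, length.out = 25)
  phis <- vapply(qs, function(q)
    phi_from_invariant(q, drho, phi_tot)$phi_cell, numeric(1))
  expect_true(all(diff(phis) < 0))
})
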