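test_that("unified intensity reaches its Guinier and power-law limits", {
  m <- unified_model(G = 2, Rg = 150, B = 1e-5, P = 2.5)
  # q -> 0: the erf-damped power-law term vanishes as q^(2P)
  expect_equal(unified_intensity(1e-6, m), 2, tolerance = 1e-6)

  # G = 0, q Rg / sqrt(6) >= 3: pure power law within 0.1%
  m0 <- unified_model(G = 0, Rg = 150, B = 1e-5, P = 2.5)
  q_hi <- seq(3 * sqrt(6) / 150, 0.264, length.out = 20)
  expect_equal(unified_intensity(q_hi, m0), 1e-5 * q_hi^(-2.5),
               tolerance = 1e-3)
})

test_that("unified intensity matches the direct formula evaluation", {
  # frozen value from an independent one-line arithmetic evaluation of
  # I(q) = G exp(-q^2 Rg^2/3) + B erf(q Rg/sqrt(6))^(3P) q^-P
  m <- unified_model(G = 1, Rg = 150, B = 1e-5, P = 2.5)
  expect_equal(unified_intensity(0.05, m), 1.788655175281146e-02,
               tolerance = 1e-10)
  q <- q_grid_default(40)
  expect_equal(unified_intensity(q, m), unified_ref(q, 1, 150, 1e-5, 2.5),
               tolerance = 1e-12)
})

test_that("multi-level models damp each power-law term by the smaller level's Guinier factor", {
  l1 <- unified_level(G = 0.1, Rg = 40, B = 1e-7, P = 2.2)
  l2 <- unified_level(G = 5, Rg = 400, B = 1e-9, P = 3.1)
  m <- unified_model(levels = list(l1, l2), background = 0.01)
  q <- q_grid_default(30)
  expected <- unified_ref(q, 0.1, 40, 1e-7, 2.2) +
    unified_ref(q, 5, 400, 0, 3.1) +
    exp(-q^2 * 40^2 / 3) * 1e-9 * erf_ref(q * 400 / sqrt(6))^(3 * 3.1) *
      q^(-3.1) + 0.01
  expect_equal(unified_intensity(q, m), expected, tolerance = 1e-12)
})

test_that("invalid unified parameters are rejected", {
  expect_error(unified_model(G = NaN, Rg = 150, B = 0, P = 2.5),
               class = "saxshell_parameter_error")
  expect_error(unified_model(G = 1, Rg = -5, B = 0, P = 2.5),
               class = "saxshell_parameter_error")
  expect_error(unified_model(G = 1, Rg = 150, B = 0, P = 4),
               class = "saxshell_parameter_error")
  expect_error(unified_model(G = 1, Rg = 150, B = Inf, P = 2.5),
               class = "saxshell_parameter_error")
  m <- unified_model(G = 1, Rg = 150, B = 1e-10, P = 2.5)
  expect_error(unified_intensity(c(-0.1, 0.1), m),
               class = "saxshell_parameter_error")
})

test_that("layered-sphere intensity has the correct forward limit", {
  R <- 100; drho <- 2e-6; nd <- 1e-12
  prof <- layered_sphere(R, drho, 0, nd)
  expected <- 1e8 * nd * (drho * 4 / 3 * pi * R^3)^2  # cm^-1
  expect_equal(layered_sphere_intensity(1e-8, prof), expected,
               tolerance = 1e-9)
  expect_true(all(layered_sphere_intensity(q_grid_default(50), prof) >= 0))
})

test_that("uniform-sphere first minimum sits at qR = 4.4934 (root of tan x = x)", {
  R <- 100
  prof <- layered_sphere(R, 1e-6, 0, 1e-12)
  q <- seq(4.3, 4.7, length.out = 20001) / R
  I <- layered_sphere_intensity(q, prof)
  expect_equal(q[which.min(I)] * R, 4.493409, tolerance = 1e-4)
})

test_that("degenerate shell contrast reduces to the uniform sphere of the outer radius", {
  q <- q_grid_default(80)
  two <- layered_sphere(c(60, 140), c(3e-6, 3e-6), 1e-6, 1e-12)
  uni <- layered_sphere(140, 3e-6, 1e-6, 1e-12)
  expect_equal(layered_sphere_intensity(q, two),
               layered_sphere_intensity(q, uni), tolerance = 1e-12)
})

test_that("zero contrast everywhere warns and returns a zero curve", {
  prof <- layered_sphere(c(50, 100), c(2e-6, 2e-6), 2e-6, 1e-12)
  expect_warning(I <- layered_sphere_intensity(q_grid_default(20), prof),
                 "zero contrast")
  expect_true(all(I == 0))
})

test_that("layered-sphere intensity agrees with a brute-force radial Fourier integral", {
  prof <- layered_sphere(c(100, 180, 220), c(7.1e-6, 1.17e-5, 1.07e-5),
                         9.47e-6, 1e-13)
  slds <- c(prof$layer_slds, prof$solvent_sld)
  bounds <- c(0, prof$radii)
  amp_ref <- function(q) {
    total <- 0
    for (j in seq_along(prof$radii)) {
      drho <- slds[j] - prof$solvent_sld
      if (drho == 0) next
      total <- total + stats::integrate(
        function(r) 4 * pi * r^2 * drho * sin(q * r) / (q * r),
        bounds[j], bounds[j + 1], rel.tol = 1e-11,
        subdivisions = 2000L)$value
    }
    total
  }
  withr::with_seed(7, {
    q <- sort(runif(50, 7.5e-3, 0.264))
  })
  I_ref <- 1e8 * prof$number_density * vapply(q, amp_ref, numeric(1))^2
  I_pkg <- layered_sphere_intensity(q, prof)
  # compare where the form factor is not at a deep null
  big <- I_ref > 1e-6 * max(I_ref)
  expect_true(sum(big) > 30)
  expect_equal(I_pkg[big], I_ref[big], tolerance = 5e-3)
})

test_that("Stuhrmann decomposition is exactly additive and commutative", {
  q <- q_grid_default(40)
  a <- saxs_curve(q, unified_ref(q, 1, 150, 1e-9, 2.5))
  b <- saxs_curve(q, 0.3 * q^(-2))
  zero <- saxs_curve(q, rep(0, length(q)))

  expect_equal(stuhrmann_total(stuhrmann_terms(a, zero))$intensity,
               a$intensity)
  expect_equal(stuhrmann_total(stuhrmann_terms(zero, b))$intensity,
               b$intensity)
  tot_ab <- stuhrmann_total(stuhrmann_terms(a, b))$intensity
  expect_identical(tot_ab - (a$intensity + b$intensity),
                   rep(0, length(q)))
  expect_equal(stuhrmann_total(stuhrmann_terms(b, a))$intensity, tot_ab)

  cross <- saxs_curve(q, rep(1e-3, length(q)))
  expect_equal(stuhrmann_total(stuhrmann_terms(a, b, cross))$intensity,
               tot_ab + 1e-3)

  other <- saxs_curve(q * 1.001, a$intensity)
  expect_error(stuhrmann_terms(a, other), class = "saxshell_grid_error")
})

test_that("negligibility verdicts follow the physics of the shape term", {
  phi <- 0.0137
  # a 50 A sphere at the emulsion volume fraction scatters well inside
  # the measured window: never negligible at a few-percent noise floor
  small <- mk_sphere(50, 5.03e-6, phi)
  expect_warning(rep_small <- shape_term_negligibility(small, noise_floor = 1),
                 "does not apply")
  expect_identical(rep_small$verdict, "not negligible")

  # an infinite floor makes anything negligible
  droplet <- droplet_profile()
  rep_inf <- shape_term_negligibility(droplet, noise_floor = Inf)
  expect_identical(rep_inf$verdict, "negligible")

  # micron droplets push their shape scattering below a few-cm^-1 floor
  # beyond a crossover q that the report localises
  rep_d <- shape_term_negligibility(droplet, noise_floor = 5)
  expect_lte(rep_d$q_at_max, rep_d$smeared$q[3])
  expect_true(is.finite(rep_d$q_clear))
  q <- rep_d$smeared$q
  above <- rep_d$smeared$intensity >= 5
  expect_true(all(q[above] < rep_d$q_clear))
})

test_that("enlarging droplets at fixed volume fraction never makes the shape term less negligible", {
  phi <- 0.0137
  base_radii <- c(1.2e4, 1.45e4, 1.5e4)
  slds <- c(7.14e-6, 1.17e-5, 1.07e-5)
  maxima <- vapply(c(1, 2, 4, 8), function(s) {
    prof <- layered_sphere(base_radii * s, slds, 9.47e-6,
                           phi / (4 / 3 * pi * (1.2e4 * s)^3))
    shape_term_negligibility(prof, noise_floor = 5)$max_intensity
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
})
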