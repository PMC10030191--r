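# Closed-form wrapping thermodynamics and the composite propensity model.

test_that("spreading area follows the saturating tanh law", {
  p <- mechanics_params()
  expect_identical(spreading_area(0, p), 0)
  # frozen arbitrary-precision value of tanh(12.8)
  expect_equal(spreading_area(64, p), 0.999999999984756269611090384,
               tolerance = 1e-7)
  expect_lt(spreading_area(8, p), spreading_area(16, p))
  expect_true(all(diff(spreading_area(log_grid(0.1, 64), p)) >= 0))
  expect_true(all(spreading_area(c(0, 1, 64), p) < 1))
  expect_error(spreading_area(-1, p), "xi")
})

test_that("cell modulus saturates at E_max", {
  expect_identical(cell_modulus(0), 0)
  p1 <- mechanics_params(E_max = 1)
  # frozen arbitrary-precision value of tanh(0.8)
  expect_equal(cell_modulus(16, p1), 0.664036770267848963684844656,
               tolerance = 1e-12)
  for (em in c(0.5, 1, 5)) {
    p <- mechanics_params(E_max = em)
    expect_gt(cell_modulus(32, p), cell_modulus(8, p))
    expect_true(all(cell_modulus(c(1, 10, 64), p) < em))
  }
  expect_error(cell_modulus(-0.1), "xi")
})

test_that("contact angle balances adhesion against bending and compliance", {
  p <- mechanics_params()
  # frozen high-precision evaluation of 0.75*pi*(0.002 - 4*1.9e-5/0.16)/(1*0.4)
  expect_equal(contact_angle(1, 0.4, p), 0.00898299149385831504122912,
               tolerance = 1e-12)
  # clamp engaged at huge adhesion: full wrapping
  expect_identical(contact_angle(1, 1, mechanics_params(delta_gamma = 1e3)),
                   pi)
  # strictly decreasing in E where interior
  E <- seq(0.5, 5, length.out = 50)
  expect_true(all(diff(contact_angle(E, 0.4, p)) < 0))
  expect_error(contact_angle(0, 0.4, p), "singular")
  expect_error(contact_angle(c(1, -1), 0.4, p), "> 0")
})

test_that("wrapping vanishes exactly below the critical radius", {
  p <- mechanics_params()
  rc <- critical_radius(p)
  expect_equal(rc, sqrt(4 * p$kappa / p$delta_gamma), tolerance = 1e-15)
  # frozen closed-form value at the default constants
  expect_equal(rc, 0.194935886896179278, tolerance = 1e-12)
  eps <- 1e-9
  expect_identical(contact_angle(1, rc - eps, p), 0)
  expect_gt(contact_angle(1, rc + eps, p), 0)
  expect_identical(contact_angle(1, rc / 2, p), 0)
  expect_identical(contact_angle(1, 0.01, p), 0)
})

test_that("contact area is the spherical-cap area", {
  expect_identical(contact_area(0, 1), 0)
  expect_equal(contact_area(pi, 1), 4 * pi, tolerance = 1e-15)
  # hemisphere, frozen closed form 2*pi*1.2^2
  expect_equal(contact_area(pi / 2, 1.2), 9.04778684233860452677,
               tolerance = 1e-12)
  th <- seq(0, pi, length.out = 100)
  expect_true(all(diff(contact_area(th, 0.7)) > 0))
  expect_error(contact_area(-0.1, 1), "0, pi")
  expect_error(contact_area(3.2, 1), "0, pi")
})

test_that("small wrapping angles reduce to the quadratic cap limit", {
  for (R in c(0.4, 1.2)) {
    th <- c(1e-4, 1e-3, 5e-3, 9.9e-3)
    expect_equal(contact_area(th, R), pi * R^2 * th^2, tolerance = 1e-4)
  }
})

test_that("functionality factor is a saturating multiplier", {
  expect_identical(functionality_factor(0, mechanics_params(beta_func = 2)), 1)
  expect_identical(functionality_factor(c(1, 10, 64), mechanics_params()),
                   rep(1, 3))  # beta = 0: pure physics
  p <- mechanics_params(beta_func = 1, xi_half = 16)
  expect_equal(functionality_factor(16, p), 1.5, tolerance = 1e-15)
  xi <- log_grid(0.1, 1e4)
  g <- functionality_factor(xi, mechanics_params(beta_func = 3))
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 1 & g < 4))
})

test_that("propensity rises then falls once over the model domain", {
  for (R in c(0.4, 1.2)) {
    v <- uptake_propensity(log_grid(1e-3, 64, 2000), R)
    expect_identical(n_sign_changes(v), 1L)
    expect_identical(uptake_propensity(0, R), 0)
    expect_true(all(is.finite(v)) && all(v >= 0))
  }
})

test_that("propensity is ordered by bead size on the panel", {
  small <- uptake_propensity(default_panel, 0.4)
  large <- uptake_propensity(default_panel, 1.2)
  expect_true(all(large >= small))
})

test_that("contact angle and area shrink with rigidity where interior", {
  p <- mechanics_params()
  xi <- log_grid(0.5, 64)
  E <- cell_modulus(xi, p)
  th <- contact_angle(E, 0.4, p)
  interior <- th > 0 & th < pi
  expect_true(all(diff(th[interior]) <= 0))
  expect_true(all(diff(contact_area(th[interior], 0.4)) <= 0))
})

test_that("contact angle is invariant under consistent unit changes", {
  p <- mechanics_params()
  E_kpa <- cell_modulus(8, p)
  th_kpa_um <- contact_angle(E_kpa, 0.4, p)
  # same physics in Pa and m: kPa*um -> 1e-3 Pa*m, kPa*um^3 -> 1e-15 Pa*m^3
  p_si <- mechanics_params(delta_gamma = p$delta_gamma * 1e-3,
                           kappa = p$kappa * 1e-15,
                           E_max = p$E_max * 1e3,
                           alpha_A = p$alpha_A, alpha_E = p$alpha_E)
  th_pa_m <- contact_angle(E_kpa * 1e3, 0.4e-6, p_si)
  expect_equal(th_kpa_um, th_pa_m, tolerance = 1e-12)
})

test_that("predicted curve matches a brute-force peak scan", {
  curve <- predict_uptake_curve(default_panel, 0.4)
  expect_s3_class(curve, "uptake_curve")
  expect_identical(nrow(curve), 6L)
  expect_identical(unique(curve$value_kind), "propensity")
  # independent brute force on a much denser grid
  dense <- log_grid(0.5, 64, 4096)
  brute <- dense[which.max(uptake_propensity(dense, 0.4))]
  expect_equal(attr(curve, "peak_rigidity"), brute, tolerance = 0.01)
  expect_gt(attr(curve, "peak_rigidity"), 0.5)
  expect_lt(attr(curve, "peak_rigidity"), 64)
})

test_that("single-point panels are consistent with pointwise evaluation", {
  c1 <- predict_uptake_curve(8, 1.2)
  expect_identical(nrow(c1), 1L)
  expect_equal(c1$value, uptake_propensity(8, 1.2), tolerance = 1e-15)
})

test_that("a strong functionality term dominates the stiff tail", {
  p <- mechanics_params(beta_func = 10)
  curve <- predict_uptake_curve(default_panel, 0.4, p,
                                include_functionality = TRUE)
  phys <- predict_uptake_curve(default_panel, 0.4, mechanics_params())
  peak_phys <- max(phys$value)
  expect_gt(curve$value[curve$rigidity_kpa == 64], peak_phys)
})

test_that("invalid panels and parameters are rejected", {
  expect_error(predict_uptake_curve(numeric(0), 0.4), "empty")
  expect_error(predict_uptake_curve(c(2, 1), 0.4), "increasing")
  expect_error(predict_uptake_curve(c(0, 2), 0.4), "increasing|> 0")
  expect_error(mechanics_params(delta_gamma = -1), "must be > 0")
  expect_error(mechanics_params(beta_func = -0.5), ">= 0")
  expect_error(uptake_propensity(1, -0.4), "radius")
})

test_that("measured uptake curves validate their values", {
  uc <- uptake_curve(default_panel, c(10, 30, 95, 80, 60, 70) / 100,
                     "measured_fraction", radius = 0.4)
  expect_identical(nrow(uc), 6L)
  expect_error(uptake_curve(default_panel, c(1, 2, 3, 4, 5, 6),
                            "measured_fraction", radius = 0.4), "<= 1")
  expect_error(uptake_curve(c(1, 2), c(0.1), "probability", radius = 1),
               "length")
})
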