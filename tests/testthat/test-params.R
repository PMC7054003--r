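test_that("motor parameter validation enforces the model's assumptions", {
  expect_error(motor_params(lp = 20), "stiff regime")
  expect_error(motor_params(b = 0), "binding penalty")
  expect_error(motor_params(b = 1.5), "binding penalty")
  expect_error(motor_params(dphi_ac = 200), "dphi_ac")
  expect_equal(motor_params(mutant = "4IQ")$L, 25)
  expect_equal(motor_params(mutant = "8IQ")$dV, 35)
  expect_equal(motor_params()$kappa, 0.1)
})

test_that("power stroke effectiveness matches its closed form", {
  p <- wt_params
  expect_equal(power_stroke_effectiveness(p),
               1 + 20 * 261 / (20 + 7 * 0.1 * 261))
  expect_equal(power_stroke_effectiveness(p), 26.752, tolerance = 1e-4)
})

test_that("force renormalization of the power stroke obeys its limits", {
  p <- wt_params
  # zero force: identity
  ec0 <- effective_constraint(p, load_force(0))
  expect_equal(ec0$T_eff, ec0$T0)
  expect_equal(ec0$u_c_prime, ec0$u_c)
  # backward 1.9 pN: independent scalar computation of the vector norm
  ec <- effective_constraint(p, load_force(1.9))
  bFL <- 1.9 * 35 / 4.1
  T0 <- ec$T0
  expect_equal(ec$bFL, bFL)
  expect_equal(ec$T_eff,
               sqrt(T0^2 + bFL^2 + 2 * T0 * bFL * (-cos(65 * pi / 180))),
               tolerance = 1e-12)
  expect_equal(ec$T_eff, 24.7, tolerance = 0.01)
  # strong-force limit: constraint direction approaches the force direction
  ec_big <- effective_constraint(p, load_force(500, theta_F = 30))
  expect_gt(sum(ec_big$u_c_prime * load_force(500, theta_F = 30)$Fhat),
            0.999)
  # the backward force tilts the effective angle past the zero-force value
  expect_gt(ec$theta_c_prime, p$theta_c)
  # exact cancellation is degenerate
  # force anti-parallel to the power-stroke direction with |bFL| = T
  Fc <- ec0$T0 * p$kBT / p$L
  expect_error(effective_constraint(p, load_force(Fc, theta_F = 65,
                                                  phi_F = 180)),
               "degenerate")
})

test_that("joint potential forms agree where they should", {
  expect_equal(joint_potential(1.2, 5, 1.2), 0)
  expect_equal(joint_potential(1.2, 5, 1.2, "quartic"), 0)
  expect_equal(joint_potential(pi / 2 + 0.5, 5, 0.5), 5)  # mu (1 - cos(pi/2))
  # small-angle agreement between cosine and pure-harmonic quartic
  dt <- 0.05
  expect_equal(joint_potential(1 + dt, 7, 1),
               joint_potential(1 + dt, 7, 1, "quartic"),
               tolerance = 1e-3)
  # cubic/quartic coefficients enter the quartic form
  expect_gt(joint_potential(1.5, 5, 1, "quartic", h3 = 2, h4 = 3),
            joint_potential(1.5, 5, 1, "quartic"))
})

test_that("kinetic rates encode gating", {
  r <- kinetic_rates()
  expect_equal(r$g, 8)
  expect_equal(r$td1, 1000 / 12)
  expect_error(kinetic_rates(td1 = 100, td2 = 50), "gating")
})
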