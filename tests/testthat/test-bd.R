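test_that("without thermal noise the chain relaxes instead of binding far away", {
  st <- bd_settings(seed = 41, max_time = 0.005, record_stride = 100)
  res <- simulate_step(wt_params, wt_rates, wt_lattice, load_force(0), st,
                       "trailing", n_traj = 1, noise_scale = 0)
  expect_identical(res$outcome, "timeout")  # gradient descent cannot reach a site
  # and the relaxed head ends near the energy minimum, far from the anchor
  tr <- bd_equilibrium_sample(wt_params, load_force(0), st,
                              t_total = 0.005, record_stride = 100,
                              burn_ms = 0, noise_scale = 0)
  drift <- sqrt(sum((tr[nrow(tr), ] - tr[nrow(tr) - 1, ])^2))
  expect_lt(drift, 0.05)  # converged to a stationary point
})

test_that("BD trajectories are reproducible and stable", {
  st <- bd_settings(seed = 42, max_time = 0.05)
  r1 <- simulate_step(wt_params, wt_rates, wt_lattice, load_force(0), st,
                      "trailing", n_traj = 2)
  r2 <- simulate_step(wt_params, wt_rates, wt_lattice, load_force(0), st,
                      "trailing", n_traj = 2)
  expect_identical(r1, r2)
  # a grossly large time step triggers the instability guard
  st_bad <- bd_settings(dt = 50, seed = 1, max_time = 0.001)
  expect_error(simulate_step(wt_params, wt_rates, wt_lattice, load_force(0),
                             st_bad, "trailing", n_traj = 1),
               "instability")
})

test_that("BD equilibrium sampling matches the Metropolis oracle", {
  # average over several trajectories: the compass-arc swing is the slow mode
  st <- bd_settings(seed = 43)
  zm <- rm <- numeric(6)
  for (k in 1:6) {
    s2 <- st; s2$seed <- 430 + k
    tr <- bd_equilibrium_sample(wt_params, load_force(0), s2,
                                t_total = 0.35, record_stride = 100,
                                burn_ms = 0.05)
    zm[k] <- mean(tr[, "z"])
    rm[k] <- mean(sqrt(rowSums(tr^2)))
  }
  mc <- density_oracle_mc(wt_params, load_force(0), n_samples = 5e4,
                          seed = 44)
  r_mc <- mean(sqrt(rowSums(mc$samples[, 1:3]^2)))
  expect_equal(mean(rm), r_mc, tolerance = 0.05)
  expect_equal(mean(zm), mean(mc$samples[, "z"]),
               tolerance = 3 * sd(zm) / sqrt(6) + 3)
})

test_that("the cover slip removes excluded half-space without killing the lobes", {
  st <- bd_settings(seed = 46, coverslip = -11)
  ct <- ensemble_contours(wt_params, load_force(0), st, n_traj = 10,
                          t_total = 0.1, spacing = 4, plane = "y-x")
  # no mass beyond the wall (x is the second axis of the y-x projection)
  wall_cols <- ct$v < -11 - 4
  expect_equal(sum(ct$values[, wall_cols]), 0)
  expect_gt(max(ct$values), 0)
})

test_that("effective exclusion length collapses when exclusion is disabled", {
  dv0 <- suppressWarnings(
    estimate_dV(wt_params, bd_settings(seed = 47), n_samples = 4e4,
                explicit_ev = FALSE))
  expect_lt(dv0$dV, 15)  # no repulsion scale, fit sees only noise
  dv <- suppressWarnings(
    estimate_dV(wt_params, bd_settings(seed = 47), n_samples = 8e4))
  expect_equal(dv$dV, 27.5, tolerance = 0.15)
  expect_gt(dv$dV, dv0$dV)
})
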