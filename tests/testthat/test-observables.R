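make_point_pp <- function(n_sep, lattice = wt_lattice) {
  # minimal pathway object with all trailing mass on one site
  tb <- data.frame(n = c(-n_sep, n_sep), z = c(-n_sep, n_sep) * lattice$dz / 2,
                   pT = c(0, 0.9), pL = c(0.05, 0))
  structure(list(table = tb, Pf = 0.8, Pb = 0.005, PTs = 0, PLs = 0.045,
                 Pt = 0.05, g = 8), class = "pathway_probabilities")
}

test_that("head-separation distribution is normalized and peaks half-helically", {
  kin <- wt_kinetics()
  sep <- head_separation_distribution(kin$pp, wt_lattice)
  expect_equal(sum(sep$mass), 1, tolerance = 1e-12)
  expect_true(all(sep$n > 0))
  expect_equal(sep$n[which.max(sep$mass)], 13)
  # separation cap removes large separations
  sep_cut <- head_separation_distribution(kin$pp, wt_lattice,
                                          max_separation = 12)
  expect_true(all(sep_cut$mass[sep_cut$n > 12] == 0))
})

test_that("step distributions are convolutions with the expected shift", {
  pp <- make_point_pp(13)
  tr <- step_distribution(pp, wt_lattice, "trailing")
  # point separation at 13 convolved with point binding at 13: step of 26
  # subunits, i.e. 72 nm
  expect_equal(tr$n[which.max(tr$mass)], 26)
  expect_equal(tr$z[which.max(tr$mass)], 72, tolerance = 1e-10)
  # combined distribution carries the non-terminated mass
  kin <- wt_kinetics()
  cb <- step_distribution(kin$pp, wt_lattice, "combined")
  expect_equal(sum(cb$mass), 1 - kin$pp$Pt, tolerance = 1e-9)
  fw <- step_distribution(kin$pp, wt_lattice, "forward-only")
  expect_equal(sum(fw$mass), 1, tolerance = 1e-12)
  expect_equal(fw$z[which.max(fw$mass)], 72, tolerance = 1e-10)
})

test_that("measurement convolution preserves mass and matches the normal CDF", {
  pt <- structure(list(n = 13L, z = 36, mass = 1, kind = "forward-only"),
                  class = "step_distribution")
  h <- measurement_convolve(pt, sigma = 1, bin_width = 2)
  expect_equal(sum(h$mass), 1, tolerance = 1e-6)
  # closed-form check: bin mass = Phi(hi) - Phi(lo) for N(36, 1)
  for (i in seq_along(h$z)) {
    expect_equal(h$mass[i],
                 pnorm(h$z[i] + 1, 36, 1) - pnorm(h$z[i] - 1, 36, 1),
                 tolerance = 1e-10)
  }
  # sigma = 0 reduces to binning
  kin <- wt_kinetics()
  fw <- step_distribution(kin$pp, wt_lattice, "forward-only")
  h0 <- measurement_convolve(fw, sigma = 0, bin_width = 5)
  expect_equal(sum(h0$mass), 1, tolerance = 1e-9)
  expect_error(measurement_convolve(fw, sigma = 1, bin_width = -1), "bin")
})

test_that("run statistics satisfy their identities", {
  kin <- wt_kinetics()
  cb <- step_distribution(kin$pp, wt_lattice, "combined")
  rs <- run_statistics(kin$pp, cb, kin$bt, wt_rates)
  expect_equal(rs$v_run, rs$z_run / rs$t_run, tolerance = 1e-12)
  expect_equal(rs$N_run, 1 / kin$pp$Pt, tolerance = 1e-12)
  expect_equal(rs$t_wait, 8 * wt_rates$td1 / 9, tolerance = 1e-12)
  expect_error(run_statistics(kin$pp,
                              step_distribution(kin$pp, wt_lattice,
                                                "forward-only"),
                              kin$bt, wt_rates), "combined")
})

test_that("run length decreases monotonically with backward load", {
  Fs <- c(0.5, 1.2, 1.9, 2.6)
  z <- vapply(Fs, function(F) {
    run_at_force(wt_params, load_force(F), wt_rates, wt_lattice)$rs$z_run
  }, numeric(1))
  expect_true(all(diff(z) < 0))
  # ratio increases monotonically over the same range
  r <- vapply(Fs, function(F) {
    kin <- myov_kinetics(wt_params, load_force(F), wt_rates, wt_lattice)
    kin$pp$Pb / kin$pp$Pf
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(stall_force(wt_params, wt_rates, wt_lattice,
                           bracket = c(0.1, 0.3)), "bracket")
})

test_that("forward-step distribution is robust to sub-stall load", {
  fw0 <- step_distribution(wt_kinetics()$pp, wt_lattice, "forward-only")
  kin1 <- myov_kinetics(wt_params, load_force(1), wt_rates, wt_lattice)
  fw1 <- step_distribution(kin1$pp, wt_lattice, "forward-only")
  shift <- fw0$z[which.max(fw0$mass)] - fw1$z[which.max(fw1$mass)]
  # peak moves backward by at most one actin subunit (two half-subunits)
  expect_gte(shift, 0)
  expect_lte(shift, wt_lattice$dz + 1e-9)
})

test_that("at stall the forward and backward step lobes carry equal mass", {
  sf <- 1.89  # near the computed stall point
  kin <- myov_kinetics(wt_params, load_force(sf), wt_rates, wt_lattice)
  cb <- step_distribution(kin$pp, wt_lattice, "combined")
  fwd <- sum(cb$mass[cb$z > 18])
  bwd <- sum(cb$mass[cb$z < -18])
  expect_equal(fwd / bwd, 1, tolerance = 0.15)
})

test_that("low-ATP kinetics walk backward above stall", {
  r_low <- kinetic_rates(td1 = 1000 / 2.2, td2 = 1000 / 1.5)
  rs <- run_at_force(wt_params, load_force(3), r_low, wt_lattice)$rs
  v_nm_s <- rs$v_run * 1000
  expect_lt(v_nm_s, 0)
  expect_lt(abs(v_nm_s), 90)
})

test_that("kinetic Monte-Carlo runs reproduce the closed-form statistics", {
  n_runs <- 400
  mc <- run_monte_carlo(wt_params, wt_rates, n_runs = n_runs, seed = 11,
                        force = load_force(0), lattice = wt_lattice)
  kin <- wt_kinetics()
  cb <- step_distribution(kin$pp, wt_lattice, "combined")
  rs <- run_statistics(kin$pp, cb, kin$bt, wt_rates)
  se_steps <- sd(mc$runs$n_steps) / sqrt(n_runs)
  expect_lt(abs(mean(mc$runs$n_steps) - rs$N_run), 3 * se_steps)
  se_len <- sd(mc$runs$length) / sqrt(n_runs)
  expect_lt(abs(mean(mc$runs$length) - rs$z_run), 3 * se_len)
  se_t <- sd(mc$runs$time) / sqrt(n_runs)
  expect_lt(abs(mean(mc$runs$time) - rs$t_run), 3 * se_t)
  # determinism
  mc2 <- run_monte_carlo(wt_params, wt_rates, n_runs = 5, seed = 11,
                         force = load_force(0), lattice = wt_lattice)
  mc3 <- run_monte_carlo(wt_params, wt_rates, n_runs = 5, seed = 11,
                         force = load_force(0), lattice = wt_lattice)
  expect_identical(mc2$runs, mc3$runs)
})

test_that("the optical-trap rule ramps the load and ends runs at higher force", {
  mt <- run_monte_carlo(wt_params, wt_rates, n_runs = 6, seed = 5,
                        force_rule = "trap",
                        trap = list(stiffness = 0.02, offaxis_y = 50),
                        lattice = wt_lattice)
  expect_true(all(mt$runs$F_end >= 0))
  expect_gt(mean(mt$runs$F_end), 0.5)
})
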