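test_that("the Metropolis oracle is deterministic and symmetric where it should be", {
  mc1 <- density_oracle_mc(wt_params, load_force(0), n_samples = 5000,
                           seed = 21)
  mc2 <- density_oracle_mc(wt_params, load_force(0), n_samples = 5000,
                           seed = 21)
  expect_identical(mc1$samples, mc2$samples)
  # the Hamiltonian is y-mirror symmetric at zero off-axis force
  mc <- density_oracle_mc(wt_params, load_force(0), n_samples = 5e4,
                          seed = 22)
  se <- sd(mc$samples[, "y"]) / sqrt(mc$ess)
  expect_lt(abs(mean(mc$samples[, "y"])), 4 * se)
  # actin and the power stroke break the x symmetry
  expect_gt(mean(mc$samples[, "x"]), 10)
})

test_that("with all constraints off the chain reproduces the mean-field leg statistics", {
  p0 <- wt_params
  p0$nu_c <- 0
  p0$mu_c <- 0
  mc <- density_oracle_mc(p0, load_force(0), n_samples = 4e4, seed = 23,
                          use_hv = FALSE, n_segments = 14)
  r <- sqrt(rowSums(mc$samples[, 1:3]^2))
  # reference: head = sum of two independent mean-field chords with
  # isotropic orientations
  lg <- seq(1e-3, p0$L - 1e-6, length.out = 8000)
  f <- myovstep:::wlc_radial_shape(lg, p0$L, p0$kappa) * lg^2
  cdf <- cumsum(f) / sum(f)
  set.seed(1)
  qs <- function(u) lg[findInterval(u, cdf) + 1]
  l1 <- qs(runif(2e5)); l2 <- qs(runif(2e5))
  rr <- sqrt(l1^2 + l2^2 + 2 * l1 * l2 * runif(2e5, -1, 1))
  expect_equal(mean(r), mean(rr), tolerance = 0.02)
  expect_equal(sd(r), sd(rr), tolerance = 0.05)
})
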