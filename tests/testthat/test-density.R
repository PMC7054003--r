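test_that("KL divergence satisfies its defining properties", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # hand evaluation for a two-point pair
  expect_equal(kl_divergence(c(0.8, 0.2), c(0.5, 0.5)),
               0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.8, 0.2), c(0.5, 0.5)), 0.1927,
               tolerance = 1e-3)
  set.seed(7)
  for (i in 1:20) {
    P <- runif(6); Q <- runif(6) + 0.01
    expect_gte(kl_divergence(P, Q), 0)
  }
  expect_error(kl_divergence(c(1, 0), c(1)), "support")
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "vanishes")
})

test_that("radial quadrature integrates the semiflexible end distribution", {
  # dense-trapezoid reference for int l^2 f(l) g(l) dl
  L <- 35; kap <- 0.1
  lg <- seq(1e-4, L - 1e-9, length.out = 40000)
  f <- myovstep:::wlc_radial_shape(lg, L, kap)
  rq <- myovstep:::radial_quadrature(L, kap, 24)
  for (g in list(function(l) 1, function(l) l, function(l) sin(l / 10))) {
    ref <- sum(lg^2 * f * g(lg)) * (lg[2] - lg[1])
    expect_equal(sum(rq$w * g(rq$l)), ref, tolerance = 1e-3)
  }
  # the chord-length distribution is sharply peaked just below full extension
  expect_equal(rq$l[which.max(rq$w)] / L, sqrt(1 - kap / 4),
               tolerance = 0.02)
})

test_that("free-head density normalizes and projections are consistent", {
  g <- free_head_density(wt_params, load_force(0), spacing = 3,
                         check_norm = FALSE)
  expect_lt(abs(g$total - 1), 0.01)
  h <- g$spacing
  for (pl in c("z-x", "z-y", "y-x", "z-rho")) {
    pr <- project_density(g, pl)
    expect_lt(abs(sum(pr$values) * h^2 - g$total) /
                g$total, 1e-6)
  }
  # Fubini: both z-x and z-y marginals collapse to the same z-marginal
  zx <- project_density(g, "z-x")
  zy <- project_density(g, "z-y")
  expect_equal(rowSums(zx$values), rowSums(zy$values), tolerance = 1e-10)
  expect_error(project_density(g, "q-w"))
})

test_that("windowed site densities reduce to the marginal and to zero", {
  p <- wt_params
  model <- density_model(p)
  n <- c(11, 13, 15)
  full <- joint_density_at_site(p, load_force(0), n, wt_lattice, model,
                                delta1 = pi, delta2 = pi)
  marg <- myovstep:::density_eval(model, site_position(wt_lattice, n))
  expect_equal(full, marg, tolerance = 1e-6)
  zero <- joint_density_at_site(p, load_force(0), n, wt_lattice, model,
                                delta1 = 0, delta2 = 0)
  expect_equal(zero, rep(0, 3))
  win <- joint_density_at_site(p, load_force(0), n, wt_lattice, model)
  expect_true(all(win > 0 & win <= marg))
  # window mass grows with the half-width
  wider <- joint_density_at_site(p, load_force(0), n, wt_lattice, model,
                                 delta1 = 80 * pi / 180,
                                 delta2 = 80 * pi / 180)
  expect_true(all(wider >= win))
})

test_that("backward load rotates the free-head distribution toward the minus end", {
  g0 <- free_head_density(wt_params, load_force(0), spacing = 5,
                          check_norm = FALSE)
  g2 <- free_head_density(wt_params, load_force(2), spacing = 5,
                          check_norm = FALSE)
  zc <- function(g) sum(apply(g$values, 3, sum) * g$axes$z) / sum(g$values)
  expect_lt(zc(g2), zc(g0) - 5)
})

test_that("mutant densities are near-radial rescalings of the wild type", {
  # mean head-bound-head distance scales with leg length
  r_mean <- vapply(c("4IQ", "6IQ", "8IQ"), function(m) {
    p <- motor_params(mutant = m)
    mc <- density_oracle_mc(p, load_force(0), n_samples = 2e4, seed = 3)
    mean(sqrt(rowSums(mc$samples[, 1:3]^2)))
  }, numeric(1))
  expect_equal(r_mean[["4IQ"]] / r_mean[["6IQ"]], 25 / 35, tolerance = 0.08)
  expect_equal(r_mean[["8IQ"]] / r_mean[["6IQ"]], 45 / 35, tolerance = 0.08)
})

test_that("small anharmonic joint potentials barely change the density", {
  m_cos <- density_model(wt_params)
  m_q <- density_model(wt_params,
                       joint_spec = list(form = "quartic", h3 = 0.2,
                                         h4 = 0.2))
  pts <- site_position(wt_lattice, c(-13, 11, 13, 15))
  d_cos <- myovstep:::density_eval(m_cos, pts)
  d_q <- myovstep:::density_eval(m_q, pts)
  expect_equal(d_q / d_cos, rep(1, 4), tolerance = 0.35)
})
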