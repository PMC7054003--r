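test_that("constant-effectiveness curves invert correctly", {
  p <- wt_params
  T0 <- power_stroke_effectiveness(p)
  expect_equal(nu_c_for_T(T0, p$kappa), p$nu_c, tolerance = 1e-9)
  # moving lp along the curve preserves T (T = 26.75 needs lp > ~315 nm)
  p2 <- myovstep:::apply_free_params(p, list(lp = 330, T = T0))
  expect_equal(power_stroke_effectiveness(p2), T0, tolerance = 1e-9)
  expect_error(nu_c_for_T(100, 0.1), "unreachable")
  expect_error(myovstep:::apply_free_params(p, list(lp = 150, T = T0)),
               "unreachable")
})

test_that("fixture histograms are reproducible and peak at the full step size", {
  fx1 <- generate_fixture_histograms(wt_params, mutants = "6IQ",
                                     n_samples = 400, seed = 5)
  fx2 <- generate_fixture_histograms(wt_params, mutants = "6IQ",
                                     n_samples = 400, seed = 5)
  expect_identical(fx1, fx2)
  h <- fx1[["6IQ"]]
  expect_equal(sum(h$count), 400)
  # wild-type forward steps cluster at twice the half-helical separation
  expect_equal(h$z[which.max(h$count)], 72, tolerance = 5)
  # large-sample limit: empirical histogram converges on the model law
  fx_big <- generate_fixture_histograms(wt_params, mutants = "6IQ",
                                        n_samples = 1e5, seed = 6)[["6IQ"]]
  kin <- wt_kinetics()
  mh <- myovstep:::model_histogram(wt_params, fx_big$z, 1, wt_rates,
                                  wt_lattice)
  expect_lt(kl_divergence(fx_big$count / sum(fx_big$count), mh,
                          floor = 1e-6), 1e-3)
})

test_that("the KL objective vanishes on perfect data and is label-invariant", {
  # exact model histogram as data: objective at the generating truth ~ 0
  kin <- wt_kinetics()
  zg <- seq(32.5, 122.5, by = 5)
  mh <- myovstep:::model_histogram(wt_params, zg, 1, wt_rates, wt_lattice)
  dat <- data.frame(z = zg, count = mh * 1e6)
  spec <- fit_spec(datasets = list(`6IQ` = dat), base_params = wt_params)
  obj_at <- function(vals, sp, floor = 1e-6) {
    p <- myovstep:::apply_free_params(sp$base_params, vals, "6IQ")
    m <- myovstep:::model_histogram(p, dat$z, 1, wt_rates, wt_lattice)
    kl_divergence(dat$count / sum(dat$count), m, floor = floor)
  }
  truth <- list(theta_c = 65, dphi_ac = 55.6, theta_p = 83)
  expect_lt(obj_at(truth, spec, floor = 0), 1e-6)
  # permuting histogram rows leaves the objective unchanged
  perm <- sample(nrow(dat))
  spec2 <- fit_spec(datasets = list(`6IQ` = dat[perm, ]),
                    base_params = wt_params)
  expect_equal(obj_at(truth, spec2), obj_at(truth, spec), tolerance = 1e-12)
  # a strongly over-constrained joint fits the same data worse
  spec12 <- spec
  spec12$base_params$mu_c <- 12
  expect_gt(obj_at(truth, spec12), obj_at(truth, spec) + 0.001)
})

test_that("force-response fitting recovers the binding penalty", {
  spec <- fit_spec(base_params = wt_params,
                   constraints = list(F_stall = 1.9, z_run0 = 1300))
  fr <- fit_force_response(spec, wt_rates, wt_lattice, maxit = 25)
  expect_equal(fr$b, 0.045, tolerance = 0.35)
  expect_equal(fr$F_stall, 1.9, tolerance = 0.05)
  expect_equal(fr$z_run0, 1300, tolerance = 0.1 * 1300)
})

test_that("the step-ratio bump below stall requires a small binding penalty", {
  # the bump is a plateau in the otherwise exponential rise of Pb/Pf: the
  # local logarithmic slope dips strongly near ~1.3 pN when b is small and
  # barely when binding is hardly penalized
  Fs <- seq(0.2, 1.6, by = 0.2)
  min_log_slope <- function(b) {
    p <- wt_params; p$b <- b
    r <- vapply(Fs, function(F) {
      kin <- myov_kinetics(p, load_force(F), wt_rates, wt_lattice)
      kin$pp$Pb / kin$pp$Pf
    }, numeric(1))
    min(diff(log(r)) / diff(Fs))
  }
  expect_lt(min_log_slope(0.045), 0.5 * min_log_slope(0.3))
})

test_that("histogram files round-trip through the two-column text format", {
  fx <- generate_fixture_histograms(wt_params, mutants = "6IQ",
                                    n_samples = 100, seed = 7)[["6IQ"]]
  path <- tempfile(fileext = ".txt")
  write_histogram(fx, path, comment = "synthetic 6IQ step histogram")
  back <- read_histogram(path)
  expect_equal(back$z, fx$z)
  expect_equal(back$count, fx$count)
})
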