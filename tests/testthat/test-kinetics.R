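test_that("first-passage times scale and combine as diffusion-limited rates", {
  kin <- wt_kinetics()
  sp <- kin$sp
  # doubling the capture radius halves every first-passage time
  p2 <- wt_params
  p2$a <- 2 * wt_params$a
  sp2 <- first_passage_times(p2, load_force(0), wt_lattice, kin$model)
  expect_equal(sp2$table$tfp, sp$table$tfp / 2, tolerance = 1e-12)
  # tdiff is the harmonic combination of the site times
  expect_equal(sp$tdiff, 1 / sum(1 / sp$table$tfp), tolerance = 1e-12)
  # fastest site is a forward site at the half-helical distance
  expect_equal(sp$table$n[which.min(sp$table$tfp)] %in% c(13, 15), TRUE)
  expect_error(first_passage_times(wt_params, load_force(0),
                                   wt_lattice, kin$model,
                                   density_floor = 1), "unreachable")
})

test_that("the five-pathway network conserves probability exactly", {
  pp <- wt_kinetics()$pp
  expect_equal(pp$Pf + pp$Pb + pp$PTs + pp$PLs + pp$Pt, 1,
               tolerance = 1e-12)
  expect_true(all(c(pp$Pf, pp$Pb, pp$PTs, pp$PLs, pp$Pt) >= 0))
  # at zero force forward steps dominate the trailing branch, and the
  # leading branch is dominated by stomps
  expect_gt(pp$Pf, 10 * pp$PTs)
  expect_gt(pp$PLs, 10 * pp$Pb)
})

test_that("trailing and leading per-site formulas coincide when th = 0, b = 1", {
  sp <- wt_kinetics()$sp
  r0 <- kinetic_rates(th = 0)
  pp <- pathway_probabilities(sp, r0, b = 1)
  expect_equal(pp$table$pT, pp$table$pL, tolerance = 1e-12)
})

test_that("binding times follow their closed forms", {
  kin <- wt_kinetics()
  bt <- kin$bt
  expect_equal(bt$tT, 1 / kin$pp$rT + wt_rates$th, tolerance = 1e-12)
  expect_equal(bt$tL, 1 / kin$pp$rL, tolerance = 1e-12)
  expect_gte(bt$tT, wt_rates$th)
  expect_gte(bt$tL, bt$tdiff)
  # without the binding penalty leading binding is diffusion-limited
  bt1 <- binding_times(kin$sp, wt_rates, b = 1)
  expect_equal(bt1$tL, bt1$tdiff, tolerance = 1e-12)
})

test_that("trailing binding time rises to an interior maximum under load", {
  Fs <- c(0, 0.9, 1.8, 2.5)
  tT <- vapply(Fs, function(F) {
    myov_kinetics(wt_params, load_force(F), wt_rates, wt_lattice)$bt$tT
  }, numeric(1))
  expect_true(which.max(tT) %in% c(3))
  expect_gt(max(tT), 5 * tT[1])
  # leading binding approaches pure diffusion at high backward force
  kin_hi <- myov_kinetics(wt_params, load_force(2.2), wt_rates, wt_lattice)
  expect_lt(kin_hi$bt$tL / kin_hi$bt$tdiff, 1.1)
})
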