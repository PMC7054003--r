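test_that("binding-site positions follow the double-helix geometry", {
  lat <- wt_lattice
  expect_equal(unname(site_position(lat, 0)[1, ]), c(0, 0, 0))
  # half- and full-helical sites lie on the filament axis side (x = y = 0)
  expect_equal(unname(site_position(lat, 13)[1, ]), c(0, 0, 36),
               tolerance = 1e-12)
  expect_equal(unname(site_position(lat, 26)[1, ]), c(0, 0, 72),
               tolerance = 1e-12)
  # direct evaluation at n = 1
  expect_equal(unname(site_position(lat, 1)[1, ]),
               c(5.5 * (cos(-12 * pi / 13) - 1), 5.5 * sin(-12 * pi / 13),
                 36 / 13),
               tolerance = 1e-12)
  expect_equal(unname(site_position(lat, 1)[1, ]), c(-10.84, -1.316, 2.769),
               tolerance = 1e-3)
  # periodicity: one full repeat advances 72 nm with identical (x, y)
  p <- site_position(lat, -13:13)
  q <- site_position(lat, -13:13 + 26)
  expect_equal(q[, "x"], p[, "x"], tolerance = 1e-10)
  expect_equal(q[, "y"], p[, "y"], tolerance = 1e-10)
  expect_equal(q[, "z"] - p[, "z"], rep(72, 27), tolerance = 1e-10)
  # z strictly linear in n
  expect_true(all(diff(site_position(lat, lat$sites)[, "z"]) > 0))
  expect_error(site_position(lat, 40), "out of range")
})

test_that("even and odd sites form the two protofilaments", {
  lat <- wt_lattice
  even <- seq(-26, 26, by = 2)
  phi_even <- site_normal_azimuth(lat, even)
  # each protofilament has 13-fold azimuthal period
  expect_equal(phi_even[-(1:13)], phi_even[seq_len(length(even) - 13)],
               tolerance = 1e-10)
})

test_that("normal azimuths wrap to (-pi, pi]", {
  lat <- wt_lattice
  expect_equal(site_normal_azimuth(lat, 0), 0)
  expect_equal(site_normal_azimuth(lat, 13), 0, tolerance = 1e-12)
  expect_equal(site_normal_azimuth(lat, 1), -12 * pi / 13)
  phis <- site_normal_azimuth(lat, lat$sites)
  expect_true(all(phis > -pi & phis <= pi + 1e-12))
})

test_that("azimuthal acceptance window behaves as an angular interval", {
  d <- 55.6 * pi / 180
  # exact anti-parallel orientation is always accepted
  expect_true(acceptance_test(0.3 - pi, 0.3, d))
  # empty window rejects everything
  expect_false(acceptance_test(0.3 - pi, 0.3, 0))
  # boundary: offsets just inside/outside the half-width
  expect_true(acceptance_test(-pi + 55 * pi / 180, 0, d))
  expect_false(acceptance_test(-pi + 56 * pi / 180, 0, d))
  # asymmetric window
  expect_true(acceptance_test(-pi + 0.2, 0, delta1 = 0.3, delta2 = 0.05))
  expect_false(acceptance_test(-pi - 0.2, 0, delta1 = 0.3, delta2 = 0.05))
  expect_error(acceptance_test(0, 0, 4), "half-widths")
})

test_that("acceptance is invariant under 2*pi shifts of the free-leg azimuth", {
  set.seed(42)
  for (i in 1:50) {
    phi_f <- runif(1, -10, 10)
    phi_n <- runif(1, -pi, pi)
    d1 <- runif(1, 0, pi)
    base <- acceptance_test(phi_f, phi_n, d1)
    expect_identical(acceptance_test(phi_f + 2 * pi, phi_n, d1), base)
    expect_identical(acceptance_test(phi_f - 4 * pi, phi_n, d1), base)
  }
})

test_that("lattice construction validates inputs and exports a table", {
  expect_error(actin_lattice(n_max = 20), "n_max")
  expect_error(actin_lattice(R = -1))
  df <- as.data.frame(wt_lattice)
  expect_named(df, c("n", "x", "y", "z", "phi_n"))
  expect_equal(nrow(df), 2 * wt_lattice$n_max + 1)
})
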