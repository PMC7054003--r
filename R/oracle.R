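# Equilibrium Metropolis oracle for the discretized two-leg chain.
#
# Samples the same Hamiltonian terms as the mean-field theory but with an
# explicit bead-chain representation (no mean-field approximation), so it
# serves as an independent check of the analytical free-head density.

chain_par_list <- function(params, force, n_segments = 7,
                           use_hv = TRUE, explicit_ev = FALSE, sig_ev = 4,
                           coverslip = FALSE, x_wall = -11,
                           actin_ev = FALSE, r_actin = 5) {
  tc <- params$theta_c * pi / 180
  list(ns = as.integer(n_segments), L = params$L, lp = params$lp,
       nu_c = params$nu_c, mu_c = params$mu_c,
       theta_p_rad = params$theta_p * pi / 180, dV = params$dV,
       uc = c(sin(tc), 0, cos(tc)),
       fred = force$Fhat * force$F / params$kBT,
       use_hv = use_hv, explicit_ev = explicit_ev, sig_ev = sig_ev,
       coverslip = coverslip, x_wall = x_wall,
       actin_ev = actin_ev, r_actin = r_actin, ax_x = -5.5)
}

#' Metropolis sampling of the discretized two-leg chain
#'
#' Equilibrium samples of the free-head position (and free-leg azimuth and
#' inter-leg angle) for the bead-chain representation of the motor:
#' discrete worm-like-chain bending, the bound-leg tangent constraint, the
#' inter-leg chord-angle potential, head--head exclusion, and the load force
#' applied at the joint. Deterministic given \code{seed}. Serves as the
#' independent oracle for \code{\link{free_head_density}}.
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param n_samples number of recorded samples (>= 1e5 recommended for
#'   coarse-grid density comparisons).
#' @param seed integer seed.
#' @param thin sweeps between samples.
#' @param burn burn-in sweeps.
#' @param n_segments beads per leg (NULL: one per 5 nm of contour).
#' @param step_size Metropolis rotation scale, radians.
#' @param use_hv include the effective head--head \code{(dV/r)^6} weight.
#' @param explicit_ev replace it by explicit leg--leg bead exclusion.
#' @param sig_ev bead--bead exclusion length, nm.
#' @param coverslip,x_wall optional hard wall excluding \code{x < x_wall}.
#' @return object of class \code{chain_mc}: matrix \code{samples} with
#'   columns x, y, z (head position, nm), phi_f, theta_J (radians);
#'   acceptance rate; and an autocorrelation-based effective sample size
#'   (a warning is issued if it is small).
#' @export
density_oracle_mc <- function(params, force = load_force(),
                              n_samples = 2e5, seed = 1, thin = 5,
                              burn = 2000, n_segments = NULL,
                              step_size = 0.35,
                              use_hv = TRUE, explicit_ev = FALSE, sig_ev = 4,
                              coverslip = FALSE, x_wall = -11) {
  if (is.null(n_segments)) n_segments <- max(3L, as.integer(round(params$L / 5)))
  par <- chain_par_list(params, force, n_segments, use_hv, explicit_ev,
                        sig_ev, coverslip, x_wall)
  res <- cpp_chain_mc(par, n_samples, as.integer(thin), as.integer(burn),
                      step_size, seed)
  sm <- res$samples
  colnames(sm) <- c("x", "y", "z", "phi_f", "theta_J")
  # equilibration diagnostic: integrated autocorrelation of head z
  zc <- sm[, "z"]
  n_use <- min(length(zc), 5000L)
  ac <- stats::acf(zc[seq_len(n_use)], lag.max = 100, plot = FALSE)$acf[, 1, 1]
  tau <- 1 + 2 * sum(pmax(ac[-1], 0))
  ess <- n_samples / tau
  if (ess < 1000)
    warning(sprintf("chain may not be equilibrated: effective sample size %.0f", ess))
  structure(list(samples = sm, acceptance = res$acceptance, ess = ess,
                 seed = seed, params = params, force = force),
            class = "chain_mc")
}

#' @export
print.chain_mc <- function(x, ...) {
  cat(sprintf("chain Metropolis oracle: %d samples, acceptance %.2f, ESS %.0f\n",
              nrow(x$samples), x$acceptance, x$ess))
  invisible(x)
}

#' Kullback-Leibler check of the mean-field density against the chain oracle
#'
#' Bins Metropolis samples of the discretized chain on a coarse 3D grid and
#' compares them with the cell-averaged mean-field density over the occupied
#' cells (cell averaging avoids spurious divergence at the hard reachability
#' edge |r| = 2L, where point evaluation at a cell center misrepresents the
#' cell mass). The oracle chain uses 2.5 nm segments by default so that its
#' discretization error is small compared to the mean-field approximation
#' being tested.
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param spacing grid spacing, nm.
#' @param n_samples Metropolis samples.
#' @param seed integer seed.
#' @param n_segments oracle segments per leg.
#' @param subdiv per-axis subdivisions for cell-averaging the analytic
#'   density.
#' @param model optional precomputed \code{\link{density_model}}.
#' @return list with \code{kl} (nats, sampled distribution against the
#'   mean-field), occupied-cell count, and the effective sample size.
#' @export
oracle_kl <- function(params, force = load_force(), spacing = 3,
                      n_samples = 1e6, seed = 1, n_segments = 14,
                      subdiv = 2, model = NULL) {
  mc <- density_oracle_mc(params, force, n_samples, seed, thin = 3,
                          n_segments = n_segments)
  if (is.null(model)) model <- density_model(params, force)
  lim <- 2 * params$L + spacing
  ax <- seq(-lim, lim, by = spacing)
  axes <- list(x = ax, y = ax, z = ax)
  cnt <- bin_samples_3d(mc$samples[, 1:3], axes)
  occ <- which(cnt > 0, arr.ind = TRUE)
  centers <- cbind(ax[occ[, 1]], ax[occ[, 2]], ax[occ[, 3]])
  off <- (seq_len(subdiv) - (subdiv + 1) / 2) / subdiv * spacing
  sub <- as.matrix(expand.grid(off, off, off))
  Q <- numeric(nrow(centers))
  for (s in seq_len(nrow(sub))) {
    pts <- sweep(centers, 2, sub[s, ], `+`)
    Q <- Q + density_eval(model, pts)
  }
  Q <- Q / nrow(sub) * spacing^3
  P <- cnt[occ] / sum(cnt)
  # conditional KL over the jointly occupied support (covers ~all the mass)
  ok <- Q > 0
  kl <- sum(P[ok] * log((P[ok] / sum(P[ok])) / (Q[ok] / sum(Q[ok]))))
  # cells the mean field cannot reach at all count via a floor of one count
  if (any(!ok))
    kl <- kl + sum(P[!ok]) * log(sum(cnt))
  list(kl = kl, n_cells = nrow(centers), ess = mc$ess,
       mass_covered = sum(Q))
}

#' Bin samples onto the axes of a density grid
#'
#' @param xyz matrix with columns x, y, z.
#' @param axes list of grid-center vectors (as in a \code{density_grid}).
#' @return 3D array of counts with the same dimensions as the grid values.
#' @export
bin_samples_3d <- function(xyz, axes) {
  h <- axes$x[2] - axes$x[1]
  brk <- function(ax) c(ax - h / 2, ax[length(ax)] + h / 2)
  ix <- findInterval(xyz[, 1], brk(axes$x), rightmost.closed = TRUE)
  iy <- findInterval(xyz[, 2], brk(axes$y), rightmost.closed = TRUE)
  iz <- findInterval(xyz[, 3], brk(axes$z), rightmost.closed = TRUE)
  nx <- length(axes$x); ny <- length(axes$y); nz <- length(axes$z)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
  counts <- array(0, dim = c(nx, ny, nz))
  tb <- table((ix[ok] - 1) + nx * (iy[ok] - 1) + nx * ny * (iz[ok] - 1))
  counts[as.integer(names(tb)) + 1] <- as.integer(tb)
  counts
}
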