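# Coarse-grained Brownian dynamics of the two-leg chain: diffusive search
# trajectories with the full conical binding criterion, ensemble contours,
# and estimation of the effective head-head exclusion length dV.

#' Brownian-dynamics simulation settings
#'
#' @param dt time step, ns (the default keeps the average per-component
#'   bead displacement sqrt(2 D dt) below 0.1 nm at the default head
#'   diffusivity).
#' @param n_beads_per_leg beads per leg; NULL (default) uses one bead per
#'   5 nm of contour (the size of the head and of each IQ motif), i.e. 5,
#'   7, 9 for the 4IQ, 6IQ, 8IQ constructs.
#' @param max_time maximal simulated search time, ms.
#' @param seed integer seed.
#' @param coverslip \code{FALSE} or a plane position (nm): excludes
#'   \code{x < coverslip}.
#' @param record_stride trajectory recording interval, ns (0 = record off).
#' @param kbond bond spring constant, kBT/nm^2.
#' @param actin_ev include actin cylinder excluded volume.
#' @return list of settings (class \code{bd_settings}).
#' @export
bd_settings <- function(dt = 0.085, n_beads_per_leg = NULL, max_time = 2,
                        seed = 1, coverslip = FALSE, record_stride = 0,
                        kbond = 30, actin_ev = FALSE) {
  stopifnot(dt > 0, is.null(n_beads_per_leg) || n_beads_per_leg >= 3,
            max_time > 0)
  structure(list(dt = dt,
                 n_beads_per_leg = if (is.null(n_beads_per_leg)) NULL
                                   else as.integer(n_beads_per_leg),
                 max_time = max_time, seed = seed, coverslip = coverslip,
                 record_stride = record_stride, kbond = kbond,
                 actin_ev = actin_ev),
            class = "bd_settings")
}

resolve_beads <- function(params, settings) {
  if (is.null(settings$n_beads_per_leg)) max(3L, as.integer(round(params$L / 5)))
  else settings$n_beads_per_leg
}

bd_init_positions <- function(params, settings, start, lattice) {
  ns <- resolve_beads(params, settings)
  b0 <- params$L / ns
  tc <- params$theta_c * pi / 180
  uc <- c(sin(tc), 0, cos(tc))
  pos <- matrix(0, nrow = 2 * ns + 1, ncol = 3)
  for (i in 1:ns) pos[i + 1, ] <- i * b0 * uc
  joint <- pos[ns + 1, ]
  target <- site_position(lattice, start)[1, ]
  dirv <- target - joint
  nd <- sqrt(sum(dirv^2))
  dirv <- if (nd > 1e-9) dirv / nd else c(0, 0, -1)
  for (i in 1:ns) pos[ns + 1 + i, ] <- joint + i * b0 * dirv
  pos
}

bd_D_per_ns <- function(params) params$Dh * 1e-6  # nm^2/ms -> nm^2/ns

#' Simulate one diffusive search step with Brownian dynamics
#'
#' Overdamped Langevin trajectories of the bead-chain motor after head
#' detachment: the bound leg holds the post-power-stroke constraint, the
#' free head searches until it reaches a binding site within the capture
#' radius with the free leg inside the conical acceptance region (angle to
#' the outward site normal below \code{dphi_ac}); binding against the
#' recovery-stroke orientation succeeds with probability \code{b}, and for
#' the trailing leg binding is gated by ATP hydrolysis.
#'
#' @param params \code{\link{motor_params}}.
#' @param rates \code{\link{kinetic_rates}} (supplies the hydrolysis time).
#' @param lattice \code{\link{actin_lattice}}.
#' @param force \code{\link{load_force}}.
#' @param settings \code{\link{bd_settings}}.
#' @param detached \code{"trailing"} or \code{"leading"}.
#' @param n_traj number of independent trajectories.
#' @param start_site site index the detached head starts from (default one
#'   half-helical repeat behind/ahead of the bound head).
#' @param hydrolyzed if TRUE (default) the trajectory starts with hydrolysis
#'   already completed, sampling the post-hydrolysis binding-site
#'   distribution directly; if FALSE an exponential hydrolysis time is drawn
#'   and binding is disallowed before it.
#' @param noise_scale multiplies the thermal noise amplitude (0 gives the
#'   deterministic gradient-descent limit).
#' @param check_stride steps between binding checks.
#' @return data.frame with one row per trajectory: \code{site} (bound index
#'   or NA), \code{t_ms} (binding time, NA if none), \code{outcome}.
#' @export
simulate_step <- function(params = motor_params(), rates = kinetic_rates(),
                          lattice = actin_lattice(), force = load_force(),
                          settings = bd_settings(),
                          detached = c("trailing", "leading"), n_traj = 1,
                          start_site = NULL, hydrolyzed = TRUE,
                          noise_scale = 1, check_stride = 2L) {
  detached <- match.arg(detached)
  if (is.null(start_site)) start_site <- if (detached == "trailing") -13 else 13
  nbl <- resolve_beads(params, settings)
  par <- chain_par_list(params, force, nbl,
                        use_hv = TRUE,
                        coverslip = !isFALSE(settings$coverslip),
                        x_wall = if (isFALSE(settings$coverslip)) -11
                                 else settings$coverslip,
                        actin_ev = settings$actin_ev)
  ns_idx <- setdiff(lattice$sites, 0L)
  pos <- site_position(lattice, ns_idx)
  phin <- site_normal_azimuth(lattice, ns_idx)
  ord <- order(pos[, "z"])
  pos <- pos[ord, , drop = FALSE]
  phin <- phin[ord]
  ns_idx <- ns_idx[ord]
  penal <- if (detached == "trailing") as.integer(ns_idx < 0)
           else as.integer(ns_idx > 0)
  init <- bd_init_positions(params, settings, start_site, lattice)
  out <- data.frame(site = rep(NA_integer_, n_traj), t_ms = NA_real_,
                    outcome = character(n_traj))
  set.seed(settings$seed)
  hyd_ms <- if (detached == "trailing" && !hydrolyzed)
    rexp(n_traj, 1 / rates$th) else rep(0, n_traj)
  for (k in seq_len(n_traj)) {
    res <- cpp_bd_run(par, settings$kbond, bd_D_per_ns(params), settings$dt,
                      settings$max_time * 1e6, pos, phin, params$a,
                      params$dphi_ac * pi / 180, params$b, penal,
                      hyd_ms[k] * 1e6, TRUE, settings$record_stride,
                      settings$seed * 1e6 + k, init, noise_scale,
                      check_stride)
    if (res$max_step_nm > 0.5 * params$L / nbl)
      stop("BD integrator instability (bond stretch > 50%): decrease dt")
    if (!is.na(res$site_row)) {
      out$site[k] <- ns_idx[res$site_row]
      out$t_ms[k] <- res$t_ms + hyd_ms[k]
      out$outcome[k] <- "bound"
    } else {
      out$outcome[k] <- "timeout"
    }
  }
  out
}

#' Equilibrium BD sampling of the free head (no binding)
#'
#' @inheritParams simulate_step
#' @param t_total total simulated time, ms.
#' @param record_stride recording interval, ns.
#' @param burn_ms discarded initial relaxation, ms.
#' @param use_hv,explicit_ev,sig_ev exclusion options as in
#'   \code{\link{density_oracle_mc}}.
#' @param noise_scale multiplies the thermal noise amplitude.
#' @param start_site lattice site the free leg initially points toward.
#' @return matrix of recorded head positions (columns x, y, z).
#' @export
bd_equilibrium_sample <- function(params = motor_params(),
                                  force = load_force(),
                                  settings = bd_settings(), t_total = 0.5,
                                  record_stride = 50, burn_ms = 0.02,
                                  use_hv = TRUE, explicit_ev = FALSE,
                                  sig_ev = 4, noise_scale = 1,
                                  start_site = -13) {
  nbl <- resolve_beads(params, settings)
  par <- chain_par_list(params, force, nbl,
                        use_hv = use_hv, explicit_ev = explicit_ev,
                        sig_ev = sig_ev,
                        coverslip = !isFALSE(settings$coverslip),
                        x_wall = if (isFALSE(settings$coverslip)) -11
                                 else settings$coverslip,
                        actin_ev = settings$actin_ev)
  init <- bd_init_positions(params, settings, start_site, actin_lattice())
  dummy_sites <- matrix(c(0, 0, 1e6), 1, 3)
  res <- cpp_bd_run(par, settings$kbond, bd_D_per_ns(params), settings$dt,
                    t_total * 1e6, dummy_sites, 0, 0.01, pi, 1, 0L,
                    0, FALSE, record_stride, settings$seed, init,
                    noise_scale, 2L)
  if (res$max_step_nm > 0.5 * params$L / nbl)
    stop("BD integrator instability (bond stretch > 50%): decrease dt")
  tr <- res$trajectory
  colnames(tr) <- c("x", "y", "z")
  tr[-seq_len(min(nrow(tr) - 1, ceiling(burn_ms * 1e6 / record_stride))), ,
     drop = FALSE]
}

#' Ensemble diffusion contours from BD trajectories
#'
#' Time-weighted 2D histogram of the free-head position over an ensemble of
#' equilibrium BD trajectories.
#'
#' @inheritParams bd_equilibrium_sample
#' @param n_traj number of trajectories (different seeds).
#' @param plane projection plane as in \code{\link{project_density}}
#'   (\code{"z-x"}, \code{"z-y"}, \code{"y-x"}).
#' @param spacing histogram bin size, nm.
#' @param burn_ms discarded initial relaxation per trajectory, ms.
#' @param start_sites detachment sites cycled across trajectories (the two
#'   physical starts, behind and ahead of the bound head; alternating them
#'   decorrelates the slow swing of the compass arc).
#' @return list with axes \code{u}, \code{v} and normalized density matrix
#'   \code{values} (per nm^2).
#' @export
ensemble_contours <- function(params = motor_params(), force = load_force(),
                              settings = bd_settings(), n_traj = 100,
                              t_total = 0.35, plane = "z-x", spacing = 3,
                              record_stride = 50, burn_ms = 0.05,
                              start_sites = c(-13, 13)) {
  cols <- switch(plane, "z-x" = c("z", "x"), "z-y" = c("z", "y"),
                 "y-x" = c("y", "x"),
                 stop("unknown plane for BD contours: ", plane))
  lim <- 2 * params$L + 5
  ax <- seq(-lim, lim, by = spacing)
  counts <- matrix(0, length(ax), length(ax))
  for (k in seq_len(n_traj)) {
    st <- settings
    st$seed <- settings$seed + k - 1
    tr <- bd_equilibrium_sample(params, force, st, t_total, record_stride,
                                burn_ms = burn_ms,
                                start_site =
                                  start_sites[(k - 1) %% length(start_sites) + 1])
    iu <- findInterval(tr[, cols[1]], c(ax - spacing / 2, lim + spacing / 2),
                       rightmost.closed = TRUE)
    iv <- findInterval(tr[, cols[2]], c(ax - spacing / 2, lim + spacing / 2),
                       rightmost.closed = TRUE)
    ok <- iu >= 1 & iu <= length(ax) & iv >= 1 & iv <= length(ax)
    for (ii in which(ok)) counts[iu[ii], iv[ii]] <- counts[iu[ii], iv[ii]] + 1
  }
  list(u = ax, v = ax, values = counts / (sum(counts) * spacing^2),
       plane = plane, n_traj = n_traj)
}

#' Estimate the effective head-head exclusion length dV
#'
#' Samples the chain with explicit leg-leg bead exclusion (and the effective
#' head-head term switched off), and again with no exclusion at all, then
#' fits \code{-log} of the head-head distance distribution ratio to the
#' \code{(dV/r)^6} Boltzmann weight (linear fit in \code{r^-6} with an
#' intercept absorbing normalization).
#'
#' @param params \code{\link{motor_params}}.
#' @param settings \code{\link{bd_settings}} (seed is used).
#' @param n_samples Metropolis samples per condition.
#' @param sig_ev bead-bead exclusion length, nm (the legs' contact
#'   distance).
#' @param explicit_ev if FALSE the exclusion is disabled (the fitted dV then
#'   collapses toward zero, a consistency check).
#' @return list with \code{dV} (nm), the fit table, and the relative
#'   residual; a warning is issued if the (dV/r)^6 form fits poorly.
#' @export
estimate_dV <- function(params = motor_params(), settings = bd_settings(),
                        n_samples = 2e5, sig_ev = 5, explicit_ev = TRUE) {
  base <- density_oracle_mc(params, load_force(0), n_samples,
                            seed = settings$seed, use_hv = FALSE,
                            explicit_ev = FALSE)
  excl <- density_oracle_mc(params, load_force(0), n_samples,
                            seed = settings$seed + 1, use_hv = FALSE,
                            explicit_ev = explicit_ev, sig_ev = sig_ev)
  r0 <- sqrt(rowSums(base$samples[, 1:3]^2))
  r1 <- sqrt(rowSums(excl$samples[, 1:3]^2))
  brk <- seq(0, 2 * params$L, length.out = 41)
  h0 <- hist(r0, breaks = brk, plot = FALSE)$counts
  h1 <- hist(r1, breaks = brk, plot = FALSE)$counts
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  ok <- h0 >= 50 & h1 >= 5
  y <- log(h0[ok] / sum(h0)) - log(h1[ok] / sum(h1))
  x <- mid[ok]^-6
  # fit the shoulder of the repulsion (suppression between e^-3 and
  # e^-0.05), the region that defines an effective exclusion length; deeper
  # bins deviate from the power-law form and carry few counts
  sh <- y > 0.05 & y < 3
  if (sum(sh) >= 5) { y <- y[sh]; x <- x[sh]; ok <- which(ok)[sh] }
  else ok <- which(ok)
  # count-based weights: var(log ratio) ~ 1/n0 + 1/n1 per bin, so the
  # poorly populated small-r bins do not dominate through their huge r^-6
  w <- 1 / (1 / h0[ok] + 1 / h1[ok])
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2])
  dV <- if (slope > 0) slope^(1 / 6) else 0
  resid_rel <- sqrt(stats::weighted.mean(residuals(fit)^2, w)) /
    max(sqrt(stats::weighted.mean((y - stats::weighted.mean(y, w))^2, w)),
        1e-12)
  if (resid_rel > 0.2)
    warning(sprintf("(dV/r)^6 form fits poorly (relative residual %.2f)",
                    resid_rel))
  list(dV = dV, fit = data.frame(r = mid[ok], log_ratio = y),
       relative_residual = resid_rel, sig_ev = sig_ev)
}
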