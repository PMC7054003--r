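# Step/stomp distributions, run statistics, parameter scans, and a kinetic
# Monte-Carlo run simulator built on the five-pathway network.

#' One-call kinetic state of the motor
#'
#' Convenience pipeline: density model, site first-passage times, pathway
#' probabilities and binding times for one parameter/force setting.
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param quad quadrature settings passed to \code{\link{density_model}}.
#' @return object of class \code{myov_kinetics}: list with \code{model},
#'   \code{sp} (site passage), \code{pp} (pathway probabilities), \code{bt}
#'   (binding times) and the inputs.
#' @export
myov_kinetics <- function(params = motor_params(), force = load_force(),
                          rates = kinetic_rates(), lattice = actin_lattice(),
                          quad = NULL) {
  model <- if (is.null(quad)) density_model(params, force)
           else density_model(params, force, quad)
  sp <- first_passage_times(params, force, lattice, model)
  pp <- pathway_probabilities(sp, rates)
  bt <- binding_times(sp, rates)
  structure(list(model = model, sp = sp, pp = pp, bt = bt, params = params,
                 force = force, rates = rates, lattice = lattice),
            class = "myov_kinetics")
}

# internal: per-site probabilities as dense vectors over n = -n_max..n_max
dense_pathway_vectors <- function(pp, lattice) {
  n_all <- lattice$sites
  pT <- pL <- numeric(length(n_all))
  idx <- match(pp$table$n, n_all)
  pT[idx] <- pp$table$pT
  pL[idx] <- pp$table$pL
  list(n = n_all, pT = pT, pL = pL)
}

#' Head-separation (raw step) distribution
#'
#' Probability of observing the bound motor with \code{n} subunits between
#' the two heads, renormalized to remove the termination pathway:
#' \code{Pdist_n = [g/(1+g)](PT_n + PT_-n) + [1/(1+g)](PL_n + PL_-n)},
#' \code{n > 0}.
#'
#' @param pp \code{\link{pathway_probabilities}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param max_separation optional cap on the head separation in subunits
#'   (used for the "small steps" 8IQ variant where separations above 18
#'   subunits are not resolved experimentally).
#' @return object of class \code{step_distribution} with support \code{n},
#'   axial positions \code{z = n dz/2} and normalized \code{mass}.
#' @export
head_separation_distribution <- function(pp, lattice = actin_lattice(),
                                         max_separation = NULL) {
  v <- dense_pathway_vectors(pp, lattice)
  g <- pp$g
  np <- v$n[v$n > 0]
  iplus <- match(np, v$n)
  iminus <- match(-np, v$n)
  mass <- g / (1 + g) * (v$pT[iplus] + v$pT[iminus]) +
    1 / (1 + g) * (v$pL[iplus] + v$pL[iminus])
  if (!is.null(max_separation)) mass[np > max_separation] <- 0
  if (sum(mass) <= 0) stop("no bound-state pathway mass")
  mass <- mass / sum(mass)
  structure(list(n = np, z = np * lattice$dz / 2, mass = mass,
                 kind = "raw-separation"),
            class = "step_distribution")
}

#' @export
print.step_distribution <- function(x, ...) {
  m <- sum(x$z * x$mass) / sum(x$mass)
  cat(sprintf("step distribution (%s): support %d..%d, total mass %.4g, mean z %.2f nm\n",
              x$kind, min(x$n), max(x$n), sum(x$mass), m))
  invisible(x)
}

# discrete linear convolution of two distributions given as (n, mass) pairs
convolve_support <- function(nA, mA, nB, mB) {
  lo <- min(nA) + min(nB)
  hi <- max(nA) + max(nB)
  out <- numeric(hi - lo + 1)
  for (i in seq_along(nA)) {
    k <- nA[i] + nB - lo + 1
    out[k] <- out[k] + mA[i] * mB
  }
  list(n = lo:hi, mass = out)
}

#' Step-size distributions (trailing, leading, combined, forward-only)
#'
#' The distance moved by the stepping head is the head separation at
#' detachment plus the separation at rebinding, so the step distribution is
#' a convolution: trailing \code{(Pdist * PT)[n]}, leading
#' \code{(P-dist * PL)[n]} with \code{P-dist_n = Pdist_-n}, and the combined
#' distribution is their \code{g/(1+g)}, \code{1/(1+g)} mixture. The
#' forward-only variant zeroes backward binding (\code{PT_n = 0}, n < 0)
#' before convolving, mimicking experimental forward-step selections, and is
#' normalized; the other kinds keep their raw pathway mass (summing to
#' \code{1 - Pt} for \code{"combined"}) so that run statistics can reuse
#' them.
#'
#' @param pp \code{\link{pathway_probabilities}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param mode one of \code{"trailing"}, \code{"leading"},
#'   \code{"combined"}, \code{"forward-only"}.
#' @param max_separation optional head-separation cap (subunits) applied to
#'   the separation distribution before convolving.
#' @return \code{step_distribution} on the axial grid \code{z_n = n dz/2}.
#' @export
step_distribution <- function(pp, lattice = actin_lattice(),
                              mode = c("combined", "trailing", "leading",
                                       "forward-only"),
                              max_separation = NULL) {
  mode <- match.arg(mode)
  v <- dense_pathway_vectors(pp, lattice)
  sep <- head_separation_distribution(pp, lattice, max_separation)
  g <- pp$g
  wT <- g / (1 + g)
  wL <- 1 / (1 + g)
  if (mode == "trailing") {
    cv <- convolve_support(sep$n, sep$mass, v$n, v$pT)
  } else if (mode == "leading") {
    cv <- convolve_support(-sep$n, sep$mass, v$n, v$pL)
  } else if (mode == "combined") {
    cvT <- convolve_support(sep$n, sep$mass, v$n, v$pT)
    cvL <- convolve_support(-sep$n, sep$mass, v$n, v$pL)
    lo <- min(cvT$n[1], cvL$n[1])
    hi <- max(cvT$n[length(cvT$n)], cvL$n[length(cvL$n)])
    mass <- numeric(hi - lo + 1)
    mass[cvT$n - lo + 1] <- wT * cvT$mass
    mass[cvL$n - lo + 1] <- mass[cvL$n - lo + 1] + wL * cvL$mass
    cv <- list(n = lo:hi, mass = mass)
  } else {
    pTf <- ifelse(v$n > 0, v$pT, 0)
    cv <- convolve_support(sep$n, sep$mass, v$n, pTf)
    cv$mass <- cv$mass / sum(cv$mass)
  }
  structure(list(n = cv$n, z = cv$n * lattice$dz / 2, mass = cv$mass,
                 kind = mode),
            class = "step_distribution")
}

#' Convolve a step distribution with measurement noise and bin it
#'
#' Gaussian localization noise (closed-form normal CDF differences per bin)
#' followed by histogramming; total mass is preserved.
#'
#' @param dist \code{step_distribution}.
#' @param sigma measurement noise standard deviation, nm (1 nm emulates
#'   FIONA localization error).
#' @param bin_width histogram bin width, nm.
#' @param range optional c(lo, hi) bin range, nm.
#' @return data.frame with \code{z} (bin centers), \code{mass}.
#' @export
measurement_convolve <- function(dist, sigma = 1, bin_width = 5,
                                 range = NULL) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(range)) range <- c(min(dist$z) - 3 * sigma - bin_width,
                                 max(dist$z) + 3 * sigma + bin_width)
  edges <- seq(range[1], range[2] + bin_width, by = bin_width)
  k <- length(edges) - 1
  mass <- numeric(k)
  if (sigma == 0) {
    bin <- findInterval(dist$z, edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= k
    for (i in which(ok)) mass[bin[i]] <- mass[bin[i]] + dist$mass[i]
  } else {
    for (i in seq_along(dist$z)) {
      p <- pnorm(edges, mean = dist$z[i], sd = sigma)
      mass <- mass + dist$mass[i] * diff(p)
    }
  }
  data.frame(z = edges[-length(edges)] + bin_width / 2, mass = mass)
}

#' Run-level observables
#'
#' Mean run length \code{z_run = (1/2) sum z_n P(z_n) / (Pt (1 - Pt))} (the
#' center of mass moves half the head displacement), mean run time with
#' waiting time \code{t_wait = g td1/(1+g)} between detachments, run
#' velocity, mean step count \code{1/Pt} and the backward/forward step
#' ratio.
#'
#' @param pp \code{\link{pathway_probabilities}}.
#' @param dist combined \code{step_distribution} carrying raw pathway mass.
#' @param bt binding times from \code{\link{binding_times}}.
#' @param rates \code{\link{kinetic_rates}}.
#' @return object of class \code{run_observables}.
#' @export
run_statistics <- function(pp, dist, bt, rates = kinetic_rates()) {
  if (dist$kind != "combined")
    stop("run_statistics needs the combined step distribution")
  Pt <- pp$Pt
  if (Pt <= 0) stop("termination probability is zero: infinite run")
  if (Pt >= 1) warning("termination certain: motor takes no steps")
  g <- rates$g
  wT <- g / (1 + g)
  wL <- 1 / (1 + g)
  twait <- g * rates$td1 / (1 + g)
  ST <- sum(pp$table$pT)
  SL <- sum(pp$table$pL)
  z_run <- 0.5 * sum(dist$z * dist$mass) / (Pt * (1 - Pt))
  t_run <- (wT * ST * (twait + bt$tT) + wL * SL * (twait + bt$tL)) /
    (Pt * (1 - Pt))
  structure(list(z_run = z_run, t_run = t_run, v_run = z_run / t_run,
                 N_run = 1 / Pt, step_ratio = pp$Pb / pp$Pf,
                 t_wait = twait, Pt = Pt),
            class = "run_observables")
}

#' @export
print.run_observables <- function(x, ...) {
  cat(sprintf("run: z_run = %.3g nm, t_run = %.3g ms, v_run = %.3g nm/ms\n",
              x$z_run, x$t_run, x$v_run))
  cat(sprintf("     <N> = %.3g steps, Pb/Pf = %.3g, t_wait = %.3g ms\n",
              x$N_run, x$step_ratio, x$t_wait))
  invisible(x)
}

# internal: z_run and step ratio at one force setting
run_at_force <- function(params, force, rates, lattice, quad = NULL) {
  kin <- myov_kinetics(params, force, rates, lattice, quad)
  dist <- step_distribution(kin$pp, lattice, "combined")
  rs <- run_statistics(kin$pp, dist, kin$bt, rates)
  list(kin = kin, dist = dist, rs = rs)
}

#' Stall force
#'
#' The backward force at which the mean run length crosses zero, found by
#' bisection; also reports the force at which the backward/forward step
#' ratio equals one (experimentally these coincide).
#'
#' @param params \code{\link{motor_params}}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param bracket force bracket, pN.
#' @param tol bisection tolerance, pN.
#' @return list with \code{F_stall} (z_run = 0), \code{F_ratio1}
#'   (Pb/Pf = 1), both in pN.
#' @export
stall_force <- function(params = motor_params(), rates = kinetic_rates(),
                        lattice = actin_lattice(), bracket = c(0.5, 3),
                        tol = 1e-3) {
  fz <- function(F) run_at_force(params, load_force(F), rates, lattice)$rs$z_run
  fr <- function(F) {
    kin <- myov_kinetics(params, load_force(F), rates, lattice)
    log(kin$pp$Pb / kin$pp$Pf)
  }
  bisect <- function(f) {
    lo <- bracket[1]; hi <- bracket[2]
    flo <- f(lo); fhi <- f(hi)
    if (flo * fhi > 0) stop("stall bracket does not contain a sign change")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
    }
    (lo + hi) / 2
  }
  list(F_stall = bisect(fz), F_ratio1 = bisect(fr))
}

#' Run-length response to off-axis load direction
#'
#' Percent change of the mean run length when a load of fixed magnitude is
#' rotated away from the backward direction:
#' \code{100 (z_run(thetaF, phiF)/z_run(0,0) - 1)}.
#'
#' @param params \code{\link{motor_params}}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param F load magnitude, pN (1 pN default).
#' @param theta_F,phi_F grids of polar/azimuthal angles, degrees.
#' @param lattice \code{\link{actin_lattice}}.
#' @return list with the angle grids and a \code{percent} matrix
#'   (rows = theta_F, cols = phi_F).
#' @export
offaxis_scan <- function(params = motor_params(), rates = kinetic_rates(),
                         F = 1, theta_F = seq(0, 40, by = 4),
                         phi_F = seq(-90, 90, by = 15),
                         lattice = actin_lattice()) {
  z0 <- run_at_force(params, load_force(F, 0, 0), rates, lattice)$rs$z_run
  pc <- matrix(NA_real_, length(theta_F), length(phi_F),
               dimnames = list(theta_F, phi_F))
  for (i in seq_along(theta_F)) for (j in seq_along(phi_F)) {
    z <- run_at_force(params, load_force(F, theta_F[i], phi_F[j]),
                      rates, lattice)$rs$z_run
    pc[i, j] <- 100 * (z / z0 - 1)
  }
  list(theta_F = theta_F, phi_F = phi_F, percent = pc, F = F, z_run0 = z0)
}

#' Scan of the inter-leg constraint strength
#'
#' Width (standard deviation) of the forward-only step distribution and the
#' trailing-leg mean binding time at zero load, as functions of the joint
#' constraint strength and preferred angle.
#'
#' @param params \code{\link{motor_params}} (its \code{mu_c}/\code{theta_p}
#'   are overridden by the scan values).
#' @param rates \code{\link{kinetic_rates}}.
#' @param mu_c vector of constraint strengths, kBT.
#' @param theta_p vector of preferred angles, degrees.
#' @param lattice \code{\link{actin_lattice}}.
#' @return data.frame with columns mu_c, theta_p, sigma_step (nm), tT (ms).
#' @export
constraint_scan <- function(params = motor_params(), rates = kinetic_rates(),
                            mu_c = 0:10, theta_p = 83,
                            lattice = actin_lattice()) {
  out <- expand.grid(mu_c = mu_c, theta_p = theta_p)
  out$sigma_step <- NA_real_
  out$tT <- NA_real_
  for (i in seq_len(nrow(out))) {
    p <- params
    p$mu_c <- out$mu_c[i]
    p$theta_p <- out$theta_p[i]
    kin <- myov_kinetics(p, load_force(0), rates, lattice)
    fwd <- step_distribution(kin$pp, lattice, "forward-only")
    mu <- sum(fwd$z * fwd$mass)
    out$sigma_step[i] <- sqrt(sum((fwd$z - mu)^2 * fwd$mass))
    out$tT[i] <- kin$bt$tT
  }
  out
}

#' Kinetic Monte-Carlo simulation of processive runs
#'
#' Samples the five-pathway network event by event: exponential waiting
#' times for head detachment, the hydrolysis gate and the binding race, and
#' per-site binding targets, until the run terminates. Under the
#' \code{"trap"} force rule the load magnitude grows linearly with the
#' distance walked from the start (optical-trap emulation) and the trap
#' anchor is shifted off-axis after two steps.
#'
#' @param params \code{\link{motor_params}}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param n_runs number of independent runs.
#' @param seed integer RNG seed (deterministic output per seed).
#' @param force_rule \code{"constant"} or \code{"trap"}.
#' @param force \code{\link{load_force}} used for \code{"constant"}.
#' @param trap list for \code{"trap"}: \code{stiffness} (pN/nm),
#'   \code{offaxis_y} (nm, lateral anchor shift applied after two steps).
#' @param lattice \code{\link{actin_lattice}}.
#' @param max_events safety cap on events per run.
#' @param force_grid rounding (pN, degrees) used to cache kinetic states
#'   under the trap rule.
#' @return object of class \code{mc_runs}: data.frame \code{runs} with
#'   per-run length (nm, center of mass), time (ms), n_steps (binding
#'   events), and the termination force magnitude (pN); plus the step
#'   record of the first run.
#' @export
run_monte_carlo <- function(params = motor_params(), rates = kinetic_rates(),
                            n_runs = 100, seed = 1,
                            force_rule = c("constant", "trap"),
                            force = load_force(0),
                            trap = list(stiffness = 0.02, offaxis_y = 50),
                            lattice = actin_lattice(), max_events = 10000,
                            force_grid = c(0.05, 5)) {
  force_rule <- match.arg(force_rule)
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  get_state <- function(f) {
    key <- sprintf("%.6g_%.6g_%.6g", f$F, f$theta_F, f$phi_F)
    if (!is.null(cache[[key]])) return(cache[[key]])
    kin <- myov_kinetics(params, f, rates, lattice)
    st <- list(tb = kin$sp$table, bt = kin$bt,
               rT = kin$pp$rT, rL = kin$pp$rL)
    cache[[key]] <- st
    st
  }
  round_force <- function(f) {
    load_force(round(f$F / force_grid[1]) * force_grid[1],
               round(f$theta_F / force_grid[2]) * force_grid[2],
               round(f$phi_F / force_grid[2]) * force_grid[2])
  }
  td1 <- rates$td1; td2 <- rates$td2; th <- rates$th
  runs <- data.frame(length = numeric(n_runs), time = numeric(n_runs),
                     n_steps = integer(n_runs), F_end = numeric(n_runs))
  first_steps <- NULL
  for (r in seq_len(n_runs)) {
    # head axial positions in subunit indices: trailing at s1, leading at s2
    s1 <- -13; s2 <- 0
    t_el <- 0
    nstep <- 0L
    steps <- integer(0)
    f_now <- force
    repeat {
      if (force_rule == "trap") {
        com <- (s1 + s2) / 2 * lattice$dz / 2  # nm from start (-6.5 subunits)
        disp <- com + 13 / 2 * lattice$dz / 2
        y_off <- if (nstep >= 2) trap$offaxis_y else 0
        fvec <- c(0, trap$stiffness * y_off, -trap$stiffness * disp)
        Fm <- sqrt(sum(fvec^2))
        if (Fm < 1e-9) {
          f_now <- load_force(0)
        } else {
          u <- fvec / Fm
          f_now <- round_force(load_force(Fm,
                                          acos(pmin(pmax(-u[3], -1), 1)) * 180 / pi,
                                          atan2(u[2], u[1]) * 180 / pi))
        }
      }
      st <- get_state(f_now)
      # waiting state: detachment competition
      t_el <- t_el + rexp(1, 1 / td1 + 1 / td2)
      trailing <- runif(1) < (1 / td1) / (1 / td1 + 1 / td2)
      bound <- if (trailing) s2 else s1
      moving_from <- if (trailing) s1 else s2
      if (trailing) {
        # hydrolysis gate vs bound-head detachment
        t_hyd <- rexp(1, 1 / th)
        t_det <- rexp(1, 1 / td1)
        if (t_det < t_hyd) { t_el <- t_el + t_det; break }
        t_el <- t_el + t_hyd
        rate <- st$rT
      } else {
        rate <- st$rL
      }
      t_bind <- rexp(1, rate)
      t_det <- rexp(1, 1 / td1)
      if (t_det < t_bind) { t_el <- t_el + t_det; break }
      t_el <- t_el + t_bind
      w <- if (trailing) ifelse(st$tb$n > 0, 1, params$b) / st$tb$tfp
           else ifelse(st$tb$n < 0, 1, params$b) / st$tb$tfp
      n_new <- sample(st$tb$n, 1, prob = w)
      target <- bound + n_new
      if (trailing) { s1 <- min(bound, target); s2 <- max(bound, target) }
      else { s1 <- min(bound, target); s2 <- max(bound, target) }
      nstep <- nstep + 1L
      steps <- c(steps, target - moving_from)
      if (nstep >= max_events) break
    }
    runs$length[r] <- ((s1 + s2) / 2 + 13 / 2) * lattice$dz / 2
    runs$time[r] <- t_el
    runs$n_steps[r] <- nstep
    runs$F_end[r] <- f_now$F
    if (r == 1) first_steps <- steps
  }
  structure(list(runs = runs, first_steps = first_steps, seed = seed,
                 force_rule = force_rule),
            class = "mc_runs")
}

#' @export
print.mc_runs <- function(x, ...) {
  cat(sprintf("kinetic MC: %d runs (%s force), mean length %.3g nm, mean steps %.3g\n",
              nrow(x$runs), x$force_rule, mean(x$runs$length),
              mean(x$runs$n_steps)))
  invisible(x)
}
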