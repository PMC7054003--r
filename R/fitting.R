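# Fitting model parameters to step-distribution histograms (KL objective)
# and to force-response constraints (stall force, zero-force run length),
# plus a synthetic-histogram generator for parameter-recovery tests.

#' Solve the bound-leg constraint strength for a given power stroke T
#'
#' Inverts \code{T = 1 + 20 nu_c/(20 + 7 kappa nu_c)} so that (lp, nu_c)
#' can be moved along curves of constant power stroke effectiveness.
#'
#' @param T_eff target effectiveness.
#' @param kappa L/lp.
#' @return nu_c (kBT units).
#' @export
nu_c_for_T <- function(T_eff, kappa) {
  beta <- T_eff - 1
  den <- 20 - 7 * kappa * beta
  if (den <= 0) stop("T_eff unreachable at this kappa (nu_c -> infinity)")
  20 * beta / den
}

#' Fit specification
#'
#' @param free_params character vector: subset of \code{"theta_c"},
#'   \code{"dphi_ac"}, \code{"theta_p"}, \code{"lp"}, \code{"b"},
#'   \code{"a"}, \code{"T"} (power stroke effectiveness; moves \code{nu_c}).
#' @param datasets named list (mutant label -> data.frame with columns
#'   \code{z} (bin center, nm) and \code{count}); labels must be
#'   \code{"4IQ"}, \code{"6IQ"} or \code{"8IQ"}.
#' @param base_params \code{\link{motor_params}} supplying all fixed values.
#' @param constraints list with \code{F_stall} (pN) and \code{z_run0} (nm)
#'   targets for the force-response fit.
#' @param weights per-dataset weights in the joint objective (equal by
#'   default).
#' @param noise_sigma measurement noise used in model histograms, nm.
#' @return object of class \code{fit_spec}.
#' @export
fit_spec <- function(free_params = c("theta_c", "dphi_ac", "theta_p"),
                     datasets = list(), base_params = motor_params(),
                     constraints = list(F_stall = 1.9, z_run0 = 1300),
                     weights = NULL, noise_sigma = 1) {
  allowed <- c("theta_c", "dphi_ac", "theta_p", "lp", "b", "a", "T")
  if (!all(free_params %in% allowed))
    stop("unknown free parameter(s): ",
         paste(setdiff(free_params, allowed), collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(datasets))
  structure(list(free_params = free_params, datasets = datasets,
                 base_params = base_params, constraints = constraints,
                 weights = weights, noise_sigma = noise_sigma),
            class = "fit_spec")
}

fit_bounds <- function() {
  list(theta_c = c(40, 85), dphi_ac = c(20, 120), theta_p = c(50, 120),
       lp = c(100, 375), b = c(0.005, 0.5), a = c(0.1, 1.5),
       T = c(5, 60))
}

apply_free_params <- function(base, vals, mutant = NULL) {
  p <- base
  if (!is.null(mutant)) p <- motor_params(mutant = mutant, lp = base$lp,
                                          theta_c = base$theta_c,
                                          nu_c = base$nu_c,
                                          theta_p = base$theta_p,
                                          mu_c = base$mu_c, a = base$a,
                                          b = base$b, dphi_ac = base$dphi_ac,
                                          Dh = base$Dh, kBT = base$kBT)
  for (nm in setdiff(names(vals), c("lp", "T"))) p[[nm]] <- vals[[nm]]
  if ("lp" %in% names(vals) || "T" %in% names(vals)) {
    # move along curves of constant power stroke effectiveness
    T_target <- if ("T" %in% names(vals)) vals[["T"]]
                else power_stroke_effectiveness(p)
    if ("lp" %in% names(vals)) p$lp <- vals[["lp"]]
    p$kappa <- p$L / p$lp
    p$nu_c <- nu_c_for_T(T_target, p$kappa)
  }
  p
}

# model histogram on the data's bins for one mutant
model_histogram <- function(params, bins_z, noise_sigma, rates, lattice,
                            max_separation = NULL, quad = NULL) {
  bw <- if (length(bins_z) > 1) min(diff(sort(bins_z))) else 5
  kin <- myov_kinetics(params, load_force(0), rates, lattice, quad = quad)
  fwd <- step_distribution(kin$pp, lattice, "forward-only", max_separation)
  hb <- measurement_convolve(fwd, noise_sigma, bw,
                             range = c(min(bins_z) - bw / 2,
                                       max(bins_z) - bw / 2))
  hb$mass[match(round(bins_z, 6), round(hb$z, 6))]
}

#' Fit structural parameters to step-distribution histograms
#'
#' Minimizes the summed Kullback-Leibler divergence between supplied step
#' histograms (one per mutant) and the model's forward-step distributions,
#' over a bounded search box, using Nelder-Mead on logit-transformed
#' coordinates with optional Latin-hypercube restarts. Empty data bins
#' receive a 1e-6 pseudo-mass. When \code{"lp"} or \code{"T"} is free,
#' \code{nu_c} is moved along curves of constant power stroke effectiveness.
#'
#' @param spec \code{\link{fit_spec}} with non-empty \code{datasets}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param n_restarts Latin-hypercube restarts (first start is the center of
#'   the box unless \code{start} is given).
#' @param start optional named start values.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param seed seed for the restart design.
#' @param quad quadrature settings forwarded to \code{\link{density_model}}
#'   (reduced node counts speed up large fit campaigns).
#' @return list with \code{par} (fitted values), \code{params} (fitted
#'   \code{motor_params} at the base mutant), per-dataset \code{kl},
#'   \code{objective}, \code{convergence} and the evaluation \code{trace}.
#' @export
fit_step_distributions <- function(spec, rates = kinetic_rates(),
                                   lattice = actin_lattice(),
                                   n_restarts = 5, start = NULL,
                                   maxit = 200, seed = 1, quad = NULL) {
  if (!length(spec$datasets)) stop("fit_step_distributions needs datasets")
  bounds <- fit_bounds()[spec$free_params]
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  k <- length(lo)
  to_x <- function(p) stats::qlogis(pmin(pmax((p - lo) / (hi - lo), 1e-6),
                                         1 - 1e-6))
  to_p <- function(x) lo + (hi - lo) * stats::plogis(x)
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  objective <- function(x) {
    vals <- setNames(as.list(to_p(x)), spec$free_params)
    tot <- 0
    kls <- numeric(length(spec$datasets))
    for (i in seq_along(spec$datasets)) {
      lab <- names(spec$datasets)[i]
      dat <- spec$datasets[[i]]
      p <- apply_free_params(spec$base_params, vals, mutant = lab)
      mh <- model_histogram(p, dat$z, spec$noise_sigma, rates, lattice,
                            quad = quad)
      Pd <- dat$count / sum(dat$count)
      kls[i] <- kl_divergence(Pd, mh, floor = 1e-6)
      tot <- tot + spec$weights[i] * kls[i]
    }
    trace_env$rows[[length(trace_env$rows) + 1]] <-
      c(unlist(vals), objective = tot)
    tot
  }
  starts <- list()
  if (!is.null(start)) starts[[1]] <- to_x(unlist(start)[spec$free_params])
  else starts[[1]] <- to_x(lo + 0.5 * (hi - lo))
  if (n_restarts > 1) {
    set.seed(seed)
    lh <- matrix(runif((n_restarts - 1) * k), ncol = k)
    # stratify each column (Latin hypercube)
    for (j in seq_len(k))
      lh[, j] <- (sample(n_restarts - 1) - lh[, j]) / (n_restarts - 1)
    for (r in seq_len(n_restarts - 1))
      starts[[r + 1]] <- to_x(lo + (hi - lo) * lh[r, ])
  }
  best <- NULL
  conv <- 1
  for (st in starts) {
    op <- stats::optim(st, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || op$value < best$value) { best <- op; conv <- op$convergence }
  }
  vals <- setNames(as.list(to_p(best$par)), spec$free_params)
  kls <- vapply(seq_along(spec$datasets), function(i) {
    lab <- names(spec$datasets)[i]
    dat <- spec$datasets[[i]]
    p <- apply_free_params(spec$base_params, vals, mutant = lab)
    mh <- model_histogram(p, dat$z, spec$noise_sigma, rates, lattice,
                          quad = quad)
    kl_divergence(dat$count / sum(dat$count), mh, floor = 1e-6)
  }, numeric(1))
  names(kls) <- names(spec$datasets)
  if (conv != 0)
    warning("step-distribution fit did not converge within the iteration budget")
  list(par = unlist(vals), params = apply_free_params(spec$base_params, vals),
       kl = kls, objective = best$value, convergence = conv,
       trace = do.call(rbind, trace_env$rows))
}

#' Fit the force response (power stroke effectiveness and binding penalty)
#'
#' Adjusts \code{T} (through \code{nu_c}) and \code{b} -- and optionally the
#' capture radius \code{a} -- so that the stall force and zero-force run
#' length match their targets (1.9 pN and 1.3 um by default).
#'
#' @param spec \code{\link{fit_spec}} (uses \code{constraints} and
#'   \code{base_params}).
#' @param rates \code{\link{kinetic_rates}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param fit_a also vary the capture radius.
#' @param maxit Nelder-Mead iteration cap.
#' @return list with fitted \code{T}, \code{b} (and \code{a}), the implied
#'   \code{nu_c}, fitted \code{params}, achieved \code{F_stall} and
#'   \code{z_run0}, and the residual.
#' @export
fit_force_response <- function(spec, rates = kinetic_rates(),
                               lattice = actin_lattice(), fit_a = FALSE,
                               maxit = 60) {
  cons <- spec$constraints
  base <- spec$base_params
  pars0 <- c(T = power_stroke_effectiveness(base), b = base$b)
  if (fit_a) pars0 <- c(pars0, a = base$a)
  make_params <- function(x) {
    p <- base
    p$b <- min(max(x[["b"]], 1e-4), 1)
    if (fit_a) p$a <- max(x[["a"]], 0.05)
    p$nu_c <- nu_c_for_T(min(max(x[["T"]], 2), 1 + 20 / (7 * p$kappa) - 0.5),
                         p$kappa)
    p
  }
  eval_targets <- function(p) {
    z0 <- run_at_force(p, load_force(0), rates, lattice)$rs$z_run
    fs <- tryCatch(stall_force(p, rates, lattice, tol = 5e-3)$F_stall,
                   error = function(e) NA_real_)
    c(F_stall = fs, z_run0 = z0)
  }
  obj <- function(x) {
    tg <- eval_targets(make_params(x))
    if (is.na(tg["F_stall"])) return(25)
    (log(tg["F_stall"] / cons$F_stall))^2 + (log(tg["z_run0"] / cons$z_run0))^2
  }
  op <- stats::optim(pars0, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-4))
  p <- make_params(op$par)
  tg <- eval_targets(p)
  if (op$value > 0.01)
    warning(sprintf(paste0("force-response constraints not met ",
                           "(stall %.2f pN vs %.2f, z_run %.0f nm vs %.0f): ",
                           "targets may be infeasible"),
                    tg["F_stall"], cons$F_stall, tg["z_run0"], cons$z_run0))
  list(T = unname(op$par[["T"]]), b = p$b, a = p$a, nu_c = p$nu_c,
       params = p, F_stall = unname(tg["F_stall"]),
       z_run0 = unname(tg["z_run0"]), residual = op$value)
}

#' Alternating refinement of structure and force response
#'
#' Runs the step-distribution fit and the force-response fit in alternation
#' for a fixed number of cycles, feeding each result into the other.
#'
#' @param spec \code{\link{fit_spec}}.
#' @param cycles number of alternations.
#' @param ... passed to \code{\link{fit_step_distributions}}.
#' @return list with the final fits of both stages.
#' @export
fit_alternating <- function(spec, cycles = 3, ...) {
  sd_fit <- NULL
  fr_fit <- NULL
  for (cy in seq_len(cycles)) {
    if (length(spec$datasets)) {
      sd_fit <- fit_step_distributions(spec, ...)
      spec$base_params <- sd_fit$params
    }
    fr_fit <- fit_force_response(spec)
    spec$base_params <- fr_fit$params
  }
  list(step_fit = sd_fit, force_fit = fr_fit, params = spec$base_params)
}

#' Generate synthetic step-distribution histograms
#'
#' Samples forward steps from the model's own forward-only step
#' distribution for each mutant, adds Gaussian localization noise, and bins
#' the samples; deterministic per seed. Used for parameter-recovery tests.
#'
#' @param params \code{\link{motor_params}} (generating truth; its mutant
#'   field is overridden per requested mutant).
#' @param mutants character vector of mutant labels.
#' @param n_samples steps sampled per mutant.
#' @param seed integer seed.
#' @param noise_sigma localization noise, nm.
#' @param bin_width histogram bin width, nm; the 2.5 nm default resolves
#'   the 2.77 nm half-subunit site spacing, consistent with the ~1 nm
#'   localization accuracy of the stepping assays being emulated.
#' @param rates,lattice kinetics inputs.
#' @param quad quadrature settings forwarded to \code{\link{density_model}}.
#' @return named list of data.frames with columns \code{z}, \code{count}.
#' @export
generate_fixture_histograms <- function(params = motor_params(),
                                        mutants = c("4IQ", "6IQ", "8IQ"),
                                        n_samples = 500, seed = 1,
                                        noise_sigma = 1, bin_width = 2.5,
                                        rates = kinetic_rates(),
                                        lattice = actin_lattice(),
                                        quad = NULL) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  out <- list()
  for (m in mutants) {
    p <- apply_free_params(params, list(), mutant = m)
    kin <- myov_kinetics(p, load_force(0), rates, lattice, quad = quad)
    fwd <- step_distribution(kin$pp, lattice, "forward-only")
    z <- sample(fwd$z, n_samples, replace = TRUE, prob = fwd$mass) +
      rnorm(n_samples, 0, noise_sigma)
    edges <- seq(floor(min(z) / bin_width) * bin_width - bin_width / 2,
                 max(z) + bin_width, by = bin_width)
    h <- hist(z, breaks = edges, plot = FALSE)
    out[[m]] <- data.frame(z = h$mids, count = h$counts)
  }
  out
}

#' Read/write two-column step histograms
#'
#' Plain text with comment lines starting with '#': columns are bin center
#' (nm) and count.
#'
#' @param path file path.
#' @return data.frame with columns \code{z}, \code{count}.
#' @export
read_histogram <- function(path) {
  d <- read.table(path, comment.char = "#", col.names = c("z", "count"))
  if (any(d$count < 0)) stop("negative counts in histogram file")
  d
}

#' @rdname read_histogram
#' @param hist data.frame with columns \code{z}, \code{count}.
#' @param comment optional header comment.
#' @export
write_histogram <- function(hist, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# bin_center_nm count", con)
  utils::write.table(hist[, c("z", "count")], con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
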