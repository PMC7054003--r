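# Model parameters and load-force containers.
#
# Units used throughout the package: nm, ms, pN, and thermal energy kBT
# (4.1 pN nm, T ~ 297 K). Angles are degrees at the user interface and
# radians internally.

#' Thermal energy used throughout the package
#'
#' @return kBT in pN nm (4.1, i.e. T of roughly 297 K).
#' @export
kBT_default <- function() 4.1

#' Myosin V motor parameters
#'
#' Bundles the structural, binding and diffusion parameters of the two-leg
#' polymer model of myosin V. Defaults are the wild-type (6IQ) parameter set
#' used for all headline results; the \code{mutant} presets change the leg
#' contour length \code{L} (5 nm per IQ motif plus the head) and the
#' head--head exclusion length \code{dV}.
#'
#' @param L leg contour length (head + lever arm), nm.
#' @param lp leg persistence length, nm (stiff regime \code{lp >= L}).
#' @param theta_c bound-leg (post power stroke) constraint polar angle,
#'   degrees from the actin plus-end axis.
#' @param nu_c bound-leg tangent constraint strength, kBT units.
#' @param theta_p preferred inter-leg joint angle, degrees.
#' @param mu_c inter-leg joint constraint strength, kBT units.
#' @param a capture radius for binding, nm.
#' @param b binding penalty (probability of binding against the
#'   recovery-stroke orientation), in (0, 1].
#' @param dphi_ac azimuthal binding acceptance half-width, degrees.
#' @param Dh diffusion constant of the detached head, nm^2/ms.
#' @param dV head--head effective exclusion length, nm.
#' @param kBT thermal energy, pN nm.
#' @param mutant one of \code{"4IQ"}, \code{"6IQ"}, \code{"8IQ"}; presets
#'   \code{L} and \code{dV} unless those are supplied explicitly.
#' @return object of class \code{motor_params}.
#' @examples
#' p <- motor_params()            # wild type
#' p8 <- motor_params(mutant = "8IQ")
#' @export
motor_params <- function(L = NULL, lp = 350, theta_c = 65, nu_c = 261,
                         theta_p = 83, mu_c = 5, a = 0.4, b = 0.045,
                         dphi_ac = 55.6, Dh = 5.7e4, dV = NULL,
                         kBT = kBT_default(), mutant = c("6IQ", "4IQ", "8IQ")) {
  mutant <- match.arg(mutant)
  preset <- list(`4IQ` = c(L = 25, dV = 20),
                 `6IQ` = c(L = 35, dV = 27.5),
                 `8IQ` = c(L = 45, dV = 35))[[mutant]]
  if (is.null(L)) L <- unname(preset["L"])
  if (is.null(dV)) dV <- unname(preset["dV"])
  stopifnot(L > 0, lp > 0, a > 0, kBT > 0, Dh > 0)
  if (lp < L) stop("stiff regime assumed: persistence length lp must be >= L")
  if (!(b > 0 && b <= 1)) stop("binding penalty b must be in (0, 1]")
  if (dphi_ac < 0 || dphi_ac > 180) stop("dphi_ac must be in [0, 180] degrees")
  if (mu_c < 0 || nu_c < 0) stop("constraint strengths must be non-negative")
  p <- list(L = L, lp = lp, kappa = L / lp, theta_c = theta_c, nu_c = nu_c,
            theta_p = theta_p, mu_c = mu_c, a = a, b = b, dphi_ac = dphi_ac,
            Dh = Dh, dV = dV, kBT = kBT, mutant = mutant)
  class(p) <- "motor_params"
  p
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf("Myosin V motor parameters (%s):\n", x$mutant))
  cat(sprintf("  L = %g nm, lp = %g nm (kappa = %.3g)\n", x$L, x$lp, x$kappa))
  cat(sprintf("  theta_c = %g deg, nu_c = %g kBT  (power stroke T = %.3f)\n",
              x$theta_c, x$nu_c, power_stroke_effectiveness(x)))
  cat(sprintf("  theta_p = %g deg, mu_c = %g kBT\n", x$theta_p, x$mu_c))
  cat(sprintf("  a = %g nm, b = %g, dphi_ac = %g deg, dV = %g nm\n",
              x$a, x$b, x$dphi_ac, x$dV))
  cat(sprintf("  Dh = %g nm^2/ms, kBT = %g pN nm\n", x$Dh, x$kBT))
  invisible(x)
}

#' Kinetic rates of the stepping cycle
#'
#' @param td1 mean trailing-head detachment time, ms (default 1/12 s).
#' @param td2 mean leading-head detachment time, ms (default 1/1.5 s).
#' @param th mean ATP hydrolysis time, ms (default 1/750 s).
#' @return object of class \code{kinetic_rates} with gating ratio
#'   \code{g = td2/td1}.
#' @export
kinetic_rates <- function(td1 = 1000 / 12, td2 = 1000 / 1.5, th = 1000 / 750) {
  stopifnot(td1 > 0, td2 > 0, th >= 0)
  g <- td2 / td1
  if (g <= 1) stop("gating requires td2 > td1 (g > 1)")
  structure(list(td1 = td1, td2 = td2, th = th, g = g),
            class = "kinetic_rates")
}

#' Load force specification
#'
#' The unit direction is \code{(sin(thF)cos(phF), sin(thF)sin(phF), -cos(thF))}
#' so that \code{theta_F = phi_F = 0} is a pure backward (resistive) force.
#'
#' @param F magnitude, pN.
#' @param theta_F polar angle from the minus-z axis, degrees.
#' @param phi_F azimuthal angle from the x axis, degrees.
#' @return object of class \code{load_force}.
#' @export
load_force <- function(F = 0, theta_F = 0, phi_F = 0) {
  stopifnot(F >= 0)
  tF <- theta_F * pi / 180
  pF <- phi_F * pi / 180
  structure(list(F = F, theta_F = theta_F, phi_F = phi_F,
                 Fhat = c(sin(tF) * cos(pF), sin(tF) * sin(pF), -cos(tF))),
            class = "load_force")
}

#' Zero-force power stroke effectiveness
#'
#' \code{T = 1 + 20 nu_c / (20 + 7 kappa nu_c)}: the harmonic composition of
#' the bound-leg tangent constraint \code{nu_c} with the stiff-chain
#' tangent-to-chord response \code{20/(7 kappa)}, measuring the energy loaded
#' into the effective lever-arm spring by the power stroke.
#'
#' @param params \code{motor_params}.
#' @return dimensionless effectiveness T.
#' @export
power_stroke_effectiveness <- function(params) {
  1 + 20 * params$nu_c / (20 + 7 * params$kappa * params$nu_c)
}

#' Force-renormalized power stroke constraint
#'
#' Under a load \code{F} applied at the joint, the bound-leg orientation
#' weight \code{exp(T uc . u)} is tilted by the force term
#' \code{beta F L Fhat . u}, giving a renormalized direction and strength:
#' \code{T' = sqrt(T^2 + (bFL)^2 + 2 T bFL Fhat.uc)} and
#' \code{uc' = (T uc + bFL Fhat)/T'}.
#'
#' @param params \code{motor_params}.
#' @param force \code{load_force}.
#' @return list with \code{T_eff}, \code{u_c} (zero force), \code{u_c_prime},
#'   \code{T0} (zero-force effectiveness) and the effective constraint polar
#'   angle \code{theta_c_prime} (degrees, in the x-z plane convention
#'   \code{atan2(x, z)}).
#' @export
effective_constraint <- function(params, force = load_force()) {
  T0 <- power_stroke_effectiveness(params)
  tc <- params$theta_c * pi / 180
  uc <- c(sin(tc), 0, cos(tc))
  bFL <- force$F * params$L / params$kBT
  if (bFL == 0) {
    ucp <- uc
    Tp <- T0
  } else {
    v <- T0 * uc + bFL * force$Fhat
    Tp <- sqrt(sum(v^2))
    if (Tp < 1e-12)
      stop("degenerate constraint direction: force exactly cancels the power stroke")
    ucp <- v / Tp
  }
  list(T_eff = Tp, T0 = T0, u_c = uc, u_c_prime = ucp, bFL = bFL,
       theta_c_prime = atan2(ucp[1], ucp[3]) * 180 / pi)
}

#' Inter-leg joint potential
#'
#' Cosine form \code{mu_c (1 - cos(theta_J - theta_p))} (the default used
#' throughout), or a general quartic
#' \code{mu_c ((dt)^2/2 + h3 (dt)^3/6 + h4 (dt)^4/24)} with
#' \code{dt = theta_J - theta_p}, used to probe sensitivity to the
#' functional form.
#'
#' @param theta_J inter-leg angle(s), radians in [0, pi].
#' @param mu_c constraint strength, kBT.
#' @param theta_p preferred angle, radians.
#' @param form \code{"cosine"} or \code{"quartic"}.
#' @param h3,h4 cubic/quartic coefficients (quartic form only).
#' @return energy in kBT, vectorized over \code{theta_J}.
#' @export
joint_potential <- function(theta_J, mu_c, theta_p, form = c("cosine", "quartic"),
                            h3 = 0, h4 = 0) {
  form <- match.arg(form)
  dt <- theta_J - theta_p
  if (form == "cosine") mu_c * (1 - cos(dt))
  else mu_c * (dt^2 / 2 + h3 * dt^3 / 6 + h4 * dt^4 / 24)
}
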