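# Site-resolved first-passage kinetics and the five-pathway network.
#
# The mean first-passage time to bind site n is the diffusion-limited
# capture expression t_fp^n = [4 pi a Dh P(r_n, window)]^-1 evaluated with
# the joint (position + azimuth-window) equilibrium density.  Combined with
# Poissonian detachment (t_d1, t_d2), hydrolysis (t_h) and binding penalty b
# this yields the probabilities of forward steps, backward steps, trailing
# and leading stomps, and run termination.

#' Site-resolved mean first-passage times
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param lattice \code{\link{actin_lattice}}.
#' @param model optional precomputed \code{\link{density_model}}.
#' @param density_floor sites with joint density below this (nm^-3) are
#'   treated as unreachable and dropped from all rate sums.
#' @return object of class \code{site_passage}: data.frame \code{table}
#'   (n, z, density, tfp) over reachable sites, the trailing/leading binding
#'   rates \code{rT}, \code{rL} (1/ms), and the pure diffusion time
#'   \code{tdiff} (ms).
#' @export
first_passage_times <- function(params, force = load_force(),
                                lattice = actin_lattice(), model = NULL,
                                density_floor = 1e-12) {
  if (is.null(model)) model <- density_model(params, force)
  ns <- setdiff(lattice$sites, 0L)  # n = 0 is occupied by the bound head
  dens <- joint_density_at_site(params, force, ns, lattice, model)
  keep <- dens > density_floor
  if (!any(keep)) stop("unreachable lattice: all site densities below floor")
  ns <- ns[keep]
  dens <- dens[keep]
  tfp <- 1 / (4 * pi * params$a * params$Dh * dens)   # ms
  bn <- ifelse(ns > 0, 1, params$b)
  rT <- sum(bn / tfp)
  rL <- sum(ifelse(ns < 0, 1, params$b) / tfp)
  structure(list(table = data.frame(n = ns, z = ns * lattice$dz / 2,
                                    density = dens, tfp = tfp),
                 rT = rT, rL = rL, tdiff = 1 / sum(1 / tfp),
                 params = params, force = force),
            class = "site_passage")
}

#' @export
print.site_passage <- function(x, ...) {
  cat(sprintf("site passage: %d reachable sites, tdiff = %.4g ms, rT = %.4g/ms, rL = %.4g/ms\n",
              nrow(x$table), x$tdiff, x$rT, x$rL))
  invisible(x)
}

#' Probabilities of the five kinetic pathways
#'
#' Per-site binding probabilities after trailing-head detachment,
#' \code{PT_n = b_n td1^2 / (tfp_n (1 + rT td1)(td1 + th))}, and after
#' leading-head detachment (no hydrolysis, mirrored penalty),
#' \code{PL_n = b_-n td1 / (tfp_n (1 + rL td1))}. Aggregates weight the two
#' branches by the detachment competition, \code{g/(1+g)} trailing and
#' \code{1/(1+g)} leading; termination is the complement, so the five
#' pathway probabilities sum to one by construction.
#'
#' @param sp \code{site_passage}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param b binding penalty; defaults to the motor parameters stored in
#'   \code{sp}.
#' @return object of class \code{pathway_probabilities}: per-site data.frame
#'   \code{table} (n, z, pT, pL) and aggregates \code{Pf}, \code{Pb},
#'   \code{PTs}, \code{PLs}, \code{Pt}.
#' @export
pathway_probabilities <- function(sp, rates = kinetic_rates(), b = NULL) {
  if (is.null(b)) b <- sp$params$b
  tb <- sp$table
  bn <- ifelse(tb$n > 0, 1, b)
  bmn <- ifelse(tb$n < 0, 1, b)
  rT <- sum(bn / tb$tfp)
  rL <- sum(bmn / tb$tfp)
  td1 <- rates$td1; th <- rates$th; g <- rates$g
  pT <- bn * td1^2 / (tb$tfp * (1 + rT * td1) * (td1 + th))
  pL <- bmn * td1 / (tb$tfp * (1 + rL * td1))
  wT <- g / (1 + g)
  wL <- 1 / (1 + g)
  Pf <- wT * sum(pT[tb$n > 0])
  PTs <- wT * sum(pT[tb$n < 0])
  Pb <- wL * sum(pL[tb$n < 0])
  PLs <- wL * sum(pL[tb$n > 0])
  Pt <- 1 - (Pf + PTs + Pb + PLs)
  structure(list(table = data.frame(n = tb$n, z = tb$z, pT = pT, pL = pL),
                 Pf = Pf, Pb = Pb, PTs = PTs, PLs = PLs, Pt = Pt,
                 rT = rT, rL = rL, g = g, rates = rates, b = b),
            class = "pathway_probabilities")
}

#' @export
print.pathway_probabilities <- function(x, ...) {
  cat(sprintf("pathways: Pf=%.4g Pb=%.4g PTs=%.4g PLs=%.4g Pt=%.4g (ratio Pb/Pf=%.4g)\n",
              x$Pf, x$Pb, x$PTs, x$PLs, x$Pt, x$Pb / x$Pf))
  invisible(x)
}

#' Mean binding times after detachment
#'
#' Trailing leg: \code{tT = 1/rT + th} (hydrolysis gates binding); leading
#' leg: \code{tL = 1/rL} (ADP retained, no hydrolysis).
#'
#' @param sp \code{site_passage}.
#' @param rates \code{\link{kinetic_rates}}.
#' @param b binding penalty; defaults to the motor parameters in \code{sp}.
#' @return list with \code{tT}, \code{tL}, \code{tdiff} (ms).
#' @export
binding_times <- function(sp, rates = kinetic_rates(), b = NULL) {
  if (is.null(b)) b <- sp$params$b
  tb <- sp$table
  rT <- sum(ifelse(tb$n > 0, 1, b) / tb$tfp)
  rL <- sum(ifelse(tb$n < 0, 1, b) / tb$tfp)
  if (rT <= 0 || rL <= 0) stop("unreachable lattice: zero binding rate")
  list(tT = 1 / rT + rates$th, tL = 1 / rL, tdiff = sp$tdiff)
}
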