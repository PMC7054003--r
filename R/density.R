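# Equilibrium free-head density of the detached leg.
#
# The two lever arms are stiff semiflexible chains (kappa = L/lp <= 1).
# In the mean-field stiff limit each leg's end-to-end (chord) vector
# factorizes into a sharply peaked radial part and an orientational part:
#
#   * radial: the mean-field semiflexible end-to-end density
#       f(l) ~ (1-(l/L)^2)^(-9/2) exp[-(9 kappa/8) / (1-(l/L)^2)],  l < L
#   * bound-leg orientation u1 (origin -> joint): von Mises-Fisher weight
#       exp(T' uc' . u1), where T' and uc' are the force-renormalized power
#       stroke effectiveness and direction (see effective_constraint); the
#       load enters exactly through this renormalization because the tail
#       force acts at the joint, beta F . r_J ~ beta F L Fhat . u1.
#   * free-leg orientation u2 (joint -> head): isotropic.
#
# The inter-leg joint potential H_J acts on the angle between the two arm
# chords, theta_J = acos(-u1 . u2), and the head-head exclusion weight
# exp[-(dV/r)^6] multiplies the joint density (r = head-head distance).
# All densities are reported in nm^-3 and normalized over 3-space.

wlc_radial_shape <- function(l, L, kappa) {
  x <- 1 - (l / L)^2
  out <- numeric(length(l))
  ok <- l >= 0 & l < L & x > 0
  out[ok] <- x[ok]^(-4.5) * exp(-(9 * kappa / 8) / x[ok])
  out
}

# Nodes/weights for integrals int_0^L dl l^2 f(l) g(l).  The radial shape is
# sharply peaked at x = 1 - (l/L)^2 ~ kappa/4, so integrate in s = log(x).
radial_quadrature <- function(L, kappa, n = 16) {
  s_lo <- log(min(kappa / 400, 1e-4))
  gl <- pracma::gaussLegendre(n, s_lo, 0)
  x <- exp(gl$x)
  l <- L * sqrt(pmax(1 - x, 0))
  # l^2 dl = (L^3/2) e^s sqrt(1 - e^s) ds
  w <- gl$w * (L^3 / 2) * x * sqrt(pmax(1 - x, 0)) * wlc_radial_shape(l, L, kappa)
  keep <- w > 0
  list(l = l[keep], w = w[keep])
}

#' Precompute the mean-field density model for one parameter/force setting
#'
#' Builds the radial quadrature rules and the global normalization constant,
#' after which pointwise density evaluations are cheap. Used internally by
#' \code{\link{free_head_density}} and \code{\link{joint_density_at_site}};
#' exposed for scans that reuse one setting many times.
#'
#' Pointwise evaluation integrates over the joint position in two-center
#' coordinates \code{(l1, l2, phi)} (distances to the bound head and to the
#' evaluation point, azimuth about the axis joining them), which places both
#' sharply peaked radial factors on explicit quadrature axes; the volume
#' element is \code{l1 l2 / c} with \code{c} the distance to the point.
#'
#' The bound-leg orientation weight supports two forms. \code{"vmf"} (the
#' default) is the von Mises-Fisher weight \code{exp(T' uc'. u1)} with the
#' force-renormalized effectiveness and direction obtained by composing the
#' power stroke vector \code{T uc} with \code{beta F L Fhat}
#' (\code{\link{effective_constraint}}). \code{"gauss"} instead uses the
#' bent-cantilever response: a Gaussian in the chord rotation angle with
#' concentration \code{T - 1} times the exact load weight
#' \code{exp(beta F . r_J)}; its bending energy keeps growing quadratically
#' at large rotations, which tracks the bead-chain oracle more closely under
#' strong loads. The two coincide for small rotations.
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param quad list of quadrature sizes: \code{n_l} (radial nodes per leg),
#'   \code{n_phi} (azimuth nodes about the two-center axis), \code{n_gamma}
#'   (normalization integral).
#' @param form bound-leg orientation weight: \code{"vmf"} (default) or
#'   \code{"gauss"} (cantilever response).
#' @param joint_spec inter-leg potential specification: list with
#'   \code{form} ("cosine" or "quartic") and coefficients \code{h3},
#'   \code{h4} (see \code{\link{joint_potential}}); cosine by default.
#' @return object of class \code{density_model}.
#' @export
density_model <- function(params, force = load_force(),
                          quad = list(n_l = 14, n_phi = 64, n_gamma = 128),
                          form = c("vmf", "gauss"), joint_spec = NULL) {
  form <- match.arg(form)
  if (is.null(joint_spec)) joint_spec <- list(form = "cosine", h3 = 0, h4 = 0)
  ec <- effective_constraint(params, force)
  rq <- radial_quadrature(params$L, params$kappa, quad$n_l)
  mu_c <- params$mu_c
  tp <- params$theta_p * pi / 180
  dV <- params$dV
  fred <- force$Fhat * force$F / params$kBT  # beta F vector, 1/nm
  Tg <- ec$T0 - 1                            # Gaussian-angle concentration
  shift <- params$L * sqrt(sum(fred^2))      # exponent offset for stability

  # orientation weight (unnormalized, exponent shifted): vectorized over
  # pairs (l1, cos_uc = uc.u1, cos_f = Fhat-projected fred.u1*l1 term)
  orient_w <- function(l1, dot_uc, dot_fred) {
    # dot_fred = fred . u1 (1/nm)
    if (form == "gauss") {
      # cantilever response with the exact load arm l1
      ang <- acos(pmin(pmax(dot_uc, -1), 1))
      exp(-0.5 * Tg * ang^2 + l1 * dot_fred - shift)
    } else {
      # printed renormalization: exp(T' uc'.u1) = exp(T uc.u1 + bFL Fhat.u1)
      exp(ec$T0 * dot_uc + params$L * dot_fred - ec$T_eff)
    }
  }

  # sphere integral A(l1) of the orientation weight, by quadrature on a
  # frame aligned with uc
  A_of_l1 <- function(l1v) {
    tq <- pracma::gaussLegendre(96, -1, 1)
    nphi <- 48
    phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
    ref <- c(0, 0, 1)
    if (abs(ec$u_c[3]) > 0.9) ref <- c(0, 1, 0)
    e1 <- ref - sum(ref * ec$u_c) * ec$u_c
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ec$u_c[2] * e1[3] - ec$u_c[3] * e1[2],
            ec$u_c[3] * e1[1] - ec$u_c[1] * e1[3],
            ec$u_c[1] * e1[2] - ec$u_c[2] * e1[1])
    st <- sqrt(pmax(1 - tq$x^2, 0))
    out <- numeric(length(l1v))
    for (k in seq_along(l1v)) {
      acc <- 0
      for (j in seq_len(nphi)) {
        u <- outer(tq$x, ec$u_c) + outer(st * cos(phi[j]), e1) +
          outer(st * sin(phi[j]), e2)
        df <- u %*% fred
        acc <- acc + sum(tq$w * orient_w(l1v[k], tq$x, as.numeric(df)))
      }
      out[k] <- acc * 2 * pi / nphi
    }
    out
  }

  # normalization Z = 2*pi * int dl1 dl2 dcg A(l1) l1^2 f l2^2 f W_J W_V
  gg <- pracma::gaussLegendre(quad$n_gamma, -1, 1)
  nl <- length(rq$l)
  Al <- A_of_l1(rq$l)
  L1 <- rep(rq$l, times = nl)
  L2 <- rep(rq$l, each = nl)
  W12 <- rep(rq$w, times = nl) * rep(rq$w, each = nl)
  A1 <- rep(Al, times = nl)
  zint <- 0
  for (i in seq_along(gg$x)) {
    cg <- gg$x[i]
    thJ <- acos(pmin(pmax(-cg, -1), 1))
    WJ <- exp(-joint_potential(thJ, mu_c, tp, joint_spec$form,
                               joint_spec$h3, joint_spec$h4))
    r2 <- L1^2 + L2^2 + 2 * L1 * L2 * cg
    WV <- exp(-(dV^2 / pmax(r2, 1e-12))^3)
    zint <- zint + gg$w[i] * sum(W12 * A1 * WJ * WV)
  }
  Z <- 2 * pi * zint

  # precomputed (l1, l2) mesh for pointwise evaluation
  structure(list(params = params, force = force, constraint = ec,
                 form = form, Tg = Tg, shift = shift, orient_w = orient_w,
                 joint_spec = joint_spec,
                 fred = fred, rq = rq, L1 = L1, L2 = L2,
                 W12 = W12 / (L1 * L2),   # measure l1 l2 / c, c applied later
                 Z = Z, mu_c = mu_c, theta_p_rad = tp, dV = dV, quad = quad),
            class = "density_model")
}

# Evaluate the (optionally azimuth-windowed) density at arbitrary points.
# pts: m x 3 matrix; if window is given it is list(phi_n, delta1, delta2).
# n_phi overrides the azimuth node count (windowed evaluations use more).
density_eval <- function(model, pts, window = NULL, n_phi = NULL) {
  if (is.null(n_phi)) n_phi <- if (is.null(window)) model$quad$n_phi
                               else 4L * model$quad$n_phi
  uc <- model$constraint$u_c
  fred <- model$fred
  L1 <- model$L1
  L2 <- model$L2
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dphi <- 2 * pi / n_phi
  cphi <- cos(phi); sphi <- sin(phi)
  # triangle geometry on the (l1, l2) mesh is independent of the point except
  # through c, so compute per point
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, ]
    c2 <- sum(r * r)
    cc <- sqrt(c2)
    WV <- exp(-(model$dV / max(cc, 1e-9))^6)
    if (WV == 0 || cc < 1e-6) next
    # joint axial/radial coordinates relative to the axis e = r/c
    t_ax <- (c2 + L1^2 - L2^2) / (2 * cc)
    rho2 <- L1^2 - t_ax^2
    live <- which(rho2 > 0)
    if (!length(live)) next
    rho <- sqrt(rho2[live])
    ta <- t_ax[live]
    l1 <- L1[live]; l2 <- L2[live]
    # inter-arm chord angle: cos(theta_J) = -(u1.u2),
    # u1.u2 = (c*t_ax - l1^2)/(l1*l2)  since u2 = (r - rJ)/l2
    cthJ <- pmin(pmax(-(cc * ta - l1^2) / (l1 * l2), -1), 1)
    WJ <- exp(-joint_potential(acos(cthJ), model$mu_c, model$theta_p_rad,
                               model$joint_spec$form, model$joint_spec$h3,
                               model$joint_spec$h4))
    base <- model$W12[live] * WJ / cc  # f-weights * measure l1 l2 / c
    # orthonormal frame about the axis
    e <- r / cc
    ref <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * e) * e
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(e[2] * e1[3] - e[3] * e1[2],
            e[3] * e1[1] - e[1] * e1[3],
            e[1] * e1[2] - e[2] * e1[1])
    # orientation weight needs uc.u1 and fred.u1 for each (node, phi),
    # with u1 = (t e + rho(cos e1 + sin e2))/l1
    dot_uc <- (ta * sum(uc * e) + outer(rho, cphi * sum(uc * e1) +
                                          sphi * sum(uc * e2))) / l1
    dot_fr <- (ta * sum(fred * e) + outer(rho, cphi * sum(fred * e1) +
                                            sphi * sum(fred * e2))) / l1
    vmf <- model$orient_w(l1, dot_uc, dot_fr)
    if (!is.null(window)) {
      # free-leg azimuth phi_f = atan2(y, x) of d = r - rJ
      dx0 <- r[1] - ta * e[1]; dy0 <- r[2] - ta * e[2]
      dx <- dx0 - outer(rho, cphi * e1[1] + sphi * e2[1])
      dy <- dy0 - outer(rho, cphi * e1[2] + sphi * e2[2])
      ok <- acceptance_test(atan2(dy, dx), window$phi_n,
                            window$delta1, window$delta2)
      vmf <- vmf * ok
    }
    out[i] <- WV * sum(base * rowSums(vmf)) * dphi / model$Z
  }
  out
}

#' Joint density of head position and free-leg azimuth at binding sites
#'
#' Evaluates \code{P(r_n, window)}: the joint probability density (nm^-3) of
#' the free head being at site \code{n} with the free-leg azimuth
#' anti-parallel to the site's outward normal within the acceptance window.
#' With \code{dphi_ac = 180} degrees this reduces to the positional marginal
#' \code{P(r_n)}.
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param n integer site indices.
#' @param lattice \code{\link{actin_lattice}}.
#' @param model optional precomputed \code{\link{density_model}} (must match
#'   \code{params}/\code{force}).
#' @param delta1,delta2 acceptance half-widths in radians; default the
#'   symmetric \code{dphi_ac} from \code{params}.
#' @return numeric vector of densities, one per site index.
#' @export
joint_density_at_site <- function(params, force = load_force(), n,
                                  lattice = actin_lattice(), model = NULL,
                                  delta1 = NULL, delta2 = NULL) {
  if (is.null(model)) model <- density_model(params, force)
  if (is.null(delta1)) delta1 <- params$dphi_ac * pi / 180
  if (is.null(delta2)) delta2 <- delta1
  pos <- site_position(lattice, n)
  phin <- site_normal_azimuth(lattice, n)
  out <- numeric(length(n))
  full <- delta1 >= pi - 1e-12 && delta2 >= pi - 1e-12
  for (i in seq_along(n)) {
    win <- if (full) NULL else list(phi_n = phin[i], delta1 = delta1,
                                    delta2 = delta2)
    out[i] <- density_eval(model, pos[i, , drop = FALSE], win)
  }
  out
}

#' Free-head equilibrium density on a 3D grid
#'
#' @param params \code{\link{motor_params}}.
#' @param force \code{\link{load_force}}.
#' @param spacing grid spacing, nm (0.5 nm default; use 2-3 nm for quick
#'   validation grids).
#' @param pad padding beyond the maximal reach 2L, nm.
#' @param model optional precomputed \code{\link{density_model}}.
#' @param chunk number of grid points evaluated per vectorized block.
#' @param check_norm if TRUE, stop when the Riemann sum of the grid deviates
#'   from 1 by more than 5\% (resolution error) and warn beyond 1\%.
#' @return object of class \code{density_grid}: axes (x, y, z vectors) and a
#'   3D array of densities (nm^-3).
#' @export
free_head_density <- function(params, force = load_force(), spacing = 0.5,
                              pad = 5, model = NULL, chunk = 2048,
                              check_norm = TRUE) {
  if (is.null(model)) model <- density_model(params, force)
  lim <- 2 * params$L + pad
  ax <- seq(-lim, lim, by = spacing)
  nx <- length(ax)
  vals <- array(0, dim = c(nx, nx, nx))
  reach <- 2 * params$L
  # evaluate only points inside the reachable sphere
  grid_xy <- expand.grid(x = ax, y = ax)
  for (k in seq_len(nx)) {
    z <- ax[k]
    rho2max <- reach^2 - z^2
    if (rho2max <= 0) next
    sel <- which(grid_xy$x^2 + grid_xy$y^2 < rho2max)
    if (!length(sel)) next
    pts <- cbind(grid_xy$x[sel], grid_xy$y[sel], z)
    v <- numeric(length(sel))
    for (start in seq(1, length(sel), by = chunk)) {
      idx <- start:min(start + chunk - 1, length(sel))
      v[idx] <- density_eval(model, pts[idx, , drop = FALSE])
    }
    slice <- numeric(nx * nx)
    slice[sel] <- v
    vals[, , k] <- slice
  }
  tot <- sum(vals) * spacing^3
  if (check_norm) {
    if (abs(tot - 1) > 0.05)
      stop(sprintf(paste0("density grid resolution error: Riemann sum = %.4f;",
                          " decrease spacing"), tot))
    if (abs(tot - 1) > 0.01)
      warning(sprintf("density grid normalization %.4f deviates by >1%%", tot))
  }
  structure(list(axes = list(x = ax, y = ax, z = ax), values = vals,
                 spacing = spacing, total = tot,
                 params = params, force = force),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("free-head density grid: %d^3 points, %.2f nm spacing, sum %.4f\n",
              length(x$axes$x), x$spacing, x$total))
  invisible(x)
}

#' Project a 3D density grid onto a plane
#'
#' Marginalizes the remaining coordinate. The \code{"z-rho"} projection bins
#' the cylindrical radius \code{rho = sqrt(x^2+y^2)} mass-preservingly so the
#' 2D marginal still integrates to 1.
#'
#' @param grid \code{density_grid}.
#' @param plane one of \code{"z-x"}, \code{"z-y"}, \code{"y-x"},
#'   \code{"z-rho"}.
#' @return list with axes \code{u}, \code{v} and matrix \code{values}
#'   (density per nm^2, rows = u = first named coordinate).
#' @export
project_density <- function(grid, plane = c("z-x", "z-y", "y-x", "z-rho")) {
  plane <- match.arg(plane)
  h <- grid$spacing
  v <- grid$values  # dims x, y, z
  if (plane == "z-x") {
    m <- apply(v, c(3, 1), sum) * h
    out <- list(u = grid$axes$z, v = grid$axes$x, values = m, plane = plane)
  } else if (plane == "z-y") {
    m <- apply(v, c(3, 2), sum) * h
    out <- list(u = grid$axes$z, v = grid$axes$y, values = m, plane = plane)
  } else if (plane == "y-x") {
    m <- apply(v, c(2, 1), sum) * h
    out <- list(u = grid$axes$y, v = grid$axes$x, values = m, plane = plane)
  } else {
    rho_edges <- seq(0, max(abs(grid$axes$x)) * sqrt(2) + h, by = h)
    rho_mid <- rho_edges[-1] - h / 2
    nx <- length(grid$axes$x)
    rho_xy <- sqrt(outer(grid$axes$x^2, grid$axes$y^2, `+`))
    bin <- findInterval(rho_xy, rho_edges, rightmost.closed = TRUE)
    nz <- length(grid$axes$z)
    m <- matrix(0, nrow = nz, ncol = length(rho_mid))
    for (k in seq_len(nz)) {
      sl <- v[, , k]
      s <- vapply(seq_along(rho_mid),
                  function(j) sum(sl[bin == j]), numeric(1))
      m[k, ] <- s * h  # mass per (z, rho) cell / (h^2)
    }
    out <- list(u = grid$axes$z, v = rho_mid, values = m, plane = plane)
  }
  out
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' \code{sum(P * log(P / Q))} in nats over the common support. Inputs are
#' normalized internally; both must be non-negative, with the same length,
#' and \code{Q} must be positive wherever \code{P} is.
#'
#' @param P,Q numeric vectors or arrays of identical dimension.
#' @param floor optional pseudo-mass added to empty Q bins before
#'   normalization (default 0: support mismatch is an error).
#' @return divergence in nats (non-negative).
#' @export
kl_divergence <- function(P, Q, floor = 0) {
  if (length(P) != length(Q)) stop("KL divergence: support mismatch")
  if (any(P < 0) || any(Q < 0)) stop("KL divergence: negative mass")
  P <- P / sum(P)
  if (floor > 0) Q <- Q + floor
  Q <- Q / sum(Q)
  on <- P > 0
  if (any(Q[on] == 0)) stop("KL divergence: Q vanishes where P > 0")
  sum(P[on] * log(P[on] / Q[on]))
}
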