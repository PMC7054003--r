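# The double-helical actin binding-site lattice.
#
# F-actin is a two-start helix: 13 subunits per strand per helical repeat,
# axial rise dz/2 per site index with dz = 72/13 nm, azimuthal twist
# -12*pi/13 per index. The bound head sits at site n = 0 (the origin).

#' Wrap angles to (-pi, pi]
#'
#' @param phi angle(s), radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(phi) {
  w <- phi %% (2 * pi)          # [0, 2*pi)
  big <- w > pi
  w[big] <- w[big] - 2 * pi
  w
}

#' Actin binding-site lattice
#'
#' @param R helix radius, nm.
#' @param dz subunit axial size, nm (72/13 by default so that 26 indices span
#'   one 72 nm repeat).
#' @param n_max maximum absolute site index kept (must cover at least one
#'   full repeat, i.e. \code{n_max >= 26}).
#' @return object of class \code{actin_lattice} with the index set
#'   \code{-n_max:n_max}.
#' @export
actin_lattice <- function(R = 5.5, dz = 72 / 13, n_max = 39) {
  stopifnot(R > 0, dz > 0)
  if (n_max < 26) stop("n_max must be >= 26 (one full helical repeat each way)")
  structure(list(R = R, dz = dz, n_max = as.integer(n_max),
                 sites = seq.int(-n_max, n_max)),
            class = "actin_lattice")
}

check_site_index <- function(lattice, n) {
  if (any(abs(n) > lattice$n_max) || any(n != round(n)))
    stop("site index out of range: |n| must be <= n_max and integer")
  as.integer(n)
}

#' Binding-site positions
#'
#' \code{r_n = (R (cos(phi_n) - 1), R sin(phi_n), n dz / 2)} with twist
#' \code{phi_n = -12 pi n / 13}. Vectorized over \code{n}.
#'
#' @param lattice \code{actin_lattice}.
#' @param n site index (integer, |n| <= n_max).
#' @return matrix with one row per index and columns x, y, z (nm).
#' @export
site_position <- function(lattice, n) {
  n <- check_site_index(lattice, n)
  phi <- -12 * pi * n / 13
  cbind(x = lattice$R * (cos(phi) - 1),
        y = lattice$R * sin(phi),
        z = n * lattice$dz / 2)
}

#' Outward-normal azimuth of a binding site
#'
#' @inheritParams site_position
#' @return \code{phi_n = -12 pi n / 13} wrapped to (-pi, pi], radians.
#' @export
site_normal_azimuth <- function(lattice, n) {
  n <- check_site_index(lattice, n)
  wrap_angle(-12 * pi * n / 13)
}

#' Azimuthal binding-acceptance test
#'
#' Binding requires the free-leg azimuth \code{phi_f} to be anti-parallel to
#' the site normal within the acceptance window:
#' \code{delta1 > wrap((phi_f + pi) - phi_n) > -delta2}.
#'
#' @param phi_f free-leg azimuth(s), radians (any real; wrapped internally).
#' @param phi_n site normal azimuth, radians.
#' @param delta1,delta2 half-widths, radians in [0, pi] (symmetric by
#'   default: pass the same value for both).
#' @return logical vector.
#' @export
acceptance_test <- function(phi_f, phi_n, delta1, delta2 = delta1) {
  if (delta1 < 0 || delta1 > pi || delta2 < 0 || delta2 > pi)
    stop("acceptance half-widths must lie in [0, pi]")
  d <- wrap_angle((phi_f + pi) - phi_n)
  d < delta1 & d > -delta2
}

#' @export
print.actin_lattice <- function(x, ...) {
  cat(sprintf("Actin lattice: R = %g nm, dz = %.4f nm, sites -%d..%d\n",
              x$R, x$dz, x$n_max, x$n_max))
  invisible(x)
}

#' Lattice table export
#'
#' @param x \code{actin_lattice}.
#' @param ... unused.
#' @return data.frame with columns n, x, y, z (nm) and phi_n (radians).
#' @export
as.data.frame.actin_lattice <- function(x, ...) {
  pos <- site_position(x, x$sites)
  data.frame(n = x$sites, pos, phi_n = site_normal_azimuth(x, x$sites))
}
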