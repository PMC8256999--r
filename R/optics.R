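#' Optical parameters of a simulated tissue sample
#'
#' Bundles the five polarization effects a turbid biological sample exhibits
#' into one parameter set: linear diattenuation (dichroism) `d` at azimuth
#' `theta_d`, circular diattenuation `cd`, linear retardance (birefringence)
#' `delta` with fast axis `theta_r`, optical rotation (circular birefringence)
#' `psi`, and a diagonal depolarizer `(a, b, c)` scaling the three polarized
#' Stokes components.
#'
#' @param d Linear diattenuation, in `[0, 1]`.
#' @param theta_d Diattenuation axis azimuth, radians.
#' @param cd Circular diattenuation, in `(-1, 1)`.
#' @param delta Linear retardance, radians.
#' @param theta_r Retarder fast-axis azimuth, radians.
#' @param psi Optical rotation, radians.
#' @param a,b,c Depolarization diagonal, each in `(0, 1]`; 1 means no
#'   depolarization of that component.
#' @return An object of class `optical_params` (a named list).
#' @export
optical_params <- function(d = 0, theta_d = 0, cd = 0,
                           delta = 0, theta_r = 0, psi = 0,
                           a = 1, b = 1, c = 1) {
  p <- list(d = d, theta_d = theta_d, cd = cd, delta = delta,
            theta_r = theta_r, psi = psi, a = a, b = b, c = c)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1)))) {
    stop("all optical parameters must be finite scalars")
  }
  if (d < 0 || d > 1) stop("linear diattenuation d must lie in [0, 1]")
  if (abs(cd) >= 1) stop("circular diattenuation cd must lie in (-1, 1)")
  if (sqrt(d^2 + cd^2) > 1) {
    stop("total diattenuation sqrt(d^2 + cd^2) must not exceed 1")
  }
  for (nm in c("a", "b", "c")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) {
      stop("depolarization diagonal '", nm, "' must lie in (0, 1]")
    }
  }
  structure(p, class = "optical_params")
}

#' Mueller matrix of a diattenuator
#'
#' Standard normalized diattenuator with diattenuation vector
#' `D = (d cos 2t, d sin 2t, cd)`: first row and column `(1, D)`, lower-right
#' block `sqrt(1 - |D|^2) I + (1 - sqrt(1 - |D|^2)) D_hat D_hat'`. With
#' `d = cd = 0` it is the identity; `d = 1, theta_d = 0` is the ideal
#' horizontal polarizer (up to the conventional 1/2 intensity prefactor,
#' which normalization removes).
#'
#' @param d Linear diattenuation in `[0, 1]`.
#' @param theta_d Diattenuation axis azimuth, radians.
#' @param cd Circular diattenuation in `(-1, 1)`.
#' @return 4x4 Mueller matrix with `m11 = 1`.
#' @export
build_diattenuator <- function(d = 0, theta_d = 0, cd = 0) {
  optical_params(d = d, theta_d = theta_d, cd = cd)  # range validation
  D <- c(d * cos(2 * theta_d), d * sin(2 * theta_d), cd)
  Dn <- sqrt(sum(D^2))
  if (Dn == 0) return(diag(4))
  Dhat <- D / Dn
  inner <- sqrt(1 - Dn^2) * diag(3) +
    (1 - sqrt(1 - Dn^2)) * tcrossprod(Dhat)
  m <- rbind(c(1, D), cbind(D, inner))
  dimnames(m) <- NULL
  m
}

#' Mueller matrix of an elliptical retarder
#'
#' Linear retarder of retardance `delta` at fast-axis azimuth `theta_r`,
#' followed by a circular retarder (optical rotator) of rotation `psi`. The
#' lower-right 3x3 block is a proper rotation (orthogonal, determinant 1);
#' the first row and column are `(1, 0, 0, 0)`.
#'
#' @param delta Linear retardance, radians.
#' @param theta_r Fast-axis azimuth, radians.
#' @param psi Optical rotation, radians (rotates the polarization azimuth by
#'   `psi`, i.e. the `(s1, s2)` plane by `2 psi`).
#' @return 4x4 Mueller matrix.
#' @export
build_retarder <- function(delta = 0, theta_r = 0, psi = 0) {
  optical_params(delta = delta, theta_r = theta_r, psi = psi)
  co <- cos(2 * theta_r); si <- sin(2 * theta_r)
  cd <- cos(delta); sd <- sin(delta)
  lr <- rbind(
    c(1, 0, 0, 0),
    c(0, co^2 + si^2 * cd, co * si * (1 - cd), -si * sd),
    c(0, co * si * (1 - cd), si^2 + co^2 * cd,  co * sd),
    c(0, si * sd, -co * sd, cd)
  )
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  rot <- rbind(
    c(1, 0, 0, 0),
    c(0, c2, -s2, 0),
    c(0, s2, c2, 0),
    c(0, 0, 0, 1)
  )
  rot %*% lr
}

#' Mueller matrix of a diagonal depolarizer
#'
#' `diag(1, a, b, c)`: preserves intensity and scales the three polarized
#' Stokes components, so the degree of polarization never increases.
#'
#' @param a,b,c Depolarization diagonal, each in `(0, 1]`.
#' @return 4x4 diagonal Mueller matrix.
#' @export
build_depolarizer <- function(a = 1, b = 1, c = 1) {
  optical_params(a = a, b = b, c = c)
  diag(c(1, a, b, c))
}

#' Compose a sample Mueller matrix from its optical parameters
#'
#' Fixed composition order depolarizer x retarder x diattenuator (the
#' conventional forward polar-decomposition order). All-neutral parameters
#' give the identity, and `m11 = 1` always, since each factor has a unit
#' `(1, 1)` element and the diattenuator is the first element the beam meets.
#'
#' @param p An [optical_params()] object.
#' @return 4x4 Mueller matrix.
#' @export
compose_sample_matrix <- function(p) {
  if (!inherits(p, "optical_params")) p <- do.call(optical_params, as.list(p))
  build_depolarizer(p$a, p$b, p$c) %*%
    build_retarder(p$delta, p$theta_r, p$psi) %*%
    build_diattenuator(p$d, p$theta_d, p$cd)
}
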