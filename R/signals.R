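# Roots of the derivative of the first-order spherical Bessel function,
# j1'(x) = 0, i.e. 2 x cos x + (x^2 - 2) sin x = 0. These are the eigenvalue
# roots of the Gaussian-phase-distribution (Murday-Cotts) series for diffusion
# restricted in an impermeable sphere.
.bessel_env <- new.env(parent = emptyenv())

sphere_bessel_roots <- function(n = 60L) {
  key <- as.character(n)
  if (!is.null(.bessel_env[[key]])) return(.bessel_env[[key]])
  f <- function(x) 2 * x * cos(x) + (x^2 - 2) * sin(x)
  xs <- seq(1e-3, (n + 2) * pi, length.out = 200 * (n + 2))
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(sgn, function(i) {
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, 0)
  roots <- roots[roots > 1]   # drop the spurious sign change near 0 if any
  if (length(roots) < n) stop("failed to bracket enough Bessel-derivative roots", call. = FALSE)
  .bessel_env[[key]] <- roots[seq_len(n)]
  .bessel_env[[key]]
}

#' Isotropic free-diffusion (Ball) attenuation
#'
#' @param b b-value(s) in s/mm^2.
#' @param D Diffusivity in 1e-3 mm^2/s (so `b * D / 1000` is dimensionless).
#' @return Signal attenuation exp(-bD) in (0, 1].
#' @examples
#' ball_signal(1000, 1)  # exp(-1)
#' @export
ball_signal <- function(b, D) {
  if (any(b < 0)) stop("b must be non-negative", call. = FALSE)
  exp(-b * D * 1e-3)
}

# primary axis from polar/azimuthal angles
axis_from_angles <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# rotation matrix with columns = eigenvectors (primary, secondary, tertiary)
rotation_from_angles <- function(theta, phi, alpha) {
  n <- axis_from_angles(theta, phi)
  e_theta <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
  nxe <- c(n[2] * e_theta[3] - n[3] * e_theta[2],
           n[3] * e_theta[1] - n[1] * e_theta[3],
           n[1] * e_theta[2] - n[2] * e_theta[1])
  m <- cos(alpha) * e_theta + sin(alpha) * nxe
  p <- c(n[2] * m[3] - n[3] * m[2],
         n[3] * m[1] - n[1] * m[3],
         n[1] * m[2] - n[2] * m[1])
  cbind(n, m, p, deparse.level = 0)
}

check_unit_dirs <- function(g, G) {
  nrm <- sqrt(rowSums(g^2))
  if (any(G > 0 & abs(nrm - 1) > 1e-9)) {
    stop("gradient directions must be unit vectors where G > 0", call. = FALSE)
  }
}

#' Cylindrically symmetric tensor (Zeppelin) attenuation
#'
#' Axially symmetric anisotropic free diffusion with principal diffusivity
#' `D1` along the axis defined by polar angle `theta` and azimuth `phi`, and
#' `D2` perpendicular to it.
#'
#' @param scheme An `acq_scheme` (or data frame with gx, gy, gz, b columns).
#' @param D1,D2 Parallel and perpendicular diffusivities (1e-3 mm^2/s).
#' @param theta,phi Orientation of the principal axis (rad).
#' @return Attenuation per measurement.
#' @export
zeppelin_signal <- function(scheme, D1, D2, theta, phi) {
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  check_unit_dirs(g, scheme$G)
  n <- axis_from_angles(theta, phi)
  ct2 <- as.vector(g %*% n)^2
  exp(-scheme$b * ((D1 - D2) * ct2 + D2) * 1e-3)
}

#' Full tensor attenuation
#'
#' Anisotropic free diffusion \eqn{\exp(-b\, g^T D g)} with eigenvalues
#' `D1 >= D2 >= D3` and eigenvectors given by `(theta, phi, alpha)`.
#'
#' @inheritParams zeppelin_signal
#' @param D3 Tertiary diffusivity (1e-3 mm^2/s).
#' @param alpha Rotation of the secondary eigenvector about the primary axis (rad).
#' @return Attenuation per measurement.
#' @export
tensor_signal <- function(scheme, D1, D2, D3, theta, phi, alpha) {
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  check_unit_dirs(g, scheme$G)
  R <- rotation_from_angles(theta, phi, alpha)
  gr <- g %*% R
  quad <- gr[, 1]^2 * D1 + gr[, 2]^2 * D2 + gr[, 3]^2 * D3
  exp(-scheme$b * quad * 1e-3)
}

#' Restricted diffusion in an impermeable sphere (GPD approximation)
#'
#' Gaussian-phase-distribution (Murday-Cotts) series for the PGSE signal of
#' water restricted in a sphere of radius `R`:
#' \deqn{\ln E = -2\gamma^2 G^2 \sum_m
#'   \frac{1}{\alpha_m^2(\alpha_m^2 R^2 - 2)}\left[
#'   \frac{2\delta}{\alpha_m^2 D} - \frac{2 + e^{-\alpha_m^2 D(\Delta-\delta)}
#'   - 2e^{-\alpha_m^2 D\delta} - 2e^{-\alpha_m^2 D\Delta}
#'   + e^{-\alpha_m^2 D(\Delta+\delta)}}{\alpha_m^4 D^2}\right]}
#' where \eqn{\alpha_m = \mu_m / R} and \eqn{\mu_m} are the roots of the
#' derivative of the first-order spherical Bessel function. The signal is
#' orientation independent.
#'
#' @param scheme An `acq_scheme` (columns G, delta, Delta used; mT/m and ms).
#' @param D_I Intracellular diffusivity (1e-3 mm^2/s).
#' @param R Sphere radius (micrometres).
#' @param n_roots Maximum number of series terms.
#' @param tol Relative truncation tolerance on ln E (with a 1e-12 absolute
#'   floor); exceeding it at `n_roots` terms raises a convergence error.
#' @return Attenuation per measurement, in (0, 1].
#' @export
sphere_signal <- function(scheme, D_I, R, n_roots = 60L, tol = 1e-9) {
  gamma <- scheme_gamma(scheme)
  sphere_signal_raw(G = scheme$G * 1e-3, delta = scheme$delta * 1e-3,
                    Delta = scheme$Delta * 1e-3, D = D_I * 1e-9, R = R * 1e-6,
                    gamma = gamma, n_roots = n_roots, tol = tol)
}

# SI-unit core: G in T/m, times in s, D in m^2/s, R in m
sphere_signal_raw <- function(G, delta, Delta, D, R, gamma = GAMMA_PROTON,
                              n_roots = 60L, tol = 1e-9) {
  mu <- sphere_bessel_roots(n_roots)
  a2 <- (mu / R)^2                     # alpha_m^2, 1/m^2
  a2D <- a2 * D                        # 1/s
  n <- length(G)
  # term matrix: measurements x roots
  e1 <- exp(-outer(Delta - delta, a2D))
  e2 <- exp(-outer(delta, a2D))
  e3 <- exp(-outer(Delta, a2D))
  e4 <- exp(-outer(Delta + delta, a2D))
  num <- sweep(-(2 + e1 - 2 * e2 - 2 * e3 + e4), 2, a2D^2, "/")
  num <- num + outer(2 * delta, 1 / a2D)
  terms <- sweep(num, 2, a2 * (mu^2 - 2), "/")
  lnE <- -2 * gamma^2 * G^2 * rowSums(terms)
  tail_term <- 2 * gamma^2 * G^2 * abs(terms[, n_roots])
  scale <- pmax(abs(lnE), 1e-30)
  if (any(G > 0 & tail_term > pmax(tol * scale, 1e-12))) {
    stop("GPD series did not converge within ", n_roots,
         " terms (max tail term ", format(max(tail_term)), "); increase n_roots",
         call. = FALSE)
  }
  exp(lnE)
}

fold_angle <- function(x, period) ((x %% period) + period) %% period

#' Canonical fundamental domain for orientation angles
#'
#' Maps (theta, phi) to theta in \[0, pi/2\] (antipodal equivalence) with
#' phi in \[0, 2*pi) and alpha in \[0, pi).
#' @param theta,phi,alpha Angles in radians.
#' @return Named list of folded angles.
#' @export
fold_orientation <- function(theta, phi, alpha = 0) {
  theta <- fold_angle(theta, 2 * pi)
  if (theta > pi) { theta <- 2 * pi - theta; phi <- phi + pi }
  if (theta > pi / 2) { theta <- pi - theta; phi <- phi + pi }
  list(theta = theta, phi = fold_angle(phi, 2 * pi), alpha = fold_angle(alpha, pi))
}
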