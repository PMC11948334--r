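#' polimage: image-charge electrostatics for charged polarizable spheres
#'
#' Tools for the pair interaction of charged dielectric (polarizable) spheres
#' in a homogeneous medium: Neumann's image principle for a single sphere,
#' its exact three-point reformulation (two surface-point charges and one
#' central image dipole), iterative image-reflection solvers for the
#' two-sphere energy and force, and closed-form first-level critical
#' conditions for the onset of like-charge attraction (LCA).
#'
#' Internally everything is computed in reduced Gaussian-style units: lengths
#' in nanometres, charges in elementary charges, energies in units of
#' e^2/(4 pi eps0 nm) (= `energy_unit_eV()` electron-volts) and forces in
#' e^2/(4 pi eps0 nm^2). The factor 1/eps_out multiplies every interaction.
#'
#' @keywords internal
"_PACKAGE"

#' Energy conversion constants
#'
#' One reduced energy unit is e^2/(4 pi eps0 nm). `energy_unit_eV()` returns
#' its value in electron-volts; `energy_unit_kT()` its value in units of
#' k_B T at the given temperature.
#'
#' @param temperature Temperature in kelvin (default 298.15).
#' @return A numeric scalar.
#' @examples
#' energy_unit_eV() # about 1.44 eV
#' @export
energy_unit_eV <- function() 1.43996454

#' @rdname energy_unit_eV
#' @export
energy_unit_kT <- function(temperature = 298.15) {
  1.43996454 * 1.602176634e-19 / (1.380649e-23 * temperature)
}

#' Specify one polarizable sphere
#'
#' A sphere of radius `a` (nm) with relative permittivity `eps_in` carrying a
#' point charge `Q` (in elementary charges) at its centre. `eps_in = Inf` is
#' the perfect-conductor limit.
#'
#' @param a Sphere radius in nm, positive.
#' @param eps_in Relative permittivity of the sphere interior, positive
#'   (may be `Inf` for a conductor).
#' @param Q Central charge in units of the elementary charge e.
#' @return An object of class `sphere_spec`.
#' @examples
#' sphere_spec(a = 1.25, eps_in = 20, Q = -7)
#' @export
sphere_spec <- function(a, eps_in, Q = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(eps_in),
            length(eps_in) == 1L, is.numeric(Q), length(Q) == 1L)
  if (!is.finite(a) || a <= 0) stop("sphere radius 'a' must be finite and > 0")
  if (is.na(eps_in) || eps_in <= 0) stop("'eps_in' must be > 0")
  structure(list(a = a, eps_in = eps_in, Q = Q), class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("<sphere_spec> a = %g nm, eps_in = %g, Q = %g e\n",
              x$a, x$eps_in, x$Q))
  invisible(x)
}

#' Specify the embedding medium
#'
#' @param eps_out Relative permittivity of the homogeneous medium, finite
#'   and positive.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(eps_out = 1) {
  stopifnot(is.numeric(eps_out), length(eps_out) == 1L)
  if (!is.finite(eps_out) || eps_out <= 0) stop("'eps_out' must be finite and > 0")
  structure(list(eps_out = eps_out), class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat(sprintf("<medium_spec> eps_out = %g\n", x$eps_out))
  invisible(x)
}

#' Two charged polarizable spheres at a given separation
#'
#' Both sphere centres lie on the z axis: sphere 1 at the origin, sphere 2 at
#' z = R. The non-overlap constraint R >= a1 + a2 is enforced.
#'
#' @param sphere1,sphere2 [sphere_spec()] objects.
#' @param medium A [medium_spec()].
#' @param R Centre-to-centre separation in nm; must satisfy `R >= a1 + a2`.
#' @return An object of class `two_sphere_system`.
#' @examples
#' s <- two_sphere_system(sphere_spec(1.25, 20, -1), sphere_spec(1.25, 20, -7),
#'                        medium_spec(1), R = 3)
#' @export
two_sphere_system <- function(sphere1, sphere2, medium = medium_spec(1), R) {
  stopifnot(inherits(sphere1, "sphere_spec"), inherits(sphere2, "sphere_spec"),
            inherits(medium, "medium_spec"), is.numeric(R), length(R) == 1L)
  if (!is.finite(R)) stop("'R' must be finite")
  if (R < sphere1$a + sphere2$a) {
    stop(sprintf("spheres overlap: R = %g < a1 + a2 = %g",
                 R, sphere1$a + sphere2$a))
  }
  structure(list(sphere1 = sphere1, sphere2 = sphere2, medium = medium, R = R),
            class = "two_sphere_system")
}

#' @export
print.two_sphere_system <- function(x, ...) {
  cat(sprintf(
    "<two_sphere_system> R = %g nm (surface gap d = %g nm), eps_out = %g\n",
    x$R, x$R - x$sphere1$a - x$sphere2$a, x$medium$eps_out))
  print(x$sphere1); print(x$sphere2)
  invisible(x)
}

#' Dielectric contrast k and screening exponent g
#'
#' `dielectric_contrast()` returns k = (eps_in - eps_out)/(eps_in + eps_out):
#' k -> 1 for a perfect conductor (eps_in -> Inf), k = 0 for index-matched
#' media, k < 0 when the medium is the more polarizable phase.
#' `screening_exponent()` returns g = eps_out/(eps_in + eps_out), the exponent
#' governing the line-image density r^(g-1); 0 < g < 1 for finite
#' permittivities and g -> 0 in the conductor limit. The two satisfy
#' k + 2 g = 1 identically.
#'
#' @param eps_in,eps_out Relative permittivities, positive; `eps_in` may be
#'   `Inf`.
#' @return A numeric scalar.
#' @examples
#' dielectric_contrast(20, 1)  # 19/21
#' dielectric_contrast(Inf, 1) # conductor: 1
#' @export
dielectric_contrast <- function(eps_in, eps_out) {
  check_eps(eps_in, eps_out)
  if (is.infinite(eps_in)) return(1)
  (eps_in - eps_out) / (eps_in + eps_out)
}

#' @rdname dielectric_contrast
#' @export
screening_exponent <- function(eps_in, eps_out) {
  check_eps(eps_in, eps_out)
  if (is.infinite(eps_in)) return(0)
  eps_out / (eps_in + eps_out)
}

check_eps <- function(eps_in, eps_out) {
  if (!is.numeric(eps_in) || length(eps_in) != 1L || is.na(eps_in) ||
      eps_in <= 0) {
    stop("'eps_in' must be a positive scalar (Inf allowed)")
  }
  if (!is.numeric(eps_out) || length(eps_out) != 1L || !is.finite(eps_out) ||
      eps_out <= 0) {
    stop("'eps_out' must be a finite positive scalar")
  }
  invisible(TRUE)
}

#' Dimensionless parameters of a two-sphere system
#'
#' Converts a [two_sphere_system()] to the dimensionless variables the
#' critical-condition theory is written in: per-sphere contact parameters
#' t_i = a_i/R (t1 + t2 = 1 at contact; for equal radii t = 1/2 at contact),
#' dielectric contrasts k_i, screening exponents g_i, the charge ratios
#' Q2/Q1 and Q1/Q2, and the combined charge/dielectric asymmetry parameter
#' chi = k1 (Q2/Q1) + k2 (Q1/Q2) used in the equal-size phase diagram.
#'
#' @param system A [two_sphere_system()].
#' @return A list of class `dimensionless_params` with elements `t1`, `t2`,
#'   `k1`, `k2`, `g1`, `g2`, `charge_ratio` (Q2/Q1), `charge_ratio_inv`, and
#'   `chi` (`NA` when either charge is zero).
#' @examples
#' s <- two_sphere_system(sphere_spec(1, 20, 1), sphere_spec(1, 20, 1), R = 2)
#' to_dimensionless(s)$t1 # 0.5 at contact
#' @export
to_dimensionless <- function(system) {
  stopifnot(inherits(system, "two_sphere_system"))
  s1 <- system$sphere1; s2 <- system$sphere2
  eo <- system$medium$eps_out; R <- system$R
  q21 <- if (s1$Q != 0) s2$Q / s1$Q else NA_real_
  q12 <- if (s2$Q != 0) s1$Q / s2$Q else NA_real_
  k1 <- dielectric_contrast(s1$eps_in, eo)
  k2 <- dielectric_contrast(s2$eps_in, eo)
  chi <- if (is.na(q21) || is.na(q12)) NA_real_ else k1 * q21 + k2 * q12
  structure(list(
    t1 = s1$a / R, t2 = s2$a / R,
    k1 = k1, k2 = k2,
    g1 = screening_exponent(s1$eps_in, eo),
    g2 = screening_exponent(s2$eps_in, eo),
    charge_ratio = q21, charge_ratio_inv = q12,
    chi = chi
  ), class = "dimensionless_params")
}
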