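#' Image-dipole strength of the three-point image formula
#'
#' The Neumann image system (Kelvin charge + line density) of a source `Q` at
#' distance R = a/t can be resummed, at the source location, into two point
#' charges -Qk/2 and +Qk/2 fixed at the sphere surface points nearest and
#' farthest from the source, plus a point dipole at the centre oriented
#' toward the source with strength
#'
#' p(t) = Q k a  sum_\{n>=0\} (g/(n+g)) t^(2n)
#'      = Q k a \[1 + g t^2/(1+g) + g t^4/(2+g) + ...\]
#'
#' `mode = "exact"` evaluates the full series (truncated at 1e-15 relative);
#' `mode = "leading"` keeps only the first term p = Q k a, the approximation
#' underlying the first-level critical-condition theory (valid when
#' 1/g >> t^2/(1+g), i.e. strongly polarizable spheres). For a conductor
#' (g = 0) the series collapses and exact equals leading.
#'
#' @param Q Source charge (e).
#' @param sphere A [sphere_spec()].
#' @param medium A [medium_spec()].
#' @param t Dimensionless source distance a/R, 0 < t < 1.
#' @param mode `"exact"` or `"leading"`.
#' @return Dipole strength in e nm, positive toward the source for Q, k > 0.
#' @export
dipole_strength <- function(Q, sphere, medium = medium_spec(1), t,
                            mode = c("exact", "leading")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t <= 0 || t >= 1) stop("'t' must lie in (0, 1)")
  k <- dielectric_contrast(sphere$eps_in, medium$eps_out)
  g <- screening_exponent(sphere$eps_in, medium$eps_out)
  base <- Q * k * sphere$a
  if (mode == "leading") base else base * dipole_series_S(g, t^2)
}

#' Three-point image set of a polarizable sphere
#'
#' Returns the three-point images induced by a source charge `Q` at distance
#' `R`: `q_near = -Qk/2` at the surface point facing the source (+a on the
#' axis), `q_far = +Qk/2` at the opposite surface point (-a), and the central
#' dipole `p_center` of [dipole_strength()]. The image positions are fixed at
#' \{+a, -a, 0\} for every source distance; only the dipole strength depends
#' on R. The pair is exactly charge-neutral, so total charge neutrality is
#' preserved. The sign assignment (near image opposite in sign to the source
#' for k > 0) is fixed by agreement with the Neumann quadrature energy.
#'
#' @inheritParams dipole_strength
#' @param R Source distance from the sphere centre (nm), `R > a`.
#' @return An object of class `image_set`: list with `q_near`, `q_far`,
#'   `p_center`, positions `pos_near = +a`, `pos_far = -a`, and `R`.
#' @export
three_point_images <- function(Q, R, sphere, medium = medium_spec(1),
                               mode = c("exact", "leading")) {
  mode <- match.arg(mode)
  a <- sphere$a
  if (!is.finite(R) || R <= a) {
    stop(sprintf("source must lie outside the sphere: R = %g <= a = %g", R, a))
  }
  k <- dielectric_contrast(sphere$eps_in, medium$eps_out)
  structure(list(
    q_near = -Q * k / 2, q_far = Q * k / 2,
    p_center = dipole_strength(Q, sphere, medium, t = a / R, mode = mode),
    pos_near = a, pos_far = -a, R = R
  ), class = "image_set")
}

#' Single-sphere polarization energy from the three-point images
#'
#' Evaluates E_pol = (1/2) Q phi(R) where phi is the potential of the
#' three-point image set at the source:
#'
#' E_pol = (1 / 2 eps_out) \[ -Q^2 k a/(R^2 - a^2) + Q p(t)/R^2 \]
#'
#' With `mode = "exact"` this equals the Neumann quadrature energy to
#' round-off (the three-point formula is an exact resummation at the source
#' point); `mode = "leading"` gives the closed approximation
#' E_pol ~ -k Q^2 a^3 / \[2 eps_out R^2 (R^2 - a^2)\].
#'
#' @inheritParams three_point_images
#' @return Polarization energy in reduced units.
#' @examples
#' s <- sphere_spec(1, 20)
#' three_point_energy(1, 2, s) - pol_energy_quadrature(1, 2, s) # ~ 0
#' @export
three_point_energy <- function(Q, R, sphere, medium = medium_spec(1),
                               mode = c("exact", "leading")) {
  mode <- match.arg(mode)
  a <- sphere$a
  if (!is.finite(R) || R <= a) {
    stop(sprintf("source must lie outside the sphere: R = %g <= a = %g", R, a))
  }
  k <- dielectric_contrast(sphere$eps_in, medium$eps_out)
  g <- screening_exponent(sphere$eps_in, medium$eps_out)
  if (k == 0) return(0)
  t <- a / R
  # (1/2) Q [q_near/(R-a) + q_far/(R+a) + p/R^2] with the pair combined to
  # -Q k a/(R^2 - a^2) and the dipole split as p = Q k a (1 + Sm1); the
  # leading parts cancel analytically, leaving a stable residual:
  # E = (k Q^2 a / 2 eo R^2) [Sm1 - t^2/(1 - t^2)]
  sm1 <- if (mode == "exact") dipole_series_Sm1(g, t^2) else 0
  (k * Q^2 * a / (2 * medium$eps_out * R^2)) * (sm1 - t^2 / (1 - t^2))
}
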