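#' Incomplete beta function B_x(g, 0)
#'
#' Evaluates B_x(g, 0) = integral from 0 to x of s^(g-1) (1-s)^(-1) ds by its
#' power series sum_{n>=0} x^(n+g)/(n+g), which converges for 0 < x < 1 and
#' g > 0. This is the special second-argument-zero case that encodes the
#' Neumann line-image energy integral; `stats::pbeta` does not cover it
#' because the underlying beta function diverges at q = 0.
#'
#' Terms decay geometrically like x^n; summation stops once the next term
#' falls below 1e-15 relative, with a hard cap of 1e5 terms (an error is
#' raised if the cap is hit while x > 0.999, the near-contact regime where
#' the series degenerates).
#'
#' @param x Upper integration limit, 0 < x < 1.
#' @param g First beta parameter, > 0.
#' @return The value of B_x(g, 0).
#' @examples
#' inc_beta_g0(0.5, 1) # -log(1 - 0.5)
#' @export
inc_beta_g0 <- function(x, g) {
  stopifnot(is.numeric(x), length(x) == 1L, is.numeric(g), length(g) == 1L)
  if (!is.finite(g) || g <= 0) stop("'g' must be > 0")
  if (!is.finite(x) || x <= 0 || x >= 1) stop("'x' must lie in (0, 1)")
  # B_x(g,0) = x^g * sum_{n>=0} x^n/(n+g)
  acc <- 0; pow <- 1; n <- 0; cap <- 1e5
  repeat {
    term <- pow / (n + g)
    acc <- acc + term
    n <- n + 1; pow <- pow * x
    if (term < 1e-15 * acc) break
    if (n >= cap) {
      if (x > 0.999) stop("inc_beta_g0: series cap reached near x = 1")
      break
    }
  }
  x^g * acc
}

# S(g, t2) = sum_{n>=0} g t2^n/(n+g) = g t2^(-g) B_{t2}(g, 0).
# The full image-dipole series in units of Q k a; S -> 1 as t2 -> 0 and
# S = 1 exactly for a conductor (g = 0).
dipole_series_S <- function(g, t2) {
  if (g == 0) return(1)
  if (t2 == 0) return(1)
  acc <- 0; pow <- 1; n <- 0
  repeat {
    term <- g * pow / (n + g)
    acc <- acc + term
    n <- n + 1; pow <- pow * t2
    if (term < 1e-15 * acc || n >= 1e5) break
  }
  acc
}

# S - 1 = sum_{n>=1} g t2^n/(n+g), summed without the unit leading term so
# downstream energy formulas can cancel it analytically instead of
# numerically (the polarization energy is t^2-fold smaller than either of
# its image contributions at long range).
dipole_series_Sm1 <- function(g, t2) {
  if (g == 0 || t2 == 0) return(0)
  acc <- 0; pow <- t2; n <- 1
  repeat {
    term <- g * pow / (n + g)
    acc <- acc + term
    n <- n + 1; pow <- pow * t2
    if (term < 1e-15 * acc || n >= 1e5) break
  }
  acc
}

# dS/d(t2) = sum_{n>=1} g n t2^(n-1)/(n+g); zero for a conductor.
dipole_series_dS <- function(g, t2) {
  if (g == 0) return(0)
  acc <- 0; pow <- 1; n <- 1
  repeat {
    term <- g * n * pow / (n + g)
    acc <- acc + term
    n <- n + 1; pow <- pow * t2
    if (term < 1e-15 * acc || n >= 1e5) break
  }
  acc
}

#' Neumann image system of a polarizable sphere
#'
#' For a point charge `Q` at distance `R` from the centre of a sphere
#' (radius a, permittivity eps_in) in a medium eps_out, the polarization
#' potential outside the sphere equals that of a Kelvin point image
#' Q_K = -k Q a/R at the inversion point r_K = a^2/R plus a line-image
#' density q_line(r) = (k Q g/a) (r/r_K)^(g-1) on r in \[0, r_K\], with
#' k the dielectric contrast and g the screening exponent. The two parts
#' cancel exactly: Q_K + integral of q_line = 0 (charge neutrality).
#'
#' The line density has an integrable r^(g-1) singularity at the origin; it
#' is discretized into `n_nodes` point charges by a Gauss-Jacobi rule whose
#' weight function is exactly r^(g-1), so the singular factor is handled by
#' construction and the accuracy is uniform in g (including the
#' near-conducting regime g -> 0, where the line mass collapses toward the
#' centre). For an exact conductor (g = 0) the line reduces analytically to
#' a single point charge +k Q a/R at the centre.
#'
#' @param Q Source charge (e).
#' @param R Source distance from the sphere centre (nm), `R > a`.
#' @param sphere A [sphere_spec()] (its central charge is irrelevant here).
#' @param medium A [medium_spec()].
#' @param n_nodes Number of discretization nodes for the line image.
#' @return An object of class `line_image`: a list with `kelvin_charge`,
#'   `kelvin_position`, `positions` and `weights` of the discretized line
#'   (positions measured from the sphere centre toward the source), the
#'   density function `q_line(r)`, and `k`, `g`, `a`, `R`.
#' @examples
#' li <- neumann_images(1, 3, sphere_spec(1, 20), medium_spec(1))
#' li$kelvin_charge + sum(li$weights) # ~ 0
#' @export
neumann_images <- function(Q, R, sphere, medium = medium_spec(1),
                           n_nodes = 64L) {
  stopifnot(inherits(sphere, "sphere_spec"), inherits(medium, "medium_spec"),
            is.numeric(Q), length(Q) == 1L, is.numeric(R), length(R) == 1L)
  if (n_nodes < 1) stop("'n_nodes' must be >= 1")
  a <- sphere$a
  if (!is.finite(R) || R <= a) {
    stop(sprintf("source must lie outside the sphere: R = %g <= a = %g", R, a))
  }
  k <- dielectric_contrast(sphere$eps_in, medium$eps_out)
  g <- screening_exponent(sphere$eps_in, medium$eps_out)
  r_K <- a^2 / R
  Q_K <- -k * Q * a / R
  if (g < 1e-7) {
    # (near-)conductor: the r^(g-1) line measure degenerates into a point
    # mass at the centre faster than double precision can resolve (its
    # median sits at exp(-O(1/g))); the exact g -> 0 image pair is then
    # accurate to O(g), far below the quadrature's attainable accuracy
    positions <- 0
    weights <- k * Q * a / R
  } else {
    gj <- gauss_jacobi_01(n_nodes, g)
    positions <- r_K * gj$x
    # density(r) dr = (k Q g / a) x^(g-1) r_K dx on x in [0, 1]
    weights <- (k * Q * g * r_K / a) * gj$w
  }
  q_line <- function(r) {
    out <- numeric(length(r))
    ok <- r > 0 & r <= r_K
    if (g > 0) out[ok] <- (k * Q * g / a) * (r[ok] / r_K)^(g - 1)
    out
  }
  structure(list(kelvin_charge = Q_K, kelvin_position = r_K,
                 positions = positions, weights = weights, q_line = q_line,
                 k = k, g = g, a = a, R = R),
            class = "line_image")
}

# Gauss-Legendre rule on [0, 1]; cached.
gauss_legendre_01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <<- list(x = gl$x, w = gl$w)
    }
    cache[[key]]
  }
})

# Gauss-Jacobi rule for integrals of x^(g-1) f(x) over [0, 1]:
# returns nodes x and weights w with sum w_i f(x_i) ~ integral, the weight
# function absorbed into w. Built by Golub-Welsch from the Jacobi(alpha = 0,
# beta = g - 1) three-term recurrence; accuracy is uniform in g, which
# matters because g can be ~1e-8 (near-conducting spheres) where the
# integrable singularity x^(g-1) degenerates into a point mass at 0.
gauss_jacobi_01 <- local({
  cache <- list()
  function(n, g) {
    key <- sprintf("%d_%.17g", n, g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    al <- 0; be <- g - 1
    k <- seq_len(n - 1)
    diag0 <- c((be - al) / (al + be + 2),
               (be^2 - al^2) /
                 ((2 * k + al + be) * (2 * k + al + be + 2)))
    b2 <- c(4 * (1 + al) * (1 + be) / ((2 + al + be)^2 * (3 + al + be)),
            if (n > 2) {
              kk <- 2:(n - 1)
              4 * kk * (kk + al) * (kk + be) * (kk + al + be) /
                ((2 * kk + al + be)^2 * (2 * kk + al + be + 1) *
                 (2 * kk + al + be - 1))
            })
    J <- diag(diag0)
    if (n > 1) {
      off <- sqrt(b2[seq_len(n - 1)])
      J[cbind(k, k + 1)] <- off
      J[cbind(k + 1, k)] <- off
    }
    ev <- eigen(J, symmetric = TRUE)
    mu0 <- 2^(al + be + 1) * beta(al + 1, be + 1)  # = 2^g / g for al = 0
    w_std <- mu0 * ev$vectors[1, ]^2
    ord <- order(ev$values)
    out <- list(x = (1 + ev$values[ord]) / 2, w = 2^(-g) * w_std[ord])
    cache[[key]] <<- out
    out
  }
})

#' Single-sphere polarization energy, three equivalent routes
#'
#' The polarization energy of a point charge `Q` at distance `R` from a
#' polarizable sphere is E_pol = (1/2) Q times the polarization potential at
#' the source, the 1/2 arising because image charges are fictitious
#' (linear-response) charges:
#'
#' E_pol = (Q / 2 eps_out) \[ Q_K/(R - r_K) + integral q_line(r)/(R - r) dr \]
#'
#' `pol_energy_quadrature()` evaluates the line integral numerically with
#' the singular-weight Gauss-Jacobi rule of [neumann_images()] (`n_nodes`
#' nodes). `pol_energy_beta()` evaluates the same quantity in
#' closed form through the incomplete beta function,
#' E_pol = (k Q^2 / 2 eps_out R) \[ g t^(1-2g) B_\{t^2\}(g,0) - t/(1-t^2) \]
#' with t = a/R; the two agree to full quadrature accuracy because they are
#' exact reformulations of one another. Energies are in reduced units of
#' e^2/(4 pi eps0 nm): negative for eps_in > eps_out (attraction to the
#' image), positive for a medium more polarizable than the sphere.
#'
#' @inheritParams neumann_images
#' @return Polarization energy in reduced units.
#' @examples
#' pol_energy_beta(1, 2, sphere_spec(1, 20), medium_spec(1))
#' @export
pol_energy_quadrature <- function(Q, R, sphere, medium = medium_spec(1),
                                  n_nodes = 64L) {
  li <- neumann_images(Q, R, sphere, medium, n_nodes)
  if (li$k == 0) return(0)
  # Kelvin and line contributions cancel to O(t^2) at large R; summing them
  # separately would lose up to 1/t^2 relative digits. Exploit the exact
  # neutrality sum(weights) = -Q_K to recombine the sum pairwise:
  #   E = (Q/2 eo) sum_i w_i [1/(R - r_i) - 1/(R - r_K)]
  #     = (Q/2 eo) sum_i w_i (r_i - r_K) / ((R - r_i)(R - r_K))
  # whose terms all share one sign, so the evaluation is cancellation-free.
  terms <- li$weights * (li$positions - li$kelvin_position) /
    ((R - li$positions) * (R - li$kelvin_position))
  Q * sum(terms) / (2 * medium$eps_out)
}

#' @rdname pol_energy_quadrature
#' @export
pol_energy_beta <- function(Q, R, sphere, medium = medium_spec(1)) {
  stopifnot(inherits(sphere, "sphere_spec"), inherits(medium, "medium_spec"))
  a <- sphere$a
  if (!is.finite(R) || R <= a) {
    stop(sprintf("source must lie outside the sphere: R = %g <= a = %g", R, a))
  }
  k <- dielectric_contrast(sphere$eps_in, medium$eps_out)
  g <- screening_exponent(sphere$eps_in, medium$eps_out)
  if (k == 0) return(0)
  t <- a / R
  # g t^(1-2g) B_{t^2}(g,0) = t S(g, t^2) with S = 1 + Sm1; the unit parts
  # of tS and t/(1-t^2) are cancelled analytically for numerical stability
  (k * Q^2 / (2 * medium$eps_out * R)) *
    (t * (dipole_series_Sm1(g, t^2) - t^2 / (1 - t^2)))
}
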