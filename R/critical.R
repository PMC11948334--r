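# First-level (single-reflection, leading-dipole) theory of like-charge
# attraction and the closed-form critical conditions derived from it.
#
# With leading-order image dipoles p = Q k a, the polarization energy a
# charge Q gains from a sphere at distance R collapses to
# -k Q^2 a^3/[2 eps_out R^2 (R^2 - a^2)], and the first-level two-sphere
# energy is bare Coulomb plus one such term per sphere. Setting the force
# -dE/dR to zero and rescaling by the Coulomb force gives the dimensionless
# critical condition
#
#   k1 (Q2/Q1) f(t1) + k2 (Q1/Q2) f(t2) = 1,  f(t) = t^3 (2-t^2)/(1-t^2)^2
#
# with t_i = a_i/R. f is strictly increasing on (0,1), so solving for the
# outermost root in R is a bracketed one-dimensional search.

#' Shape factor of the first-level critical condition
#'
#' `lca_shape_factor(t)` returns f(t) = t^3 (2 - t^2)/(1 - t^2)^2, the
#' geometric weight with which each sphere's polarizability enters the
#' critical condition; `lca_h_factor(t)` returns H(t) = -f(t), the
#' (negative-definite on the physical domain) factor the dimensionless
#' condition can equivalently be written with, 1 + chi H(t) = 0. At contact
#' of equal spheres f(1/2) = 7/18, which is the origin of the 18/7
#' threshold.
#'
#' @param t Contact parameter(s) a/R in (0, 1); vectorized.
#' @return Numeric vector.
#' @export
lca_shape_factor <- function(t) {
  stopifnot(all(t > 0 & t < 1))
  t^3 * (2 - t^2) / (1 - t^2)^2
}

#' @rdname lca_shape_factor
#' @export
lca_h_factor <- function(t) -lca_shape_factor(t)

#' First-level two-sphere energy and force (closed form)
#'
#' The total electrostatic energy truncated at the first image reflection
#' with leading-order dipoles:
#'
#' E = (1/eps_out) \[ Q1 Q2/R
#'       - k1 Q2^2 a1^3/(2 R^2 (R^2 - a1^2))
#'       - k2 Q1^2 a2^3/(2 R^2 (R^2 - a2^2)) \]
#'
#' `first_level_force()` is its analytic derivative F = -dE/dR:
#'
#' F = (1/eps_out) \[ Q1 Q2/R^2
#'       - k1 Q2^2 a1^3 (2R^2 - a1^2)/(R^3 (R^2 - a1^2)^2)
#'       - k2 Q1^2 a2^3 (2R^2 - a2^2)/(R^3 (R^2 - a2^2)^2) \]
#'
#' F > 0 repulsive, F < 0 attractive. This truncation furnishes a necessary
#' condition for attraction: by the alternating-series remainder theorem,
#' if F_coul + F_1 is repulsive at every separation then so is the fully
#' converged force.
#'
#' @param system A [two_sphere_system()].
#' @return Energy (reduced units) or force (reduced units per nm).
#' @export
first_level_energy <- function(system) {
  stopifnot(inherits(system, "two_sphere_system"))
  s1 <- system$sphere1; s2 <- system$sphere2
  eo <- system$medium$eps_out; R <- system$R
  k1 <- dielectric_contrast(s1$eps_in, eo)
  k2 <- dielectric_contrast(s2$eps_in, eo)
  (s1$Q * s2$Q / R -
     k1 * s2$Q^2 * s1$a^3 / (2 * R^2 * (R^2 - s1$a^2)) -
     k2 * s1$Q^2 * s2$a^3 / (2 * R^2 * (R^2 - s2$a^2))) / eo
}

#' @rdname first_level_energy
#' @export
first_level_force <- function(system) {
  stopifnot(inherits(system, "two_sphere_system"))
  s1 <- system$sphere1; s2 <- system$sphere2
  eo <- system$medium$eps_out; R <- system$R
  k1 <- dielectric_contrast(s1$eps_in, eo)
  k2 <- dielectric_contrast(s2$eps_in, eo)
  (s1$Q * s2$Q / R^2 -
     k1 * s2$Q^2 * s1$a^3 * (2 * R^2 - s1$a^2) / (R^3 * (R^2 - s1$a^2)^2) -
     k2 * s1$Q^2 * s2$a^3 * (2 * R^2 - s2$a^2) / (R^3 * (R^2 - s2$a^2)^2)) / eo
}

#' Dimensionless first-level critical condition
#'
#' Returns the residual of the general critical condition,
#' k1 (Q2/Q1) f(t1) + k2 (Q1/Q2) f(t2) - 1, evaluated on a
#' [to_dimensionless()] parameter set. The residual is zero exactly where
#' the first-level force vanishes; it is negative where that force is
#' repulsive (for like charges) and positive where it is attractive, since
#' F = -(Q1 Q2 / eps_out R^2) * residual.
#'
#' @param params A `dimensionless_params` object from [to_dimensionless()],
#'   or a [two_sphere_system()] (converted internally).
#' @return The residual (dimensionless scalar).
#' @export
critical_condition_general <- function(params) {
  if (inherits(params, "two_sphere_system")) params <- to_dimensionless(params)
  stopifnot(inherits(params, "dimensionless_params"))
  if (is.na(params$charge_ratio) || is.na(params$charge_ratio_inv)) {
    stop("critical condition requires two nonzero central charges")
  }
  if (params$t1 + params$t2 > 1 + 1e-12) {
    stop("nonphysical geometry: t1 + t2 > 1 (overlapping spheres)")
  }
  params$k1 * params$charge_ratio * lca_shape_factor(params$t1) +
    params$k2 * params$charge_ratio_inv * lca_shape_factor(params$t2) - 1
}

#' Critical separation for like-charge attraction
#'
#' Solves the first-level critical condition for the critical
#' centre-to-centre distance R_c >= a1 + a2: attraction is predicted for
#' every R < R_c, repulsion beyond. The residual is scanned on 512 points
#' uniformly in x = (a1+a2)/R over (0, 1\] (better conditioned near contact
#' than a scan in R) up to `R_max = 1000 (a1+a2)`, every sign change is
#' bisected to 1e-12, and the outermost crossing (largest R) is reported as
#' R_c — attraction first switches on there as the spheres approach. Absence
#' of a crossing is the valid result `lca_occurs = FALSE` (e.g. equal-sized
#' equal-charged spheres, or a medium more polarizable than the spheres).
#'
#' @param system A [two_sphere_system()] (its `R` slot is ignored; the
#'   condition is solved over all separations). Charges must satisfy
#'   Q1 Q2 > 0 (like charges).
#' @param n_scan Number of scan points.
#' @return An object of class `critical_result`: list with `lca_occurs`,
#'   `R_c`, `t_c` (c(t1, t2) at R_c), `residual` (residual at R_c),
#'   `method = "eq_first_level"`, and `all_crossings` (all roots found).
#'   When `lca_occurs` is FALSE the numeric fields are NA.
#' @examples
#' sys <- two_sphere_system(sphere_spec(1.25, 20, -1),
#'                          sphere_spec(1.25, 20, -7), medium_spec(1), R = 3)
#' solve_rc(sys)
#' @export
solve_rc <- function(system, n_scan = 512L) {
  stopifnot(inherits(system, "two_sphere_system"))
  s1 <- system$sphere1; s2 <- system$sphere2
  if (s1$Q * s2$Q <= 0) {
    stop("solve_rc: the critical condition applies to like charges (Q1 Q2 > 0)")
  }
  R0 <- s1$a + s2$a
  resid_at <- function(R) {
    critical_condition_general(to_dimensionless(with_separation(system, R)))
  }
  x <- seq(1e-4, 1, length.out = n_scan)   # x = R0/R; x = 1 is contact
  Rs <- R0 / x
  res <- vapply(Rs, resid_at, numeric(1))
  sgn <- sign(res)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  crossings <- numeric(0)
  for (i in flips) {
    root <- stats::uniroot(resid_at, lower = Rs[i + 1], upper = Rs[i],
                           tol = 1e-12)$root
    crossings <- c(crossings, root)
  }
  # exact-contact root (residual zero precisely at x = 1)
  if (length(flips) == 0 && abs(res[n_scan]) < 1e-12) crossings <- R0
  if (length(crossings) == 0) {
    return(structure(list(lca_occurs = FALSE, R_c = NA_real_,
                          t_c = c(t1 = NA_real_, t2 = NA_real_),
                          residual = NA_real_, method = "eq_first_level",
                          all_crossings = numeric(0)),
                     class = "critical_result"))
  }
  R_c <- max(crossings)
  structure(list(lca_occurs = TRUE, R_c = R_c,
                 t_c = c(t1 = s1$a / R_c, t2 = s2$a / R_c),
                 residual = resid_at(R_c), method = "eq_first_level",
                 all_crossings = sort(crossings)),
            class = "critical_result")
}

#' @export
print.critical_result <- function(x, ...) {
  if (!x$lca_occurs) {
    cat("<critical_result> no like-charge attraction at any separation\n")
  } else {
    cat(sprintf(
      "<critical_result> LCA for R < R_c = %.6f nm (t1 = %.4f, t2 = %.4f, %s)\n",
      x$R_c, x$t_c[["t1"]], x$t_c[["t2"]], x$method))
  }
  invisible(x)
}

#' Critical separation from a converged reflection solver
#'
#' Locates the zero crossing of the fully converged force (default: the
#' Neumann-reflection oracle) by bracket expansion around a seed (the
#' first-level R_c when it exists) followed by `uniroot`. Used to validate
#' the closed-form theory.
#'
#' @param system A [two_sphere_system()].
#' @param method `"neumann"` or `"three_point"`.
#' @param tol Reflection convergence tolerance.
#' @param seed_Rc Optional initial guess for R_c; defaults to the
#'   first-level prediction.
#' @param ... Passed to the solver via [force()].
#' @return The numeric R_c, or NA if no sign change is found.
#' @export
solve_rc_numeric <- function(system, method = c("neumann", "three_point"),
                             tol = 1e-12, seed_Rc = NULL, ...) {
  method <- match.arg(method)
  R0 <- system$sphere1$a + system$sphere2$a
  if (is.null(seed_Rc)) {
    th <- solve_rc(system)
    if (!th$lca_occurs) return(NA_real_)
    seed_Rc <- th$R_c
  }
  fo <- function(R) force(with_separation(system, R), method = method,
                          tol = tol, ...)
  lo <- max(0.9 * seed_Rc, R0 * 1.002); hi <- 1.1 * seed_Rc
  flo <- fo(lo); fhi <- fo(hi)
  for (i in seq_len(60)) {
    if (flo * fhi < 0) break
    if (abs(flo) < abs(fhi)) {
      lo <- max(lo * 0.97, R0 * 1.002); flo <- fo(lo)
    } else {
      hi <- hi * 1.05; fhi <- fo(hi)
    }
  }
  if (flo * fhi >= 0) return(NA_real_)
  stats::uniroot(fo, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Equal-size contact threshold of the asymmetry parameter
#'
#' For equal-sized spheres the critical condition reads
#' chi f(t) = 1 with chi = k1 (Q2/Q1) + k2 (Q1/Q2). Setting t = 1/2
#' (spheres in contact, R_c = 2a) gives the threshold
#' chi_c = 1/f(1/2) = 18/7: below it attraction cannot occur at any
#' separation; above it a critical separation exists. With equal charges
#' chi reduces to k1 + k2 <= 2 < 18/7, so equal-sized symmetrically charged
#' spheres always repel.
#'
#' @return chi_c = 18/7 (computed from the closed form, not hard-coded).
#' @export
contact_threshold_equal_size <- function() {
  1 / lca_shape_factor(0.5)
}

#' Critical-condition phase diagrams
#'
#' Traces the zero set of the first-level critical condition as an implicit
#' curve, in two standard cuts:
#'
#' * `mode = "equal_size"`: equal radii; abscissa is the asymmetry parameter
#'   chi = k1 (Q2/Q1) + k2 (Q1/Q2), ordinate the critical contact parameter
#'   t_c solving chi f(t_c) = 1. No curve exists below chi = 18/7 (no LCA);
#'   the attraction region lies at t > t_c.
#' * `mode = "equal_charge"`: equal charges and permittivities, unequal
#'   sizes; for each polarizability k the curve t2(t1) solves
#'   k \[f(t1) + f(t2)\] = 1. Points with t1 + t2 > 1 violate non-overlap and
#'   are masked. Larger k encloses the region of smaller k; as k -> 0 the
#'   attraction region shrinks to the point-charge limit.
#'
#' @param mode `"equal_size"` or `"equal_charge"`.
#' @param abscissa Grid of chi values (equal_size) or t1 values
#'   (equal_charge). Defaults cover the standard plots.
#' @param k_values Polarizability values for `equal_charge` mode.
#' @return A data.frame of class `phase_diagram` with columns `mode`, `k`,
#'   `abscissa`, `critical_value`, `masked`.
#' @export
phase_diagram <- function(mode = c("equal_size", "equal_charge"),
                          abscissa = NULL, k_values = c(0.01, 0.1, 0.5, 1)) {
  mode <- match.arg(mode)
  finv <- function(y) {
    # inverse of f on (0, 1): f is strictly increasing, f(0+) = 0, f(1-) = Inf
    if (y <= 0) return(NA_real_)
    stats::uniroot(function(t) lca_shape_factor(t) - y,
                   lower = 1e-9, upper = 1 - 1e-9, tol = 1e-13)$root
  }
  if (mode == "equal_size") {
    if (is.null(abscissa)) abscissa <- seq(1.5, 12, by = 0.05)
    tc <- vapply(abscissa, function(chi) {
      if (chi < contact_threshold_equal_size()) return(NA_real_)
      root <- finv(1 / chi)
      if (root > 0.5 + 1e-9) NA_real_ else min(root, 0.5)
    }, numeric(1))
    out <- data.frame(mode = mode, k = NA_real_, abscissa = abscissa,
                      critical_value = tc, masked = FALSE)
  } else {
    if (is.null(abscissa)) abscissa <- seq(0.005, 0.995, by = 0.005)
    stopifnot(all(k_values > 0 & k_values <= 1))
    rows <- lapply(k_values, function(k) {
      t2 <- vapply(abscissa, function(t1) {
        y <- 1 / k - lca_shape_factor(t1)
        if (y <= 0) return(0)          # already attractive for any t2
        finv(y)
      }, numeric(1))
      masked <- abscissa + t2 > 1 + 1e-12
      data.frame(mode = mode, k = k, abscissa = abscissa,
                 critical_value = ifelse(masked, NA_real_, t2),
                 masked = masked)
    })
    out <- do.call(rbind, rows)
  }
  class(out) <- c("phase_diagram", "data.frame")
  out
}
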