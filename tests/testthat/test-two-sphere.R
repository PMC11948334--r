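test_that("without dielectric contrast both solvers give bare Coulomb", {
  s <- make_pair(1, 2, -1, -3, eps1 = 5, eps2 = 5, eps_out = 5, R = 4)
  expect_identical(as.numeric(reflect_neumann(s)), -1 * -3 / (5 * 4))
  expect_identical(as.numeric(reflect_three_point(s)), 3 / 20)
  expect_equal(force(s, "coulomb"), 3 / (5 * 16), tolerance = 1e-15)
})

test_that("an inert partner reduces to the single-sphere energy", {
  # sphere 2 index-matched (k2 = 0): just a bare point charge Q2 whose only
  # effect is Coulomb plus polarizing sphere 1
  s <- make_pair(1, 0.8, -2, -5, eps1 = 20, eps2 = 1, R = 3.5)
  e_coul <- (-2) * (-5) / 3.5
  e_pol <- pol_energy_quadrature(-5, 3.5, sphere_spec(1, 20), vacuum, 64L)
  expect_equal(as.numeric(reflect_neumann(s, n_nodes = 64L)) - e_coul, e_pol,
               tolerance = 1e-10)
  expect_equal(as.numeric(reflect_three_point(s)) - e_coul, e_pol,
               tolerance = 1e-10)
})

test_that("relabelling the spheres leaves the energy unchanged", {
  s12 <- make_pair(1, 2.5, -1, -6, 15, 80, R = 5)
  s21 <- make_pair(2.5, 1, -6, -1, 80, 15, R = 5)
  expect_equal(as.numeric(reflect_neumann(s12)),
               as.numeric(reflect_neumann(s21)), tolerance = 1e-12)
  expect_equal(as.numeric(reflect_three_point(s12)),
               as.numeric(reflect_three_point(s21)), tolerance = 1e-13)
})

test_that("conducting-sphere forces match the capacitance-series oracle", {
  # independent bispherical/capacitance route, fixed charges
  a <- 1; b <- 2; E <- 1e12
  for (cc in c(3.2, 3.5, 4, 6)) {
    f_caps <- -numeric_derivative(function(x) {
      conducting_pair_energy(a, b, x, -1, -1)
    }, cc)
    sys <- make_pair(a, b, -1, -1, E, E, R = cc)
    f_pkg <- force(sys, "neumann", n_nodes = 32L, n_grid = 64L)
    expect_lt(rel_diff(f_caps, f_pkg), 1e-7)
  }
})

test_that("three-point reflections track the Neumann oracle", {
  # The accumulated three-point recursion is exact at level 1 and
  # approximate beyond (the three-point set only reproduces the response
  # potential at the inducing source's own distance). Its converged energy
  # tracks the exact oracle within measured envelopes that tighten fast
  # with separation: ~10% at a 5% surface gap, sub-percent at half-radius
  # gaps, ppm-level beyond a few diameters.
  eps_set <- c(5, 20, 100, 1e4)
  ratios <- c(1, 3, 7)
  envelope <- c("0.05" = 0.15, "0.5" = 1e-2, "5" = 1e-5)
  for (eps in eps_set) {
    for (q in ratios) {
      err <- vapply(c(0.05, 0.5, 5), function(dfrac) {
        s <- make_pair(1, 1, -1, -q, eps, eps, R = 2 * (1 + dfrac))
        rel_diff(as.numeric(reflect_neumann(s, n_nodes = 32L, n_grid = 56L)),
                 as.numeric(reflect_three_point(s)))
      }, numeric(1))
      expect_true(all(err < envelope),
                  label = sprintf("eps=%g q=%g: %s", eps, q,
                                  paste(signif(err, 2), collapse = " ")))
      expect_true(all(diff(err) < 0))   # improves monotonically with d
    }
  }
})

test_that("per-level force contributions alternate and die out", {
  s <- benchmark_pair(2.5 + 0.5)    # d = 0.5 nm
  ld <- level_decomposition(s, n_levels = 6L, method = "neumann")
  f <- ld$force[ld$level >= 1]
  # strict sign alternation level to level
  expect_true(all(sign(f[-1]) == -sign(f[-length(f)])))
  # decay to zero with the reflection level: stepwise monotone within each
  # sphere-to-sphere round trip (levels two apart) and vanishing overall;
  # consecutive levels can transiently cross because even and odd levels
  # are fed by differently charged root sources (Q1 vs Q2)
  expect_true(all(abs(f[-(1:2)]) < abs(f[seq_len(length(f) - 2)])))
  expect_lt(abs(f[6]), 1e-2 * abs(f[2]))
  # first level is attractive here, Coulomb repulsive
  expect_gt(ld$force[ld$level == 0], 0)
  expect_lt(f[1], 0)
})

test_that("energy increments alternate and decay geometrically by pairs", {
  s <- benchmark_pair(3.2)
  res <- reflect_neumann(s, tol = 1e-14)
  lv <- attr(res, "levels")
  keep <- abs(lv) > 1e-12 * abs(as.numeric(res))   # above roundoff floor
  lv <- lv[keep]
  expect_true(all(sign(lv[-1]) == -sign(lv[-length(lv)])))
  # one round trip multiplies the envelope by at most ~ (k1 a1^2/R^2)(k2
  # a2^2/R^2)-type factors; bound the two-level ratio by k1 k2 a1 a2/R^2
  # with margin
  k <- dielectric_contrast(20, 1)
  bound <- k * k * (1.25 * 1.25 / 3.2^2) * 1.3
  two_lev <- abs(lv[-(1:2)] / lv[seq_len(length(lv) - 2)])
  expect_true(all(two_lev <= bound))
  # increments shrink monotonically pairwise all the way down
  expect_true(all(two_lev < 1))
})

test_that("polarization dies off and the force approaches Coulomb", {
  s1 <- sphere_spec(1, 20, -1); s2 <- sphere_spec(1, 20, -7)
  R <- 100 * 2
  sys <- two_sphere_system(s1, s2, vacuum, R)
  expect_lt(rel_diff(force(sys, "three_point"), force(sys, "coulomb")), 1e-4)
  expect_lt(rel_diff(force(sys, "neumann"), force(sys, "coulomb")), 1e-4)
})

test_that("a more polarizable medium forbids attraction everywhere", {
  # eps_out > eps_in: the exact force is repulsive at every separation
  for (d in c(0.05, 0.2, 1, 5)) {
    s <- make_pair(1, 1, 1, 5, eps1 = 2, eps2 = 2, eps_out = 80, R = 2 + d)
    expect_gt(force(s, "neumann"), 0)
    # the approximate three-point recursion respects this at moderate
    # contrast (its near-contact error can exceed the small net force at
    # |k| ~ 1, so the oracle is the referee there)
    s2 <- make_pair(1, 1, 1, 5, eps1 = 2, eps2 = 2, eps_out = 5, R = 2 + d)
    expect_gt(force(s2, "three_point"), 0)
  }
})

test_that("force curve assembles all methods on a common grid", {
  fc <- force_curve(sphere_spec(1.25, 20, -1), sphere_spec(1.25, 20, -7),
                    vacuum, d = c(0.3, 1, 3),
                    methods = c("coulomb", "first_level", "three_point"))
  expect_s3_class(fc, "force_curve")
  expect_equal(fc$R_nm, fc$d_nm + 2.5)
  expect_equal(fc$F_coulomb, 7 / fc$R_nm^2, tolerance = 1e-14)
  expect_true(all(c("E_first_level", "F_three_point") %in% names(fc)))
  # attractive near contact, repulsive at range, for the converged method
  expect_lt(fc$F_three_point[1], 0)
  expect_gt(fc$F_three_point[3], 0)
})

test_that("non-converging setups raise a convergence error", {
  s <- benchmark_pair(2.52)
  expect_error(reflect_neumann(s, max_level = 3L), "not converged")
})
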