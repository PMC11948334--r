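test_that("contact threshold of the equal-size condition is 18/7", {
  expect_equal(contact_threshold_equal_size(), 18 / 7, tolerance = 1e-14)
  # equal charges make chi = k1 + k2 <= 2, always below threshold
  expect_lt(2, 18 / 7)
})

test_that("first-level closed form equals one leading-order reflection", {
  systems <- list(benchmark_pair(3), make_pair(1, 4, -1, -1, 9, 9, R = 6),
                  make_pair(0.5, 1, 2, 3, 50, 10, eps_out = 2, R = 2.2))
  for (s in systems) {
    expect_lt(rel_diff(first_level_energy(s),
                       as.numeric(reflect_three_point(s, mode = "leading"))),
              1e-12)
  }
})

test_that("analytic first-level force matches numeric differentiation", {
  set.seed(42)
  for (i in seq_len(100)) {
    a1 <- runif(1, 0.5, 2); a2 <- runif(1, 0.5, 2)
    R <- (a1 + a2) * runif(1, 1.05, 3)
    s <- make_pair(a1, a2, q1 = sample(c(-1, 1), 1) * runif(1, 0.5, 5),
                   q2 = sample(c(-1, 1), 1) * runif(1, 0.5, 5),
                   eps1 = runif(1, 2, 100), eps2 = runif(1, 2, 100),
                   eps_out = runif(1, 0.5, 2), R = R)
    fn <- numeric_derivative(function(r) {
      -first_level_energy(with_separation_test(s, r))
    }, R)
    scale <- max(abs(fn), abs(force(s, "coulomb")))
    expect_lt(abs(fn - first_level_force(s)) / scale, 1e-8)
  }
})

test_that("the dimensionless residual is the rescaled first-level force", {
  s0 <- benchmark_pair(3)
  for (R in seq(2.6, 8, length.out = 20)) {
    s <- with_separation_test(s0, R)
    resid <- critical_condition_general(to_dimensionless(s))
    f <- first_level_force(s)
    f_coul <- force(s, "coulomb")
    expect_lt(abs(f - (-f_coul * resid)), 1e-12 * abs(f_coul))
  }
  # long range: Coulomb repulsion dominates, residual -> -1
  far <- with_separation_test(s0, 1e3)
  expect_lt(abs(critical_condition_general(to_dimensionless(far)) + 1), 1e-6)
})

test_that("equal-sized equally-charged spheres never attract", {
  for (eps in c(5, 20, 1e6)) {
    s <- make_pair(1, 1, -3, -3, eps, eps, R = 2)
    expect_false(solve_rc(s)$lca_occurs)
  }
  # even mixed permittivities cannot push chi past 2
  s <- make_pair(1, 1, -3, -3, 5, 1e6, R = 2)
  expect_false(solve_rc(s)$lca_occurs)
  # and the converged force is repulsive right down to near contact
  for (d in c(0.02, 0.1, 1)) {
    expect_gt(force(make_pair(1, 1, -3, -3, 1e4, 1e4, R = 2 + d), "neumann"),
              0)
  }
})

test_that("medium more polarizable than the spheres: no critical point", {
  s <- make_pair(1, 1, 1, 9, eps1 = 2, eps2 = 2, eps_out = 80, R = 2)
  expect_false(solve_rc(s)$lca_occurs)
  s <- make_pair(1, 5, 2, 2, eps1 = 10, eps2 = 10, eps_out = 40, R = 6)
  expect_false(solve_rc(s)$lca_occurs)
})

test_that("benchmark system: critical separation and 1st-level consistency", {
  s <- benchmark_pair(3)
  res <- solve_rc(s)
  expect_true(res$lca_occurs)
  expect_gt(res$R_c, 2.5)
  # root of the residual coincides with the first-level force sign change
  eps_R <- 1e-6 * res$R_c
  expect_gt(first_level_force(with_separation_test(s, res$R_c + eps_R)), 0)
  expect_lt(first_level_force(with_separation_test(s, res$R_c - eps_R)), 0)
  expect_lt(abs(res$residual), 1e-10)
  # converged-solver crossing lies close by (sub-2% for this system)
  rn <- solve_rc_numeric(s, method = "neumann")
  expect_lt(abs(res$R_c - rn) / rn, 0.02)
  r3 <- solve_rc_numeric(s, method = "three_point")
  expect_lt(abs(res$R_c - r3) / r3, 0.01)
})

test_that("strong size asymmetry with conducting spheres attracts", {
  s <- make_pair(1, 8, -1, -1, Inf, Inf, R = 9)
  res <- solve_rc(s)
  expect_true(res$lca_occurs)
  expect_gt(res$R_c, 9)
  rn <- solve_rc_numeric(s, method = "neumann", n_nodes = 24L)
  expect_lt(abs(res$R_c - rn) / rn, 0.005)
})

test_that("no-attraction verdicts are confirmed by the converged force", {
  # first-level necessary condition: where the theory finds no root, the
  # converged force must be repulsive at every separation
  s <- make_pair(1, 2, -1, -1, 4, 4, R = 3)   # k = 0.6, size ratio 2
  expect_false(solve_rc(s)$lca_occurs)
  for (d in c(0.03, 0.1, 0.3, 1, 3)) {
    expect_gt(force(with_separation_test(s, 3 + d), "neumann",
                    n_nodes = 24L), 0)
  }
})

test_that("just past the contact threshold the root appears at contact", {
  # pick k = 0.9 and the charge ratio putting chi a hair above 18/7
  k <- 0.9
  chi <- 18 / 7 * (1 + 1e-4)
  q <- (chi / k + sqrt((chi / k)^2 - 4)) / 2
  eps <- (1 + k) / (1 - k)
  s <- make_pair(1, 1, -1, -q, eps, eps, R = 2)
  res <- solve_rc(s)
  expect_true(res$lca_occurs)
  expect_equal(res$t_c[["t1"]], 0.5, tolerance = 1e-2)
  # and a hair below, no attraction anywhere
  chi2 <- 18 / 7 * (1 - 1e-4)
  q2 <- (chi2 / k + sqrt((chi2 / k)^2 - 4)) / 2
  expect_false(solve_rc(make_pair(1, 1, -1, -q2, eps, eps, R = 2))$lca_occurs)
})

test_that("unlike charges are rejected by the critical-condition solver", {
  expect_error(solve_rc(make_pair(1, 1, -1, 2, 20, 20, R = 3)), "like charges")
})

test_that("equal-size phase diagram starts at 18/7 and stays below contact", {
  pd <- phase_diagram("equal_size", abscissa = seq(2, 6, by = 0.1))
  below <- pd[pd$abscissa < 18 / 7, ]
  above <- pd[pd$abscissa >= 18 / 7 + 1e-9, ]
  expect_true(all(is.na(below$critical_value)))
  expect_true(all(!is.na(above$critical_value)))
  expect_true(all(above$critical_value <= 0.5 + 1e-12))
  # attraction region grows with chi: critical t decreases
  expect_true(all(diff(above$critical_value) < 0))
  # curve point satisfies the condition
  i <- nrow(above)
  expect_equal(above$abscissa[i] * lca_shape_factor(above$critical_value[i]),
               1, tolerance = 1e-9)
})

test_that("equal-charge phase diagram nests with polarizability", {
  pd <- phase_diagram("equal_charge", abscissa = seq(0.05, 0.95, by = 0.05),
                      k_values = c(0.1, 0.5, 1))
  ok <- function(k) {
    sub <- pd[pd$k == k & !pd$masked, ]
    stats::setNames(sub$critical_value, format(sub$abscissa))
  }
  c1 <- ok(1); c05 <- ok(0.5)
  common <- intersect(names(c1), names(c05))
  expect_gt(length(common), 3)
  # larger k: smaller critical t2 at the same t1 (bigger attraction region);
  # where both curves have collapsed to the axis (already attractive for
  # any partner size) they coincide at zero
  strict <- common[c05[common] > 0]
  expect_gt(length(strict), 3)
  expect_true(all(c1[strict] < c05[strict]))
  expect_true(all(c1[setdiff(common, strict)] == 0))
  # k -> 0: the physical (unmasked) curve disappears except the degenerate
  # point-charge corner
  pd0 <- phase_diagram("equal_charge", abscissa = seq(0.05, 0.95, by = 0.05),
                       k_values = 0.01)
  expect_true(all(pd0$masked | pd0$critical_value == 0))
  expect_gt(sum(pd0$masked), 0.9 * nrow(pd0))
})

test_that("masking enforces the non-overlap constraint", {
  pd <- phase_diagram("equal_charge", abscissa = c(0.3, 0.6, 0.9),
                      k_values = 0.8)
  phys <- pd[!pd$masked, ]
  expect_true(all(phys$abscissa + phys$critical_value <= 1 + 1e-9))
})
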