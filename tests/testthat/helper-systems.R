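# Shared fixtures: reference systems and independent oracles, all built in
# code at test time.

vacuum <- medium_spec(1)

# The benchmark pair: equal 1.25 nm spheres, charges -1e and -7e, eps = 20,
# in vacuum. Shows like-charge attraction below R ~ 3.15 nm.
benchmark_pair <- function(R) {
  two_sphere_system(sphere_spec(1.25, 20, -1), sphere_spec(1.25, 20, -7),
                    vacuum, R)
}

make_pair <- function(a1, a2, q1, q2, eps1, eps2, eps_out = 1, R) {
  two_sphere_system(sphere_spec(a1, eps1, q1), sphere_spec(a2, eps2, q2),
                    medium_spec(eps_out), R)
}

# Independent oracle: classical capacitance coefficients for two external
# conducting spheres (radii a, b, centre distance c), in units 4 pi eps0 = 1:
#   cosh U = (c^2 - a^2 - b^2)/(2ab)
#   Caa = ab sinh U * sum_{n>=0} 1/(a sinh nU + b sinh (n+1)U)
#   Cbb = likewise with a and b swapped
#   Cab = -(ab/c) sinh U * sum_{n>=1} 1/sinh(nU)
# Fixed-charge energy is W = Q' P Q / 2 with P the inverse capacitance
# matrix. This bispherical series is independent of every image-reflection
# code path in the package.
conducting_pair_energy <- function(a, b, c, Qa, Qb, n_terms = 2000) {
  U <- acosh((c^2 - a^2 - b^2) / (2 * a * b))
  n <- seq_len(n_terms)
  sh <- function(x) sinh(pmin(x, 700))  # overflow guard; 1/sinh(700) ~ 0
  Caa <- a * b * sinh(U) * (1 / (b * sh(U)) +
                            sum(1 / (a * sh(n * U) + b * sh((n + 1) * U))))
  Cbb <- a * b * sinh(U) * (1 / (a * sh(U)) +
                            sum(1 / (b * sh(n * U) + a * sh((n + 1) * U))))
  Cab <- -(a * b / c) * sinh(U) * sum(1 / sh(n * U))
  P <- solve(matrix(c(Caa, Cab, Cab, Cbb), 2, 2))
  Q <- c(Qa, Qb)
  0.5 * sum(Q * (P %*% Q))
}

# Richardson-extrapolated central difference, matching the package's force
# stencil but applied to arbitrary scalar functions (test-side oracle).
numeric_derivative <- function(f, x, h = 1e-5 * x) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

rel_diff <- function(x, y) abs(x - y) / pmax(abs(x), abs(y))

with_separation_test <- function(system, R) {
  two_sphere_system(system$sphere1, system$sphere2, system$medium, R)
}
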