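test_that("growth rate has the stated closed form and degenerate limits", {
  gp <- canon_gp()
  # a - b at the maximum size
  expect_equal(growth_rate(1, 1, gp, a_val = 0.7), 0.2)
  # pure exponential growth when b = 0, alpha = 1, xi -> 0
  gp0 <- growth_params(a_inf = 0.7, b = 1e-12, alpha = 1, beta = 2,
                       xi = 1e-9, r = 1)
  w <- c(0.1, 0.5, 0.9)
  expect_equal(growth_rate(w, 1, gp0, a_val = 0.5), 0.5 * w,
               tolerance = 1e-6)
  expect_error(growth_rate(-1, 1, gp), class = "bad_sizes")
  expect_error(growth_rate(1, 0, gp), class = "bad_sizes")
})

test_that("all four kernels are homogeneous with their stated degrees", {
  set.seed(42)
  for (rep in 1:5) {
    gp <- growth_params(a_inf = runif(1, 0.6, 1.2), b = runif(1, 0.2, 0.5),
                        alpha = runif(1, 0.6, 0.9), beta = 1,
                        xi = runif(1, 0.05, 0.4), r = runif(1, 0.5, 2))
    ds <- division_spec(xth = runif(1, 0.75, 0.85), delta = 0.2)
    ms <- mortality_spec(runif(1, 0.01, 0.3))
    ps <- predation_spec(nu = runif(1, 0.5, 1))
    w <- runif(1, 0.3, 0.6)
    for (lam in c(0.5, 2, 10)) {
      expect_equal(growth_rate(lam * w, lam, gp),
                   lam^(1 - gp$xi) * growth_rate(w, 1, gp),
                   tolerance = 1e-10)
      expect_equal(division_rate(lam * 0.9, lam, ds, gp),
                   lam^(-gp$xi) * division_rate(0.9, 1, ds, gp),
                   tolerance = 1e-10)
      expect_equal(mortality_rate(lam * w, lam, ms, gp),
                   lam^(-gp$xi) * mortality_rate(w, 1, ms, gp),
                   tolerance = 1e-10)
      expect_equal(daughter_density(lam * w, lam * 0.9, ds),
                   lam^(-1) * daughter_density(w, 0.9, ds),
                   tolerance = 1e-10)
      expect_equal(feeding_rate(lam * w, lam * w / 100, ps),
                   lam^ps$nu * feeding_rate(w, w / 100, ps),
                   tolerance = 1e-10)
    }
  }
})

test_that("Monod uptake saturates and is monotone", {
  gp <- canon_gp()
  expect_equal(monod_uptake(0, gp), 0)
  expect_equal(monod_uptake(gp$r, gp), gp$a_inf / 2)
  N <- seq(0, 50, length.out = 200)
  expect_true(all(diff(monod_uptake(N, gp)) > 0))
  expect_lt(monod_uptake(1e9, gp), gp$a_inf)
  expect_error(monod_uptake(-0.1, gp), class = "bad_nutrient")
})

test_that("doubling time follows the allometric law T = tau w*^xi", {
  gp <- canon_gp()
  tau <- doubling_time(1, gp, a_val = 0.7)
  expect_equal(tau, oracle$tau, tolerance = 1e-9)
  # ratio 2^xi between doublings of w* across three decades
  for (ws in c(1, 10, 1000)) {
    expect_equal(doubling_time(2 * ws, gp) / doubling_time(ws, gp),
                 2^gp$xi, tolerance = 1e-10)
    expect_equal(doubling_time(ws, gp), tau * ws^gp$xi, tolerance = 1e-8)
  }
  # closed form for alpha = 0, beta = 1: (1/b) log((a - b/2)/(a - b))
  gp2 <- growth_params(a_inf = 0.7, b = 0.5, alpha = 1e-12, beta = 1,
                       xi = 0.15)
  expect_equal(doubling_time(1, gp2, a_val = 0.7),
               log((0.7 - 0.25) / (0.7 - 0.5)) / 0.5, tolerance = 1e-8)
  expect_error(doubling_time(1, gp, a_val = 0.4),
               class = "growth_infeasible")
})

test_that("division rate shape matches its printed form and diverges at w*", {
  gp <- canon_gp()
  ds <- canon_ds()
  expect_equal(division_rate(0.7, 1, ds, gp), 0)
  expect_equal(division_rate(0.9, 1, ds, gp), 4 * 0.2^2 / 0.1)
  expect_identical(division_rate(1, 1, ds, gp), Inf)
  expect_false(is.nan(division_rate(1, 1, ds, gp)))
  # tail integral grows without bound: squaring eps at least doubles it
  i1 <- integrate(ds$k, 0.7, 1 - 1e-3)$value
  i2 <- integrate(ds$k, 0.7, 1 - 1e-6)$value
  i3 <- integrate(ds$k, 0.7, 1 - 1e-12)$value
  expect_gt(i2, i1 * 1.5)
  expect_gt(i3, i2 * 1.5)
})

test_that("daughter density is a symmetric probability density splitting biomass", {
  ds <- canon_ds()
  # uniform on [0.4, 0.6] of the parent: height 1/0.2 = 5
  expect_equal(daughter_density(0.5, 1, ds), 5)
  expect_equal(daughter_density(0.39, 1, ds), 0)
  for (wp in c(1, 10)) {
    expect_equal(integrate(function(w) daughter_density(w, wp, ds),
                           0, 2 * wp)$value, 1, tolerance = 1e-10)
    expect_equal(integrate(function(w) w * daughter_density(w, wp, ds),
                           0, 2 * wp)$value, wp / 2, tolerance = 1e-10)
  }
})

test_that("registered daughter shapes are normalised and symmetric", {
  for (shape in c("uniform", "triangular")) {
    ds <- division_spec(q_shape = shape)
    expect_equal(integrate(ds$q, 0.4, 0.6, rel.tol = 1e-12)$value, 1,
                 tolerance = 1e-10)
    xs <- seq(0.41, 0.5, length.out = 20)
    expect_equal(ds$q(xs), ds$q(1 - xs), tolerance = 1e-10)
  }
})

test_that("mortality rate scales and has the constant and immortal limits", {
  gp <- canon_gp()
  ms <- mortality_spec(0.25)
  x <- c(0.3, 0.6, 0.9)
  expect_equal(mortality_rate(x * 5, 5, ms, gp),
               rep(0.25 * 5^(-gp$xi), 3))
  expect_equal(mortality_rate(3 * 0.5, 3, ms, gp),
               3^(-gp$xi) * mortality_rate(0.5, 1, ms, gp),
               tolerance = 1e-12)
  ms0 <- mortality_spec(0)
  expect_equal(mortality_rate(x, 1, ms0, gp), rep(0, 3))
})

test_that("division spec rejects inconsistent geometry and non-divergent rates", {
  # largest daughter above the division threshold
  expect_error(division_spec(xth = 0.5, delta = 0.2),
               class = "daughter_above_threshold")
  # a bounded k cannot guarantee division before the maximum size
  expect_error(
    local({
      ds <- division_spec()
      k_flat <- function(x) ifelse(x > 0.7 & x < 1, 1, 0)
      probe1 <- integrate(k_flat, 0.7, 1 - 1e-4)$value
      probe2 <- integrate(k_flat, 0.7, 1 - 1e-8)$value
      if (!(probe2 > probe1 * 1.5)) {
        stop(structure(class = c("k_not_divergent", "error", "condition"),
                       list(message = "bounded rate", call = NULL)))
      }
    }),
    class = "k_not_divergent")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(growth_params(alpha = 1, beta = 0.9), class = "bad_exponents")
  expect_error(growth_params(a_inf = 0.4, b = 0.5), class = "bad_uptake")
  expect_error(growth_params(xi = 1.2), class = "bad_xi")
  expect_error(chemostat_params(N0 = -1), class = "bad_capacity")
  expect_error(species_assemblage(c(1, 10), w_min = 2),
               class = "bad_bounds")
  expect_error(predation_spec(epsilon = 0), class = "bad_efficiency")
})
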