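test_that("feeding rate is homogeneous of degree nu with a peaked ratio
           kernel", {
  ps <- canon_ps()
  expect_equal(feeding_rate(10 * 2, 10 * 0.02, ps),
               10^ps$nu * feeding_rate(2, 0.02, ps), tolerance = 1e-12)
  # preference peaks at the preferred ratio and vanishes in both tails
  expect_gt(ps$s(100), ps$s(10))
  expect_gt(ps$s(100), ps$s(1000))
  expect_lt(ps$s(1e-6), 1e-10)
  expect_lt(ps$s(1e10), 1e-10)
  # nu = 0: rate depends on the ratio only
  ps0 <- predation_spec(nu = 0)
  expect_equal(feeding_rate(200, 2, ps0), feeding_rate(500, 5, ps0))
})

test_that("kernel moments match the log-normal closed form and divergent
           moments are rejected", {
  ps <- canon_ps()
  closed <- function(p, mu = log(100), sig = 1, s0 = 1) {
    s0 * sqrt(2 * pi) * sig * exp((p + 1) * mu + (p + 1)^2 * sig^2 / 2)
  }
  for (p in c(-1.15, -1, -0.5, 0.3)) {
    expect_equal(prey_kernel_moment(ps, p), closed(p), tolerance = 1e-9)
  }
  # a kernel flat in log ratio has no finite moments
  ps_flat <- predation_spec()
  ps_flat$s <- function(y) rep_len(1, length(y))
  expect_error(prey_kernel_moment(ps_flat, -1),
               class = "kernel_moment_divergent")
})

test_that("power-law predation mortality equals the direct spectrum integral
           and scales with degree -xi", {
  gp <- canon_gp()
  ps <- canon_ps()
  z0 <- 0.05
  gamma <- 1 + ps$nu + gp$xi
  ms <- predation_mortality(z0, ps, gp, background = mortality_spec(0.02))
  # direct quadrature of the predation integral with z_c = z0 w^{-gamma}
  direct <- function(w, w_star) {
    pred <- integrate(function(u) {
      wp <- exp(u)
      feeding_rate(wp, w, ps) * z0 * wp^(-gamma) * wp
    }, log(w) - 35, log(w) + 35, rel.tol = 1e-11)$value
    pred + 0.02 * w_star^(-gp$xi)
  }
  for (w in c(0.3, 0.7)) {
    expect_equal(mortality_rate(w, 1, ms, gp), direct(w, 1),
                 tolerance = 1e-6)
  }
  expect_equal(mortality_rate(2 * 0.5, 2, ms, gp),
               2^(-gp$xi) * mortality_rate(0.5, 1, ms, gp),
               tolerance = 1e-10)
  # no predators: background only
  ms0 <- predation_mortality(0, ps, gp, background = mortality_spec(0.02))
  expect_equal(ms0$m(c(0.3, 0.9)), c(0.02, 0.02))
})

test_that("zooplankton growth rate matches the direct prey integral and is
           homogeneous of degree 1 - xi", {
  gp <- canon_gp()
  ps <- canon_ps()
  p0 <- 0.7; z0 <- 0.05
  gamma <- 1 + ps$nu + gp$xi
  a_pz <- zoo_uptake(p0, z0, ps, gp)
  # direct quadrature of the predation uptake with power-law spectra
  direct_uptake <- function(w) {
    integrate(function(u) {
      wp <- exp(u)
      feeding_rate(w, wp, ps) * ps$epsilon * wp *
        (p0 + z0) * wp^(-gamma) * wp
    }, log(w) - 35, log(w) + 35, rel.tol = 1e-11)$value
  }
  for (w in c(0.4, 0.9)) {
    got <- zoo_growth_rate(w, 1, p0, z0, ps, gp)
    want <- direct_uptake(w) - gp$b * w^gp$beta
    expect_equal(got, want, tolerance = 1e-6)
  }
  expect_equal(zoo_growth_rate(5 * 0.5, 5, p0, z0, ps, gp),
               5^(1 - gp$xi) * zoo_growth_rate(0.5, 1, p0, z0, ps, gp),
               tolerance = 1e-10)
  # no prey at all: pure starvation
  expect_equal(zoo_growth_rate(0.5, 1, 0, 0, ps, gp),
               -gp$b * 0.5^gp$beta, tolerance = 1e-12)
})

test_that("the iff scaling theorem: rates are homogeneous exactly when the
           spectra carry exponent 1 + nu + xi", {
  gp <- canon_gp()
  ps <- canon_ps()
  gamma <- 1 + ps$nu + gp$xi
  at <- scaling_theorem_check(gamma, ps, gp, lambda = 2)
  expect_lt(at$defect_death, 1e-8)
  expect_lt(at$defect_growth, 1e-8)
  for (dg in c(-0.2, 0.2)) {
    off <- scaling_theorem_check(gamma + dg, ps, gp, lambda = 2)
    expect_gt(off$defect_death, 1e-3)
    expect_gt(off$defect_growth, 1e-3)
  }
})

test_that("the renormalisation factor has its closed power-law form and
           divergence sentinels", {
  gp <- canon_gp()
  # gamma = 2, xi = 0.15: integral of w^{-1.15}
  expect_equal(renormalisation_factor(1, 100, 2, gp),
               (1 - 100^(-0.15)) / 0.15, tolerance = 1e-12)
  expect_equal(renormalisation_factor(5, 5, 2, gp), 0)
  expect_identical(renormalisation_factor(0, 10, 2, gp), Inf)
  expect_identical(renormalisation_factor(1, Inf, 1.5, gp), Inf)
})

test_that("the zooplankton profile mirrors the phytoplankton construction with
           uptake exponent 1 - xi", {
  gp <- canon_gp()
  ms <- canon_ms()
  expect_equal(zoo_profile(1, a_pz = 0.65, ms, gp), 1)
  # zero mortality closed form
  x <- c(0.6, 0.8)
  expect_equal(zoo_profile(x, a_pz = 0.65, mortality_spec(0), gp),
               (0.65 - 0.5) / (0.65 * x^0.85 - 0.5 * x), tolerance = 1e-10)
  expect_equal(zoo_profile(0.5, a_pz = 0.65, ms, gp), oracle$phi_z_half,
               tolerance = 1e-9)
  expect_error(zoo_profile(0.5, a_pz = 0.4, ms, gp),
               class = "growth_infeasible")
})

test_that("the coupled steady state closes self-consistently and yields the
           power-law species abundances", {
  gp <- canon_gp()
  ps <- canon_ps()
  sol <- cached_ideal_coupled()
  expect_gt(sol$z0, 0)
  expect_gt(sol$p0, 0)
  expect_gt(sol$a_pz, gp$b)
  # both boundary conditions hold at the returned state
  expect_lt(abs(cellspectrum:::coexistence_residual_a(
    sol$a_hat, sol$mortality, gp)), 1e-9)
  gz <- cellspectrum:::zoo_growth_view(sol$a_pz, gp)
  expect_lt(abs(cellspectrum:::coexistence_residual_a(
    sol$a_pz, sol$mortality, gz)), 1e-9)
  # the closing identity between a_pz, p0 and z0
  expect_equal(sol$a_pz / (ps$epsilon * sol$S_gamma) - sol$p0, sol$z0,
               tolerance = 1e-7)
  # species abundances follow w*^{-gamma - 1}
  ab <- species_abundances(sol, c(1, 10, 100))
  expect_equal(ab$p_norm[2] / ab$p_norm[1], 10^(-sol$gamma - 1),
               tolerance = 1e-12)
  expect_equal(ab$z_norm[3] / ab$z_norm[1], 100^(-sol$gamma - 1),
               tolerance = 1e-12)
})

test_that("a vanishing conversion efficiency leaves no zooplankton-supporting
           steady state", {
  gp <- canon_gp()
  chem <- canon_chem()
  expect_error(
    solve_coupled_steady_state(
      predation_spec(epsilon = 1e-4), division_spec(idealised = TRUE),
      gp, chem, background = canon_ms()),
    class = "no_zoo_steady_state")
})

test_that("the general-division coupled steady state also closes", {
  gp <- canon_gp()
  ps <- canon_ps()
  ds <- canon_ds()
  sol <- cached(
    "general_coupled",
    solve_coupled_steady_state(ps, ds, gp, canon_chem(),
                               background = canon_ms(), n_grid = 128,
                               tol = 1e-8))
  expect_gt(sol$z0, 0)
  prof <- general_profile(ds, sol$mortality, gp, sol$a_hat, n_grid = 128)
  expect_lt(abs(prof$bc_residual), 1e-6)
  gz <- cellspectrum:::zoo_growth_view(sol$a_pz, gp)
  prof_z <- general_profile(ds, sol$mortality, gz, sol$a_pz, n_grid = 128)
  expect_lt(abs(prof_z$bc_residual), 1e-6)
})
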