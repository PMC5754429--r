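test_that("a zero-length step is the identity and mass-free states stay
           put", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                    a_fixed = 0.7, n_cells = 64)
  st <- pbe_state(cfg, w_stars = 1)
  st2 <- pbe_step(st, 0, cfg)
  expect_equal(st2$p, st$p)
  empty <- st
  empty$p[] <- 0
  out <- pbe_step(empty, cellspectrum:::pbe_dt(empty, cfg), cfg)
  expect_true(all(out$p == 0))
})

test_that("with no mortality the total cell number never decreases and grows
           only through division", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                    a_fixed = 0.7, n_cells = 128)
  st <- pbe_state(cfg, w_stars = 1)
  sim <- pbe_simulate(st, 8, cfg, record_dt = 0.1, guard = 1e30)
  n <- sim$series$number
  expect_true(all(diff(n) > -1e-10 * n[-length(n)]))
  expect_gt(n[length(n)], n[1])
  expect_true(all(sim$state$p >= 0))
})

test_that("the discrete division operator conserves number and biomass
           bookkeeping to machine precision", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                    a_fixed = 0.7, n_cells = 256)
  D <- cfg$division
  K <- cfg$K
  j <- which(K > 0)
  # each dividing parent yields exactly two daughters ...
  num <- Matrix::colSums(D * cfg$dx)
  expect_lt(max(abs(num[j] / (K[j] * cfg$dx[j]) - 2)), 1e-12)
  # ... carrying exactly the parent biomass
  bio <- Matrix::colSums(D * (cfg$x * cfg$dx))
  expect_lt(max(abs(bio[j] / (K[j] * cfg$dx[j] * cfg$x[j]) - 1)), 1e-12)
})

test_that("with division and mortality off, number is conserved up to the
           tracked boundary flux", {
  cfg <- pbe_config(canon_gp(), division_spec(idealised = TRUE),
                    ms = mortality_spec(0), a_fixed = 0.7, n_cells = 128)
  st <- pbe_state(cfg, w_stars = 1, centre = 0.3, width = 0.02)
  n0 <- cellspectrum:::total_number(st, cfg)
  # short run: the cohort stays below the reinjection boundary
  sim <- pbe_simulate(st, 1, cfg, record_dt = 0.5, guard = 1e30)
  expect_equal(cellspectrum:::total_number(sim$state, cfg), n0,
               tolerance = 1e-12)
})

test_that("the nutrient derivative has its trivial limits and is linear in
           the abundances", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = canon_ms(),
                    chem = canon_chem(), n_cells = 64)
  st <- pbe_state(cfg, w_stars = 1)
  empty <- st
  empty$p[] <- 0
  empty$N <- cfg$chem$N0
  expect_equal(nutrient_derivative(empty, cfg), 0)
  empty$N <- cfg$chem$N0 / 2
  expect_gt(nutrient_derivative(empty, cfg), 0)
  # consumption doubles when the population doubles
  st$N <- 5
  base <- cfg$chem$rho0 * (1 - st$N / cfg$chem$N0)
  cons1 <- base - nutrient_derivative(st, cfg)
  st2 <- st
  st2$p <- 2 * st$p
  cons2 <- base - nutrient_derivative(st2, cfg)
  expect_equal(cons2, 2 * cons1, tolerance = 1e-12)
})

test_that("a CFL-violating step is refused with a diagnostic", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                    a_fixed = 0.7, n_cells = 64)
  st <- pbe_state(cfg, w_stars = 1)
  expect_error(pbe_step(st, 10, cfg), class = "cfl_violation")
})

test_that("one synchronized division wave exactly doubles the cohort", {
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                    a_fixed = 0.7, n_cells = 256)
  res <- division_wave_ratio(cfg)
  expect_equal(res$ratio, 2, tolerance = 1e-3)
  expect_lt(res$parent_fraction, 1e-7)
})

test_that("the simulated exponential growth rate agrees with the renewal
           eigenvalue", {
  lam <- cached_sim_lambda()
  quad <- cached_eigen()[[1]]$Lambda
  expect_equal(lam$extrapolated, quad, tolerance = 1e-3)
  # the raw estimates converge at first order towards the quadrature value
  expect_lt(abs(lam$fine - quad), abs(lam$coarse - quad))
})

test_that("the growth-rate estimator is exact on synthetic exponentials and
           refuses non-monotone series", {
  t <- seq(0, 20, by = 0.1)
  expect_equal(measure_growth_rate(t, 3 * exp(0.3 * t)), 0.3,
               tolerance = 1e-10)
  expect_equal(measure_growth_rate(t, 300 * exp(0.3 * t)), 0.3,
               tolerance = 1e-10)
  wiggle <- exp(0.1 * t) * (1 + 0.5 * sin(3 * t))
  expect_error(measure_growth_rate(t, wiggle), class = "bad_series")
})

test_that("the chemostat-coupled simulation settles at the analytic steady
           nutrient and profile", {
  run <- cached_settled_chemostat()
  s <- run$sim$series
  late <- s[s$t > 350, ]
  # nutrient settled (no drift in the last records)
  expect_lt(max(late$N) - min(late$N), 1e-6)
  N_settled <- late$N[nrow(late)]
  expect_equal(N_settled, cached_general_solution()$N_star,
               tolerance = 1e-2)
})

test_that("the settled profile converges to psi at first order under grid
           refinement", {
  sol <- cached_general_solution()
  l1 <- vapply(c(128, 256), function(nc) {
    cfg <- pbe_config(canon_gp(), canon_ds(), ms = canon_ms(),
                      a_fixed = sol$a_star, n_cells = nc)
    st <- pbe_state(cfg, w_stars = 1)
    sim <- pbe_simulate(st, 120, cfg, record_dt = 30, guard = 1e30)
    dens <- sim$state$p[, 1]
    dens <- dens / sum(dens * cfg$dx)
    ref <- psi_profile(cfg$x, profile = sol$profile)
    ref <- ref / sum(ref * cfg$dx)
    sum(abs(dens - ref) * cfg$dx)
  }, numeric(1))
  expect_gt(l1[1] / l1[2], 1.5)
})

test_that("the long-run simulated profile matches psi closely on a fine
           grid", {
  sol <- cached_general_solution()
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = canon_ms(),
                    a_fixed = sol$a_star, n_cells = 512)
  st <- pbe_state(cfg, w_stars = 1)
  sim <- pbe_simulate(st, 150, cfg, record_dt = 50, guard = 1e30)
  dens <- sim$state$p[, 1]
  dens <- dens / sum(dens * cfg$dx)
  ref <- psi_profile(cfg$x, profile = sol$profile)
  ref <- ref / sum(ref * cfg$dx)
  expect_lt(sum(abs(dens - ref) * cfg$dx), 1e-2)
})

test_that("idealised division produces periodic, not convergent, dynamics:
           a cohort returns to its position after one doubling period", {
  gp <- canon_gp()
  cfg <- pbe_config(gp, division_spec(idealised = TRUE),
                    ms = mortality_spec(0), a_fixed = 0.7, n_cells = 256)
  st <- pbe_state(cfg, w_stars = 1, centre = 0.7, width = 0.03)
  Tdbl <- doubling_time(1, gp, 0.7)
  sim <- pbe_simulate(st, Tdbl, cfg, record_dt = Tdbl / 20, guard = 1e30,
                      checkpoints = Tdbl / 2)
  centroid <- function(p) sum(cfg$x * p * cfg$dx) / sum(p * cfg$dx)
  expect_equal(centroid(sim$state$p[, 1]), centroid(st$p[, 1]),
               tolerance = 5e-3)
  # the population doubles over each period
  expect_equal(cellspectrum:::total_number(sim$state, cfg) /
                 cellspectrum:::total_number(st, cfg), 2, tolerance = 1e-3)
  # mid-period the cohort sits elsewhere: the motion is a cycle, not a
  # fixed point
  mid_centroid <- centroid(sim$checkpoints[[1]]$p[, 1])
  expect_gt(abs(mid_centroid - centroid(st$p[, 1])), 0.05)
})

test_that("scale transformation: identity at lambda 1, composition, and the
           transformed steady community stays numerically steady", {
  sol <- cached_general_solution()
  gamma <- 2
  cfg <- pbe_config(canon_gp(), canon_ds(), ms = canon_ms(),
                    a_fixed = sol$a_star, n_cells = 256)
  ws <- c(0.5, 1, 2)
  st <- pbe_state(cfg, w_stars = ws)
  # load the analytic steady profile with power-law abundances
  psi <- psi_profile(cfg$x, profile = sol$profile)
  for (s in seq_along(ws)) st$p[, s] <- psi * ws[s]^(-gamma - 1)
  id <- scale_transform(st, 1, gamma)
  expect_equal(id$p, st$p)
  expect_equal(id$w_stars, st$w_stars)
  comp <- scale_transform(scale_transform(st, 2, gamma), 3, gamma)
  onego <- scale_transform(st, 6, gamma)
  expect_equal(comp$p, onego$p, tolerance = 1e-12)
  expect_equal(comp$w_stars, onego$w_stars, tolerance = 1e-12)
  # steadiness of the transform: residual norm within 2x of the original
  rhs0 <- pbe_rhs(st, cfg)
  tr <- scale_transform(st, 2, gamma)
  rhs1 <- pbe_rhs(tr, cfg)
  norm0 <- sum(abs(rhs0$dp))
  norm1 <- sum(abs(rhs1$dp)) / 2^(gamma - 1) * 2^(-canon_gp()$xi)
  expect_lt(norm1, 2 * norm0 + 1e-12)
  expect_error(scale_transform(st, -1, gamma), class = "bad_scale")
  expect_error(scale_transform(st, 100, gamma, bounds = c(0.1, 10)),
               class = "bad_scale")
})
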