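# Canonical parameter objects and frozen oracle fixtures.
#
# The fixture values below were computed with an independent adaptive
# quadrature / root-finding implementation (scipy.integrate.quad and
# brentq, with integration intervals split at the division-threshold kink
# and closed-form checks where available) and frozen here. Tests compare
# the package's own numerics against them.

canon_gp <- function() growth_params(a_inf = 0.7, b = 0.5, alpha = 0.85,
                                     beta = 1, xi = 0.15, r = 1)
canon_ds <- function() division_spec(xth = 0.7, delta = 0.2)
canon_ms <- function() mortality_spec(0.1)
canon_chem <- function() chemostat_params(rho0 = 1, N0 = 10, theta = 1)
canon_ps <- function() predation_spec(nu = 0.85, epsilon = 0.3,
                                      ratio_mode = 100, log_width = 1, s0 = 1)

oracle <- list(
  tau = 2.9418599141,                 # int_{1/2}^1 du / (0.7 u^0.85 - 0.5 u)
  phi_half = 1.940065239907,          # phi(1/2), a = 0.7, m0 = 0.1
  a_star_ideal = 0.572419020097,      # idealised coexistence root (a_inf=0.7, r=1)
  N_star_ideal = 4.486711267877,
  abundance_rhs = 1.765887310088,     # theta=1, rho0=1, N0=10 at the root
  e_08 = 0.857218796299,              # e(0.8), a = 0.7, m0 = 0.1
  h_05 = 8.200118539354,              # h(0.5), a = 0.7, m0 = 0.1
  a_star_general = 0.560358416234,    # renewal boundary-condition root, m0 = 0.1
  ell = 0.246046516503,               # growth eigenvalue l = Lambda w*^xi, a = 0.7
  phi_z_half = 1.981839479031         # zoo profile phi_z(1/2), a_pz = 0.65, m0 = 0.1
)

# psi(x) at the solved nutrient (a = a_star_general), oracle quadrature
oracle_psi <- data.frame(
  x = c(0.30, 0.34, 0.38, 0.42, 0.46, 0.50, 0.54, 0.58,
        0.62, 0.66, 0.70, 0.74, 0.78, 0.82, 0.86, 0.90, 0.94, 0.98),
  psi = c(0.0006554450, 0.0497926422, 0.2816286494, 0.5713334614,
          0.8270673176, 1.0222783112, 1.0915605086, 1.0373614638,
          0.9648406549, 0.9005992897, 0.8433268994, 0.7880002031,
          0.7128208949, 0.5906515997, 0.4062560112, 0.1895107166,
          0.0353813811, 0.0002257599)
)

# session-wide cache so expensive solves are shared across test files
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

cached_general_solution <- function() {
  cached("general_solution", {
    solve_nutrient_general(canon_ds(), canon_ms(), canon_gp())
  })
}

cached_eigen <- function() {
  cached("eigen_list", {
    lapply(c(1, 10, 100), function(w) {
      solve_growth_eigenvalue(w, canon_ds(), canon_gp(), tol = 1e-12)
    })
  })
}

cached_ideal_coupled <- function() {
  cached("ideal_coupled", {
    solve_coupled_steady_state(
      canon_ps(), division_spec(idealised = TRUE), canon_gp(), canon_chem(),
      background = canon_ms(),
      assemblage = make_assemblage(192, 1, 1000))
  })
}

cached_settled_chemostat <- function() {
  cached("settled_chemostat", {
    cfg <- pbe_config(canon_gp(), canon_ds(), ms = canon_ms(),
                      chem = canon_chem(), n_cells = 256)
    st <- pbe_state(cfg, w_stars = 1, N = 5, number = 2)
    sim <- pbe_simulate(st, 400, cfg, record_dt = 2)
    list(cfg = cfg, sim = sim)
  })
}

cached_sim_lambda <- function() {
  cached("sim_lambda", {
    # first-order scheme: Richardson extrapolation over two grids
    lam <- vapply(c(128, 256), function(nc) {
      cfg <- pbe_config(canon_gp(), canon_ds(), ms = mortality_spec(0),
                        a_fixed = 0.7, n_cells = nc)
      st <- pbe_state(cfg, w_stars = 1)
      sim <- pbe_simulate(st, 60, cfg, record_dt = 0.25, guard = 1e30)
      measure_growth_rate(sim$series$t, sim$series$number,
                          window_frac = 0.4)
    }, numeric(1))
    list(coarse = lam[1], fine = lam[2], extrapolated = 2 * lam[2] - lam[1])
  })
}
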