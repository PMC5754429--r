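# Analytic steady state for the idealised division process: cells grow to
# exactly w_star and split into two equal halves. The within-species profile
# phi(x) lives on x = w/w_star in [1/2, 1] and satisfies the steady transport
# equation d/dx[g(x) phi] + m(x) phi = 0 with g(x) = a x^alpha - b x^beta,
# subject to the number-doubling boundary condition at the split.

#' Within-species steady profile, idealised division
#'
#' Evaluates
#' \eqn{\phi(x) = \frac{a-b}{a x^\alpha - b x^\beta}
#'   \exp\{\int_x^1 m(y)/(a y^\alpha - b y^\beta)\,dy\}},
#' normalised so that \eqn{\phi(1) = 1}.
#'
#' @param x relative size(s) in `[1/2, 1]`.
#' @param ms a [mortality_spec()].
#' @param gp a [growth_params()].
#' @param a_val uptake coefficient `a(N)`; must exceed `b`.
#' @return profile value(s).
#' @export
phi_profile <- function(x, ms, gp, a_val) {
  if (a_val <= gp$b) {
    stop2("growth_infeasible", "a_val <= b: no positive growth on [1/2, 1]")
  }
  vapply(x, function(xi) {
    expo <- if (xi >= 1) 0 else {
      stats::integrate(function(y) ms$m(y) / growth_shape(y, gp, a_val),
                       xi, 1, rel.tol = 1e-12, abs.tol = 1e-12)$value
    }
    (a_val - gp$b) / growth_shape(xi, gp, a_val) * exp(expo)
  }, numeric(1))
}

#' Coexistence condition residual, idealised division
#'
#' The steady state admits every species simultaneously only at the nutrient
#' level where
#' \eqn{\int_{1/2}^1 m(x)/(a(N) x^\alpha - b x^\beta)\,dx = \log 2}.
#' This function returns the left side minus `log(2)`; it is strictly
#' decreasing in `N` because `a(N)` is increasing.
#'
#' @param N nutrient concentration.
#' @inheritParams phi_profile
#' @return the residual (integral minus `log 2`).
#' @export
coexistence_residual <- function(N, ms, gp) {
  a_val <- monod_uptake(N, gp)
  if (a_val <= gp$b) {
    stop2("growth_infeasible",
          sprintf("a(N) = %g <= b = %g: growth infeasible at N = %g",
                  a_val, gp$b, N))
  }
  coexistence_residual_a(a_val, ms, gp)
}

# same residual parameterised directly by the uptake coefficient
coexistence_residual_a <- function(a_val, ms, gp) {
  val <- stats::integrate(function(y) ms$m(y) / growth_shape(y, gp, a_val),
                          0.5, 1, rel.tol = 1e-12, abs.tol = 1e-12)$value
  val - log(2)
}

#' Steady-state nutrient level, idealised division
#'
#' Solves the coexistence condition for the unique nutrient level `N_star`.
#' Two routes are available: `"bisection"` on the (monotone) residual of the
#' closed-form condition, and `"shooting"`, which integrates the steady
#' transport ODE downward from `x = 1` with \pkg{deSolve} and finds the
#' nutrient at which the boundary flux ratio equals 2. The shooting route
#' never evaluates the closed-form integral and therefore serves as an
#' independent check of it.
#'
#' @inheritParams phi_profile
#' @param N_max upper end of the nutrient bracket (e.g. the chemostat
#'   capacity `N0`).
#' @param method `"bisection"` or `"shooting"`.
#' @param tol relative tolerance on `N_star`.
#' @return a list with `N_star`, `a_star`, the achieved `residual`, and the
#'   solver `method`; errors with class `"extinction_only"` when no root
#'   exists in the bracket (all species die out at every nutrient level).
#' @export
solve_nutrient_idealised <- function(ms, gp, N_max = 1e6,
                                     method = c("bisection", "shooting"),
                                     tol = 1e-12) {
  method <- match.arg(method)
  # smallest N with a(N) > b (plus margin), per the positivity requirement
  a_lo <- gp$b * (1 + 1e-6)
  if (a_lo >= gp$a_inf) {
    stop2("extinction_only", "a_inf barely exceeds b: no feasible nutrient")
  }
  N_lo <- monod_invert(a_lo, gp)
  if (N_lo >= N_max) {
    stop2("extinction_only", "feasible nutrient exceeds the bracket")
  }
  objective <- switch(method,
    bisection = function(N) coexistence_residual(N, ms, gp),
    shooting = function(N) shoot_boundary_ratio(monod_uptake(N, gp), ms, gp) - 2
  )
  ans <- tryCatch(
    bisect_root(objective, N_lo, N_max, tol = tol),
    bisect_no_bracket = function(e) {
      stop2("extinction_only",
            "no steady state is possible except full extinction (no sign change in the nutrient bracket)")
    })
  N_star <- ans$root
  list(N_star = N_star, a_star = monod_uptake(N_star, gp),
       residual = coexistence_residual(N_star, ms, gp),
       method = method, iterations = ans$iterations)
}

# Integrate u = g(x) phi(x) from x = 1 down to x = 1/2: du/dx = -m(x) u/g(x).
# Returns the flux ratio u(1/2)/u(1), which equals 2 at the steady nutrient.
shoot_boundary_ratio <- function(a_val, ms, gp) {
  if (a_val <= gp$b) {
    stop2("growth_infeasible", "a_val <= b: growth infeasible")
  }
  deriv <- function(x, u, parms) {
    list(-ms$m(x) * u / growth_shape(x, gp, a_val))
  }
  u1 <- growth_shape(1, gp, a_val)
  sol <- deSolve::ode(y = c(u = u1), times = c(1, 0.5), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  unname(sol[nrow(sol), "u"] / u1)
}

#' Idealised steady-state profile object
#'
#' Builds the full within-species profile on a grid of relative sizes,
#' either at a supplied uptake coefficient or at the solved steady-state
#' nutrient.
#'
#' @inheritParams phi_profile
#' @param a_val uptake coefficient; if `NULL` the steady nutrient is solved
#'   first (requires `N_max`).
#' @param n_grid number of grid points on `[1/2, 1]`.
#' @param N_max bracket for the nutrient solve when `a_val` is `NULL`.
#' @return an object of class `idealised_profile` with fields `x`, `phi`,
#'   `a_val`, `N_star` (when solved), `ms`, `gp`.
#' @export
idealised_profile <- function(ms, gp, a_val = NULL, n_grid = 257,
                              N_max = 1e6) {
  N_star <- NA_real_
  if (is.null(a_val)) {
    sol <- solve_nutrient_idealised(ms, gp, N_max = N_max)
    a_val <- sol$a_star
    N_star <- sol$N_star
  }
  x <- seq(0.5, 1, length.out = n_grid)
  structure(list(x = x, phi = phi_profile(x, ms, gp, a_val),
                 a_val = a_val, N_star = N_star, ms = ms, gp = gp),
            class = "idealised_profile")
}

#' @export
print.idealised_profile <- function(x, ...) {
  cat(sprintf(
    "idealised_profile: %d points on [1/2, 1], a(N)=%.6g, N_star=%.6g\n",
    length(x$x), x$a_val, x$N_star))
  invisible(x)
}

#' Boundary flux ratio of an idealised profile
#'
#' Ratio of the number flux of dividing cells reinjected at `w_star/2` to
#' the flux dividing at `w_star`:
#' \eqn{G_p(w_*/2, w_*)\phi(1/2) / (G_p(w_*, w_*)\phi(1))}. It equals 2
#' exactly at the solved steady-state nutrient (each division produces two
#' daughters), is below 2 when nutrient is in excess, and equals 1 for zero
#' mortality.
#'
#' @param profile an [idealised_profile()].
#' @return the flux ratio.
#' @export
boundary_ratio <- function(profile) {
  gp <- profile$gp
  a_val <- profile$a_val
  phi_half <- phi_profile(0.5, profile$ms, gp, a_val)
  growth_shape(0.5, gp, a_val) * phi_half / growth_shape(1, gp, a_val)
}

#' Community abundance constraint, idealised division
#'
#' At the steady nutrient the chemostat balance fixes one linear functional
#' of the across-species abundance function:
#' \eqn{\int_0^\infty w_*^{2-\xi} p(w_*, w_*)\,dw_* =
#'   \theta \varrho(N_*)/a(N_*) \cdot (\int x^\alpha \phi(x) dx)^{-1}}.
#' This returns the right-hand side, used to normalise assemblage
#' abundances.
#'
#' @param profile an [idealised_profile()] built at the solved nutrient.
#' @param chem a [chemostat_params()].
#' @return the total abundance moment sustained by the chemostat.
#' @export
abundance_constraint_rhs <- function(profile, chem) {
  gp <- profile$gp
  N_star <- profile$N_star
  if (!is.finite(N_star)) {
    stop2("profile_unsolved", "profile must be built at a solved nutrient")
  }
  rho <- chem$rho0 * (1 - N_star / chem$N0)
  Ip_alpha <- stats::integrate(
    function(x) x^gp$alpha * phi_profile(x, profile$ms, gp, profile$a_val),
    0.5, 1, rel.tol = 1e-10)$value
  chem$theta * rho / profile$a_val / Ip_alpha
}
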