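# Steady state for the general (sloppy size control) division process.
#
# Cells larger than w_+ = (1+delta)/2 w_star are depleted by division and
# death as they grow; their survival is encoded in e(x). Newborn daughters
# are re-injected below w_+ with renewal density h(x). The boundary
# condition  int_0^{(1+delta)/2} h/e dx = 1  (every cell eventually yields
# a lineage that conserves cell number flux) pins the nutrient level, and
# the within-species profile is
#   psi(x) = g((1+delta)/2)/g(x) * e(x) * Theta(x).

#' Survival factor e(x)
#'
#' \eqn{e(x) = \exp\{-\int_{(1+\delta)/2}^x (k(y)+m(y)) /
#' (a y^\alpha - b y^\beta)\,dy\}}. Equals 1 at `x = (1+delta)/2`, decreases
#' beyond the division threshold and vanishes at `x = 1` because the
#' division-rate integral diverges there; for `x` below `(1+delta)/2` the
#' integral runs backwards, so `e > 1` whenever mortality is positive.
#'
#' @param x relative size(s) in (0, 1].
#' @param ds a [division_spec()].
#' @param ms a [mortality_spec()].
#' @param gp a [growth_params()].
#' @param a_val uptake coefficient `a(N)`.
#' @return survival factor(s); exactly 0 at `x = 1`.
#' @export
survival_factor_e <- function(x, ds, ms, gp, a_val) {
  wp <- ds$w_plus
  f <- function(y) (ds$k(y) + ms$m(y)) / growth_shape(y, gp, a_val)
  vapply(x, function(xi) {
    if (xi >= 1) return(0)
    val <- stats::integrate(f, wp, xi, rel.tol = 1e-11, abs.tol = 1e-12,
                            stop.on.error = FALSE)$value
    exp(-val)
  }, numeric(1))
}

#' Renewal density h(x)
#'
#' Density of daughter-cell production at relative size `x`:
#' \eqn{h(x) = 2\int_{x_{th}}^1 \frac{k(y) e(y)}{a y^\alpha - b y^\beta}
#'  q(x/y)\,\frac{dy}{y}}. Nonzero only on
#' `(xth (1-delta)/2, (1+delta)/2)`; the factor 2 counts both daughters of
#' each division.
#'
#' @inheritParams survival_factor_e
#' @return renewal density value(s).
#' @export
renewal_density_h <- function(x, ds, ms, gp, a_val) {
  lo_q <- (1 - ds$delta) / 2
  hi_q <- (1 + ds$delta) / 2
  ef <- function(y) survival_factor_e(y, ds, ms, gp, a_val)
  vapply(x, function(xi) {
    ylo <- max(ds$xth, xi / hi_q)
    yhi <- min(1, xi / lo_q)
    if (ylo >= yhi) return(0)
    f <- function(y) {
      2 * ds$k(y) * ef(y) / growth_shape(y, gp, a_val) * ds$q(xi / y) / y
    }
    stats::integrate(f, ylo, yhi, rel.tol = 1e-9, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value
  }, numeric(1))
}

# ---- grid machinery ---------------------------------------------------------

# Renewal structure on an increasing size grid ending at the maximum size.
# All rate arguments are vectorised functions of absolute size; the grid is
# used both for the cumulative survival integral and for the renewal
# quadrature. Returns E, H on the grid and the renewal integral int H/E.
renewal_structure <- function(w_grid, w_th, w_plus, Kf, Mf, Gf, qf,
                              q_lo, q_hi) {
  n <- length(w_grid)
  w_max <- w_grid[n]
  integrand <- function(w) (Kf(w) + Mf(w)) / Gf(w)
  C <- cum_quad(integrand, w_grid)  # from w_grid[1]
  iwp <- which.min(abs(w_grid - w_plus))
  C <- C - C[iwp]
  E <- exp(-C)
  E[n] <- 0  # divergent division integral at the maximum size

  # interpolant of the cumulative integral in the coordinate
  # t = log(1 - w/w_max): C is asymptotically linear in t at the division
  # pole, so the spline stays accurate there (and t is scale-free)
  tt <- log1p(-w_grid[-n] / w_max)
  Cfun <- stats::splinefun(rev(tt), rev(C[-n]), method = "hyman")
  Efun <- function(w) {
    ifelse(w >= w_max, 0, exp(-Cfun(log1p(-w / w_max))))
  }

  # H(w) = 2 int_{w_th}^{w_max} q(w/y)/y * K(y) E(y)/G(y) dy
  # panels follow the grid so the pole-refined nodes near w_max are reused
  kernel <- function(y) {
    val <- 2 * Kf(y) * Efun(y) / Gf(y)
    val[!is.finite(val)] <- 0  # k -> Inf only where the survival factor is 0
    val
  }
  Hfun <- function(w) {
    vapply(w, function(wi) {
      ylo <- max(w_th, wi / q_hi)
      yhi <- min(w_max * (1 - 1e-13), wi / q_lo)
      if (ylo >= yhi) return(0)
      inner <- w_grid[w_grid > ylo & w_grid < yhi]
      brk <- sort(unique(c(ylo, inner, yhi)))
      sum(panel_quad(function(y) kernel(y) * qf(wi / y) / y,
                     brk[-length(brk)], brk[-1]))
    }, numeric(1))
  }
  H <- Hfun(w_grid)
  below <- w_grid <= w_plus
  ratio <- numeric(n)
  ratio[below] <- H[below] / E[below]
  # integrate H/E up to w_plus by local cubic panels on the grid values
  theta <- cum_quad_table(w_grid[below], ratio[below])
  theta <- c(theta, rep(theta[length(theta)], n - length(theta)))
  renewal_integral <- theta[iwp]
  list(w = w_grid, E = E, H = H, C = C, theta = theta,
       renewal_integral = renewal_integral, i_wplus = iwp)
}

# default relative-size grid: log-spaced on [x_lo, 1] with the support
# boundaries inserted as exact nodes, plus nodes refined geometrically
# toward the division pole at x = 1 (substitution x = 1 - e^{-u})
general_grid <- function(ds, n_grid = 512) {
  x_lo <- ds$xth * (1 - ds$delta) / 2 * 0.5
  x <- geom_seq(x_lo, 1, n_grid)
  x <- c(x, pole_nodes(1, n_pole = max(32L, n_grid %/% 8L)))
  sort(unique(c(x, ds$xth, ds$w_plus, ds$xth * (1 - ds$delta) / 2)))
}

# nodes approaching w_max with geometrically shrinking distance
pole_nodes <- function(w_max, frac = 0.02, n_pole = 64L, depth = 20) {
  w_max * (1 - frac * exp(-seq(0, depth, length.out = n_pole)))
}

#' General steady-state profile
#'
#' Builds the within-species steady profile \eqn{\psi(x)} for the sloppy
#' division process on a relative-size grid, together with the survival
#' factor `e`, renewal density `h`, the cumulative renewal integral
#' `theta`, and the boundary-condition residual
#' \eqn{\int_0^{(1+\delta)/2} h/e\,dx - 1} (zero at the steady nutrient).
#'
#' @inheritParams survival_factor_e
#' @param n_grid number of grid points.
#' @return an object of class `general_profile` with fields `x`, `psi`,
#'   `e`, `h`, `theta`, `bc_residual`, `a_val`, and the parameter objects.
#' @export
general_profile <- function(ds, ms, gp, a_val, n_grid = 512) {
  if (a_val <= gp$b) {
    stop2("growth_infeasible", "a_val <= b: no positive growth on (0, 1]")
  }
  x <- general_grid(ds, n_grid)
  rs <- renewal_structure(
    x, w_th = ds$xth, w_plus = ds$w_plus,
    Kf = ds$k, Mf = ms$m,
    Gf = function(y) growth_shape(y, gp, a_val),
    qf = ds$q, q_lo = (1 - ds$delta) / 2, q_hi = (1 + ds$delta) / 2)
  theta_fac <- ifelse(x > ds$w_plus, 1, rs$theta)
  psi <- growth_shape(ds$w_plus, gp, a_val) / growth_shape(x, gp, a_val) *
    rs$E * theta_fac
  psi[length(psi)] <- 0
  structure(list(x = x, psi = psi, e = rs$E, h = rs$H, theta = rs$theta,
                 bc_residual = rs$renewal_integral - 1,
                 a_val = a_val, N_star = NA_real_,
                 ds = ds, ms = ms, gp = gp),
            class = "general_profile")
}

#' @export
print.general_profile <- function(x, ...) {
  cat(sprintf(
    "general_profile: %d points, a(N)=%.6g, boundary residual %.3e\n",
    length(x$x), x$a_val, x$bc_residual))
  invisible(x)
}

#' Steady-profile value psi(x)
#'
#' Point evaluation of the general-division steady profile (interpolated
#' from a [general_profile()] grid).
#'
#' @inheritParams survival_factor_e
#' @param profile optionally a prebuilt [general_profile()]; otherwise one
#'   is built from the parameter objects.
#' @param n_grid grid size when building.
#' @export
psi_profile <- function(x, ds = NULL, ms = NULL, gp = NULL, a_val = NULL,
                        profile = NULL, n_grid = 512) {
  if (is.null(profile)) {
    profile <- general_profile(ds, ms, gp, a_val, n_grid = n_grid)
  }
  out <- stats::spline(profile$x, profile$psi, xout = pmin(x, 1),
                       method = "natural")$y
  out[x >= 1] <- 0
  out[x <= min(profile$x)] <- 0
  pmax(out, 0)
}

#' Steady-state nutrient level, general division
#'
#' Solves the renewal boundary condition
#' \eqn{\int_0^{(1+\delta)/2} h(x)/e(x)\,dx = 1} for the uptake coefficient
#' and hence the nutrient level.
#'
#' @inheritParams general_profile
#' @param tol relative tolerance on the uptake coefficient.
#' @return a list with `N_star`, `a_star`, the solved `profile`, and the
#'   achieved `residual`; errors with class `"extinction_only"` when the
#'   condition has no root below saturation.
#' @export
solve_nutrient_general <- function(ds, ms, gp, n_grid = 512, tol = 1e-12) {
  obj <- function(a_val) {
    general_profile(ds, ms, gp, a_val, n_grid = n_grid)$bc_residual
  }
  a_lo <- gp$b * (1 + 1e-6)
  a_hi <- gp$a_inf * (1 - 1e-9)
  ans <- tryCatch(
    bisect_root(obj, a_lo, a_hi, tol = tol),
    bisect_no_bracket = function(e) {
      stop2("extinction_only",
            "no steady state is possible except full extinction (renewal condition has no root)")
    })
  prof <- general_profile(ds, ms, gp, ans$root, n_grid = n_grid)
  prof$N_star <- monod_invert(ans$root, gp)
  list(N_star = prof$N_star, a_star = ans$root, profile = prof,
       residual = prof$bc_residual, iterations = ans$iterations)
}

#' Population growth-rate eigenvalue
#'
#' In a nutrient-rich culture with negligible mortality the population grows
#' exponentially at rate \eqn{\Lambda}, fixed by the renewal condition
#' \eqn{\int_0^{w_+} H(w)/E(w)\,dw = 1} in which the mortality is replaced
#' by \eqn{\Lambda} itself. All quadratures are carried out in absolute size
#' coordinates for the given `w_star`. The scale-free rate
#' \eqn{\ell = \Lambda w_*^\xi} is independent of the species.
#'
#' @param w_star maximum cell size of the species.
#' @param ds a [division_spec()].
#' @param gp a [growth_params()].
#' @param a_val uptake coefficient (nutrient-rich default `a_inf`).
#' @param n_grid number of grid points in absolute size.
#' @param tol relative tolerance on `Lambda`.
#' @return a list with `Lambda`, `ell = Lambda * w_star^xi`, and the
#'   renewal `residual` at the root.
#' @export
solve_growth_eigenvalue <- function(w_star, ds, gp, a_val = gp$a_inf,
                                    n_grid = 512, tol = 1e-10) {
  w_th <- ds$xth * w_star
  w_plus <- ds$w_plus * w_star
  w_lo <- ds$xth * (1 - ds$delta) / 2 * 0.5 * w_star
  w_grid <- sort(unique(c(geom_seq(w_lo, w_star, n_grid),
                          pole_nodes(w_star, n_pole = max(32L, n_grid %/% 8L)),
                          w_th, w_plus, ds$xth * (1 - ds$delta) / 2 * w_star)))
  Kf <- function(w) division_rate(w, w_star, ds, gp)
  Gf <- function(w) growth_rate(w, w_star, gp, a_val)
  qf <- function(u) ds$q(u)  # q of daughter/parent ratio
  resid <- function(Lambda) {
    rs <- renewal_structure(
      w_grid, w_th = w_th, w_plus = w_plus,
      Kf = Kf, Mf = function(w) rep_len(Lambda, length(w)),
      Gf = Gf, qf = qf,
      q_lo = (1 - ds$delta) / 2, q_hi = (1 + ds$delta) / 2)
    rs$renewal_integral - 1
  }
  # upper bracket: max growth-rate/size over the support, widened if needed
  up <- max(growth_rate(w_grid, w_star, gp, a_val) / w_grid)
  lo <- 0
  tries <- 0L
  while (resid(up) > 0 && tries < 8L) {
    up <- up * 2
    tries <- tries + 1L
  }
  if (resid(up) > 0) {
    stop2("no_growth_bracket", "parameters cannot bracket a growth rate")
  }
  ans <- bisect_root(resid, lo, up, tol = tol)
  list(Lambda = ans$root, ell = ans$root * w_star^gp$xi,
       residual = ans$f_root, iterations = ans$iterations)
}
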