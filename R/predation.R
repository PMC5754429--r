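# Predator-prey coupling between phyto- and zooplankton.
#
# Predation at rate S(w, w') = w^nu s(w/w') generates both the prey death
# rate and the predator growth rate. When the community spectra are power
# laws w^{-gamma} with gamma = 1 + nu + xi (and only then), the emergent
# death rate scales like w_*^{-xi} m(w/w_*) and the zooplankton growth rate
# like w_*^{1-xi} -- precisely the allometries required for all species to
# coexist. The coupled steady state then fixes the spectrum coefficients
# p0, z0, the zooplankton uptake a_pz, and the (renormalised) nutrient.

#' Moment of the prey-preference kernel
#'
#' \eqn{\int_0^\infty y^p s(y)\,dy}, evaluated by quadrature in log ratio.
#' The moments with `p = -xi - 1` (death rate) and `p = gamma - 3`
#' (predator uptake) must be finite for the community coupling to exist;
#' a non-decaying integrand is rejected.
#'
#' @param ps a [predation_spec()].
#' @param p moment order.
#' @return the moment value.
#' @export
prey_kernel_moment <- function(ps, p) {
  f <- function(u) exp((p + 1) * u) * ps$s(exp(u))
  # decay probe far into both tails; integration is then restricted to the
  # verified-decay window (the infinite tails would overflow exp((p+1)u)
  # before the kernel underflows)
  mu <- log(ps$ratio_mode)
  u_probe <- mu + c(-40, 40) * ps$log_width
  if (any(f(u_probe) > 1e-8 * f(mu))) {
    stop2("kernel_moment_divergent",
          sprintf("kernel moment of order %g does not converge", p))
  }
  tryCatch(
    stats::integrate(f, u_probe[1], u_probe[2], rel.tol = 1e-12,
                     abs.tol = 0)$value,
    error = function(e) stop2("kernel_moment_divergent", conditionMessage(e)))
}

#' Total mortality under a power-law zooplankton spectrum
#'
#' With the zooplankton community spectrum \eqn{z_c(w) = z_0 w^{-\gamma}},
#' \eqn{\gamma = 1+\nu+\xi}, the predation mortality collapses to the
#' scaling form with shape
#' \eqn{m(x) = m_b(x) + z_0 x^{-\xi} \int_0^\infty y^{-\xi-1} s(y)\,dy}.
#' Returns the composed total mortality as a [mortality_spec()] usable by
#' every steady-state solver.
#'
#' @param z0 zooplankton spectrum coefficient.
#' @param ps a [predation_spec()].
#' @param gp a [growth_params()] (supplies `xi`).
#' @param background background mortality as a [mortality_spec()].
#' @return a [mortality_spec()] for the total death-rate shape.
#' @export
predation_mortality <- function(z0, ps, gp, background = mortality_spec(0)) {
  if (z0 < 0) stop2("bad_spectrum", "z0 must be >= 0")
  S_m <- prey_kernel_moment(ps, -gp$xi - 1)
  mb <- background$m
  xi <- gp$xi
  mortality_spec(
    m = function(x) mb(x) + z0 * x^(-xi) * S_m,
    label = sprintf("background + predation (z0=%g, moment %.6g)", z0, S_m))
}

#' Zooplankton effective uptake coefficient
#'
#' Under power-law community spectra \eqn{p_c = p_0 w^{-\gamma}},
#' \eqn{z_c = z_0 w^{-\gamma}}, predation on all smaller cells produces a
#' growth rate of the same von Bertalanffy form as for phytoplankton with
#' uptake exponent \eqn{1-\xi} and coefficient
#' \eqn{a_{pz} = \varepsilon (p_0 + z_0) \int_0^\infty x^{\gamma-3}
#' s(x)\,dx}.
#'
#' @param p0,z0 spectrum coefficients of phyto- and zooplankton.
#' @param ps a [predation_spec()].
#' @param gp a [growth_params()].
#' @return the uptake coefficient `a_pz`.
#' @export
zoo_uptake <- function(p0, z0, ps, gp) {
  gamma <- 1 + ps$nu + gp$xi
  ps$epsilon * (p0 + z0) * prey_kernel_moment(ps, gamma - 3)
}

#' Zooplankton growth rate
#'
#' \eqn{G_z(w, w_*) = w_*^{1-\xi}[a_{pz} (w/w_*)^{1-\xi} -
#' b (w/w_*)^\beta]} with `a_pz` from [zoo_uptake()].
#'
#' @param w current cell size (vectorised).
#' @param w_star maximum cell size.
#' @inheritParams zoo_uptake
#' @export
zoo_growth_rate <- function(w, w_star, p0, z0, ps, gp) {
  if (any(w <= 0) || any(w_star <= 0)) {
    stop2("bad_sizes", "sizes must be strictly positive")
  }
  a_pz <- zoo_uptake(p0, z0, ps, gp)
  x <- w / w_star
  w_star^(1 - gp$xi) * (a_pz * x^(1 - gp$xi) - gp$b * x^gp$beta)
}

# growth-parameter view of a zooplankton predator: uptake exponent 1 - xi
zoo_growth_view <- function(a_pz, gp) {
  structure(list(a_inf = max(a_pz * 2, gp$a_inf), b = gp$b,
                 alpha = 1 - gp$xi, beta = gp$beta, xi = gp$xi, r = gp$r),
            class = "growth_params")
}

#' Scaling-theorem diagnostic
#'
#' Numerically probes the central scaling result: the predation-generated
#' death rate is homogeneous of degree \eqn{-\xi} (and the predation uptake
#' of degree \eqn{1-\xi}) if, and only if, the community spectra are power
#' laws with exponent \eqn{\gamma = 1+\nu+\xi}. Trial spectra
#' \eqn{w^{-g}} are inserted into the direct predation integrals and the
#' homogeneity defect is measured at scale factor `lambda`.
#'
#' @param g_test trial spectrum exponent.
#' @param ps a [predation_spec()].
#' @param gp a [growth_params()].
#' @param lambda scale factor of the probe.
#' @param w probe size.
#' @return list with `defect_death` and `defect_growth`, each
#'   `|lambda^deg rate(lambda w) / rate(w) - 1|`; both vanish exactly at
#'   `g_test = 1 + nu + xi`.
#' @export
scaling_theorem_check <- function(g_test, ps, gp, lambda = 2, w = 1) {
  # death rate at size w from predators z_c(w') = w'^{-g}:
  #   M(w) = int S(w', w) w'^{-g} dw'   (u = log w')
  death <- function(wq) {
    f <- function(u) {
      wp <- exp(u)
      wp^ps$nu * ps$s(wp / wq) * wp^(-g_test) * wp
    }
    stats::integrate(f, log(wq * ps$ratio_mode) - 30 * ps$log_width,
                     log(wq * ps$ratio_mode) + 30 * ps$log_width,
                     rel.tol = 1e-12)$value
  }
  # predation uptake at predator size w from prey (p_c + z_c) ~ w'^{-g}:
  #   A(w) = int S(w, w') w' w'^{-g} dw'
  uptake <- function(wq) {
    f <- function(u) {
      wp <- exp(u)
      wq^ps$nu * ps$s(wq / wp) * wp^(1 - g_test) * wp
    }
    stats::integrate(f, log(wq / ps$ratio_mode) - 30 * ps$log_width,
                     log(wq / ps$ratio_mode) + 30 * ps$log_width,
                     rel.tol = 1e-12)$value
  }
  defect_death <- abs(lambda^gp$xi * death(lambda * w) / death(w) - 1)
  defect_growth <- abs(lambda^(gp$xi - 1) * uptake(lambda * w) / uptake(w) - 1)
  list(defect_death = defect_death, defect_growth = defect_growth,
       gamma_required = 1 + ps$nu + gp$xi)
}

#' Renormalisation factor of a finite community
#'
#' \eqn{\Xi = \int_{w_{\min}}^{w_{\max}} w_*^{1-\xi-\gamma}\,dw_*}: the
#' trait integral by which all resource-related quantities diverge as the
#' community bounds widen. Returns `Inf` when the integral diverges at a
#' zero lower bound or infinite upper bound.
#'
#' @param w_min,w_max community size bounds.
#' @param gamma community spectrum exponent.
#' @param gp a [growth_params()].
#' @export
renormalisation_factor <- function(w_min, w_max, gamma, gp) {
  if (w_min > w_max) stop2("bad_bounds", "requires w_min <= w_max")
  p <- 1 - gp$xi - gamma
  if (w_min == w_max) return(0)
  if (p == -1) {
    if (w_min <= 0 || !is.finite(w_max)) return(Inf)
    return(log(w_max / w_min))
  }
  anti <- function(w) w^(p + 1) / (p + 1)
  lo <- if (w_min <= 0) { if (p + 1 <= 0) return(Inf) else 0 } else anti(w_min)
  hi <- if (!is.finite(w_max)) { if (p + 1 >= 0) return(Inf) else 0 } else anti(w_max)
  hi - lo
}

#' Zooplankton within-species steady profile
#'
#' Same construction as the phytoplankton profile with the uptake exponent
#' replaced by \eqn{1-\xi} and the uptake coefficient by `a_pz`: either the
#' idealised closed form or the sloppy-division renewal profile.
#'
#' @param x relative size(s); used for the idealised profile.
#' @param a_pz zooplankton uptake coefficient; must exceed `b`.
#' @param ms total mortality shape ([mortality_spec()]).
#' @param gp a [growth_params()].
#' @param ds a [division_spec()]; its `idealised` flag selects the flavour.
#' @param n_grid grid size for the general profile.
#' @return profile values at `x` (idealised) or a [general_profile()].
#' @export
zoo_profile <- function(x = NULL, a_pz, ms, gp, ds = NULL, n_grid = 512) {
  if (a_pz <= gp$b) {
    stop2("growth_infeasible", "a_pz <= b: zooplankton cannot sustain growth")
  }
  gz <- zoo_growth_view(a_pz, gp)
  if (is.null(ds) || ds$idealised) {
    phi_profile(x, ms, gz, a_pz)
  } else {
    prof <- general_profile(ds, ms, gz, a_pz, n_grid = n_grid)
    if (!is.null(x)) psi_profile(x, profile = prof) else prof
  }
}

# ---- coupled steady state ---------------------------------------------------

# profile moment int x^eta phi(x) dx for the idealised closed form
ideal_moment <- function(eta, ms, gp, a_val) {
  stats::integrate(function(x) x^eta * phi_profile(x, ms, gp, a_val),
                   0.5, 1, rel.tol = 1e-10)$value
}

# moment of a general_profile from its grid
general_moment <- function(eta, prof) {
  vals <- prof$x^eta * prof$psi
  cq <- cum_quad_table(prof$x, vals)
  cq[length(cq)]
}

# inner root solve for the uptake coefficient of either guild.
# residual_fun(a) must be continuous; bracket (a_min, a_max) is expanded
# upward geometrically when allowed (zooplankton uptake is uncapped).
solve_uptake <- function(residual_fun, a_min, a_max, expand = FALSE,
                         tol = 1e-11) {
  f_lo <- residual_fun(a_min)
  f_hi <- residual_fun(a_max)
  tries <- 0L
  while (expand && sign(f_lo) == sign(f_hi) && tries < 10L) {
    a_max <- a_max * 2
    f_hi <- residual_fun(a_max)
    tries <- tries + 1L
  }
  if (sign(f_lo) == sign(f_hi)) {
    stop2("uptake_no_root", "boundary condition has no root in the bracket")
  }
  stats::uniroot(residual_fun, c(a_min, a_max), f.lower = f_lo,
                 f.upper = f_hi, tol = tol)$root
}

#' Coupled phyto-zooplankton steady state
#'
#' Solves the self-consistent community steady state in renormalised
#' variables: the chemostat parameters in `chem` are interpreted per unit
#' of the renormalisation factor \eqn{\Xi}. Given a zooplankton spectrum
#' coefficient `z0`, the total mortality follows from
#' [predation_mortality()]; the phytoplankton boundary condition fixes the
#' nutrient (hence `a_hat`), the chemostat balance yields `p0`, the
#' zooplankton boundary condition yields `a_pz`, and consistency of
#' `a_pz` with [zoo_uptake()] closes the loop in `z0`.
#'
#' The closing scalar equation is solved by damped fixed-point iteration
#' (`solver = "fixed_point"`) or, by default, by bracketing and bisecting
#' its residual, which converges also when the fixed-point map is not a
#' contraction (for realistic parameter sets the map slope at the root
#' exceeds one, so plain iteration diverges; see the methods vignette).
#'
#' @param ps a [predation_spec()].
#' @param ds a [division_spec()]; its `idealised` flag (or `division`)
#'   selects the division flavour.
#' @param gp a [growth_params()].
#' @param chem a [chemostat_params()] holding the renormalised
#'   (per-unit-\eqn{\Xi}) chemostat constants.
#' @param background background mortality ([mortality_spec()]).
#' @param division `"ideal"` or `"general"`; defaults to the flag in `ds`.
#' @param assemblage optional [species_assemblage()]; when supplied, the
#'   finite renormalisation factor and per-species abundance coefficients
#'   are attached to the solution.
#' @param solver `"bisection"` (default) or `"fixed_point"`.
#' @param n_grid grid size for general-division profiles.
#' @param damping,max_iter fixed-point relaxation factor and iteration cap.
#' @param tol convergence tolerance on the `z0` residual.
#' @return an object of class `community_solution` with fields `gamma`,
#'   `p0`, `z0`, `a_pz`, `a_hat`, `N_hat`, profile moments `I_p`/`I_z` (or
#'   `J_p`/`J_z`), solver diagnostics, and (with an assemblage) `Xi` and
#'   abundance coefficients. Errors with class `"no_zoo_steady_state"` when
#'   no nonnegative `z0` satisfies the system.
#' @export
solve_coupled_steady_state <- function(ps, ds, gp, chem,
                                       background = mortality_spec(0.1),
                                       division = NULL,
                                       assemblage = NULL,
                                       solver = c("bisection", "fixed_point"),
                                       n_grid = 192, damping = 0.5,
                                       max_iter = 200L, tol = 1e-10) {
  solver <- match.arg(solver)
  division <- division %||% (if (ds$idealised) "ideal" else "general")
  gamma <- 1 + ps$nu + gp$xi
  S_g <- prey_kernel_moment(ps, gamma - 3)
  a_cap <- monod_uptake(chem$N0, gp)  # N_hat cannot exceed the capacity

  phyto_solve <- function(ms) {
    if (division == "ideal") {
      solve_uptake(function(a) coexistence_residual_a(a, ms, gp),
                   gp$b * (1 + 1e-6), a_cap * (1 - 1e-9))
    } else {
      solve_uptake(function(a) {
        general_profile(ds, ms, gp, a, n_grid = n_grid)$bc_residual
      }, gp$b * (1 + 1e-6), a_cap * (1 - 1e-9))
    }
  }
  zoo_solve <- function(ms) {
    if (division == "ideal") {
      solve_uptake(function(a) {
        gz <- zoo_growth_view(a, gp)
        coexistence_residual_a(a, ms, gz)
      }, gp$b * (1 + 1e-6), gp$a_inf, expand = TRUE)
    } else {
      solve_uptake(function(a) {
        gz <- zoo_growth_view(a, gp)
        general_profile(ds, ms, gz, a, n_grid = n_grid)$bc_residual
      }, gp$b * (1 + 1e-6), gp$a_inf, expand = TRUE)
    }
  }
  chain <- function(z0) {
    ms <- predation_mortality(z0, ps, gp, background)
    a_hat <- phyto_solve(ms)
    N_hat <- monod_invert(a_hat, gp)
    rho_hat <- chem$rho0 * (1 - N_hat / chem$N0)
    if (division == "ideal") {
      Im_gm1 <- ideal_moment(gamma - 1, ms, gp, a_hat)
      Im_al <- ideal_moment(gp$alpha, ms, gp, a_hat)
    } else {
      prof_p <- general_profile(ds, ms, gp, a_hat, n_grid = n_grid)
      Im_gm1 <- general_moment(gamma - 1, prof_p)
      Im_al <- general_moment(gp$alpha, prof_p)
    }
    p0 <- chem$theta * rho_hat * Im_gm1 / (a_hat * Im_al)
    a_pz <- zoo_solve(ms)
    z0_new <- a_pz / (ps$epsilon * S_g) - p0
    list(z0 = z0, z0_new = z0_new, a_hat = a_hat, N_hat = N_hat,
         p0 = p0, a_pz = a_pz, ms = ms)
  }

  trace <- list()
  if (solver == "fixed_point") {
    z0 <- 0.01
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      st <- chain(max(z0, 0))
      trace[[it]] <- c(z0 = st$z0, z0_new = st$z0_new, N_hat = st$N_hat)
      if (st$z0_new < 0 && z0 <= 0) {
        stop2("no_zoo_steady_state",
              "no zooplankton-supporting steady state: z0 update persistently negative")
      }
      z0_next <- (1 - damping) * z0 + damping * st$z0_new
      if (abs(z0_next - z0) <= tol * max(abs(z0), 1e-8)) {
        z0 <- z0_next
        converged <- TRUE
        break
      }
      z0 <- z0_next
    }
    if (!converged) {
      stop2("fixed_point_not_contracting",
            "damped fixed-point iteration did not converge; see trace",
            trace = do.call(rbind, trace))
    }
    st <- chain(max(z0, 0))
    iterations <- length(trace)
  } else {
    resid <- function(z0) {
      st <- chain(z0)
      st$z0_new - st$z0
    }
    # feasible range of z0: phyto condition solvable (a_hat below both
    # saturation and chemostat capacity)
    z_hi <- 1
    repeat {
      ok <- tryCatch({ resid(z_hi); TRUE },
                     uptake_no_root = function(e) FALSE,
                     uptake_saturated = function(e) FALSE)
      if (ok) break
      z_hi <- z_hi / 2
      if (z_hi < 1e-8) {
        stop2("no_zoo_steady_state",
              "phytoplankton cannot persist under any zooplankton pressure")
      }
    }
    # expand down/up to find a sign change of the residual
    zs <- seq(0, z_hi, length.out = 9)
    vals <- rep(NA_real_, length(zs))
    for (i in seq_along(zs)) {
      vals[i] <- tryCatch(resid(zs[i]), cellspectrum_error = function(e) NA)
    }
    ok <- which(is.finite(vals))
    if (length(ok) < 2) {
      stop2("no_zoo_steady_state", "coupled system infeasible on [0, z_max]")
    }
    flip <- which(diff(sign(vals[ok])) != 0)
    if (length(flip) == 0) {
      if (all(vals[ok] < 0)) {
        stop2("no_zoo_steady_state",
              "no zooplankton-supporting steady state for these parameters (z0 would be negative)")
      }
      stop2("no_zoo_steady_state",
            "zooplankton pressure runs away before the community balances")
    }
    i1 <- ok[flip[1]]; i2 <- ok[flip[1] + 1]
    ans <- bisect_root(resid, zs[i1], zs[i2], tol = tol)
    z0 <- max(ans$root, 0)
    st <- chain(z0)
    iterations <- ans$iterations
  }

  out <- list(gamma = gamma, p0 = st$p0, z0 = st$z0_new, a_pz = st$a_pz,
              a_hat = st$a_hat, N_hat = st$N_hat, mortality = st$ms,
              division = division, solver = solver,
              iterations = iterations, S_gamma = S_g,
              ps = ps, ds = ds, gp = gp, chem = chem,
              background = background, n_grid = n_grid)
  # profile moments and per-species abundance coefficients
  gz <- zoo_growth_view(st$a_pz, gp)
  if (division == "ideal") {
    out$I_p <- ideal_moment(gamma - 1, st$ms, gp, st$a_hat)
    out$I_z <- stats::integrate(function(x) {
      x^(gamma - 1) * phi_profile(x, st$ms, gz, st$a_pz)
    }, 0.5, 1, rel.tol = 1e-10)$value
  } else {
    prof_p <- general_profile(ds, st$ms, gp, st$a_hat, n_grid = n_grid)
    prof_z <- general_profile(ds, st$ms, gz, st$a_pz, n_grid = n_grid)
    out$J_p <- general_moment(gamma - 1, prof_p)
    out$J_z <- general_moment(gamma - 1, prof_z)
    out$profile_p <- prof_p
    out$profile_z <- prof_z
  }
  if (!is.null(assemblage)) {
    out$assemblage <- assemblage
    out$Xi <- renormalisation_factor(assemblage$w_min, assemblage$w_max,
                                     gamma, gp)
  }
  class(out) <- "community_solution"
  out
}

#' @export
print.community_solution <- function(x, ...) {
  cat(sprintf(
    "community_solution (%s division, %s solver)\n", x$division, x$solver))
  cat(sprintf("  gamma = %g, p0 = %.6g, z0 = %.6g\n", x$gamma, x$p0, x$z0))
  cat(sprintf("  a_hat = %.6g, a_pz = %.6g, N_hat = %.6g, iterations = %d\n",
              x$a_hat, x$a_pz, x$N_hat, x$iterations))
  invisible(x)
}

#' Per-species abundance coefficients of a community solution
#'
#' At the coupled steady state the species-level normalisations follow the
#' power law \eqn{p(\cdot, w_*) \propto w_*^{-\gamma-1}}: the boundary
#' value of each species' profile is
#' \eqn{p_0 / I_p(\gamma-1) \cdot w_*^{-\gamma-1}} (with `J_p` in the
#' general-division case), and likewise for zooplankton.
#'
#' @param sol a `community_solution`.
#' @param w_stars species characteristic sizes.
#' @return data frame with `w_star`, `p_norm`, `z_norm`.
#' @export
species_abundances <- function(sol, w_stars) {
  Ip <- sol$I_p %||% sol$J_p
  Iz <- sol$I_z %||% sol$J_z
  data.frame(w_star = w_stars,
             p_norm = sol$p0 / Ip * w_stars^(-sol$gamma - 1),
             z_norm = sol$z0 / Iz * w_stars^(-sol$gamma - 1))
}
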