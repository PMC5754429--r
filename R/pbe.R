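# Time-dependent population-balance solver.
#
# Each species lives on a shared relative-size grid x = w/w_star (all rates
# are homogeneous, so relative coordinates decouple the trait): advection at
# velocity w_star^{-xi} g(x), division as removal at rate w_star^{-xi} k(x)
# plus redistribution of two daughters through a precomputed allocation
# matrix, mortality as an explicit sink, and an explicit-Euler chemostat.
# The scheme is conservative first-order upwind; the allocation matrix is
# moment-corrected so every division yields exactly two daughters carrying
# exactly the parent biomass.

#' Simulator configuration
#'
#' Collects everything the time stepper needs. Either a fixed uptake
#' coefficient `a_fixed` (nutrient-rich culture) or chemostat parameters
#' `chem` (dynamic nutrient) must be supplied. Zooplankton species, when
#' present in the state, grow with the fixed uptake `a_pz` on the exponent
#' `1 - xi`.
#'
#' @param gp a [growth_params()].
#' @param ds a [division_spec()]; `idealised = TRUE` switches the division
#'   term to a reinjection boundary condition (split at the maximum size
#'   into two half-size cells).
#' @param ms a [mortality_spec()] (use `mortality_spec(0)` for none).
#' @param chem optional [chemostat_params()] for dynamic nutrient.
#' @param a_fixed fixed uptake coefficient when no chemostat is coupled.
#' @param a_pz fixed zooplankton uptake coefficient (if zoo species run).
#' @param n_cells number of grid cells.
#' @param x_lo lower edge of the relative-size grid.
#' @param cfl safety factor on the combined advection/sink time-step bound.
#' @return an object of class `pbe_config`.
#' @export
pbe_config <- function(gp, ds, ms = mortality_spec(0), chem = NULL,
                       a_fixed = NULL, a_pz = NULL,
                       n_cells = 256, x_lo = NULL, cfl = 0.5) {
  if (is.null(chem) && is.null(a_fixed)) {
    stop2("bad_config", "supply either a_fixed or chemostat parameters")
  }
  x_lo <- x_lo %||% (ds$xth * (1 - ds$delta) / 2 * 0.5)
  edges <- geom_seq(x_lo, 1, n_cells + 1)
  centers <- sqrt(edges[-1] * edges[-(n_cells + 1)])
  dx <- diff(edges)
  cfg <- list(gp = gp, ds = ds, ms = ms, chem = chem, a_fixed = a_fixed,
              a_pz = a_pz, n_cells = n_cells, edges = edges, x = centers,
              dx = dx, cfl = cfl)
  if (!ds$idealised) {
    cfg$division <- division_operator(ds, edges, centers, dx)
    # cells reaching the maximum size divide with certainty (divergent
    # division-rate integral): the upper boundary flux re-enters as two
    # daughters of a parent of size 1
    cfg$top_alloc <- daughter_allocation(1, ds, edges, centers, dx)
  } else {
    # reinjection target: the cell containing x = 1/2
    cfg$reinject_cell <- findInterval(0.5, edges, all.inside = TRUE)
  }
  cfg$K <- if (ds$idealised) numeric(n_cells) else ds$k(centers)
  cfg$m_bg <- ms$m(centers)
  class(cfg) <- "pbe_config"
  cfg
}

# Discrete division operator: columns are parent cells, rows daughter cells.
# alloc[, j] integrates the daughter density Q(w | x_j) over each cell and
# is then moment-corrected so that each parent yields exactly 2 daughters
# (number) and exactly its own biomass (first moment), the discrete
# counterpart of the unit integral and symmetry of q.
division_operator <- function(ds, edges, centers, dx) {
  n <- length(centers)
  K <- ds$k(centers)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in which(K > 0 & is.finite(K))) {
    alloc <- daughter_allocation(centers[j], ds, edges, centers, dx)
    if (length(alloc$cells) == 0) next
    ii <- c(ii, alloc$cells); jj <- c(jj, rep.int(j, length(alloc$cells)))
    vv <- c(vv, 2 * K[j] * alloc$frac * dx[j] / dx[alloc$cells])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

# number fraction of one daughter landing in each grid cell for a given
# parent size, moment-corrected so that sum(frac) = 1 (one daughter) and
# sum(frac * centers) = parent/2 (half the parent biomass each)
daughter_allocation <- function(parent, ds, edges, centers, dx) {
  n <- length(centers)
  w_lo <- (1 - ds$delta) / 2 * parent
  w_hi <- (1 + ds$delta) / 2 * parent
  cells <- which(edges[-1] > w_lo & edges[-(n + 1)] < w_hi)
  if (length(cells) == 0) return(list(cells = integer(0), frac = numeric(0)))
  frac <- vapply(cells, function(i) {
    a <- max(edges[i], w_lo); b <- min(edges[i + 1], w_hi)
    if (b <= a) return(0)
    sum(panel_quad(function(w) ds$q(w / parent) / parent, a, b))
  }, numeric(1))
  if (length(cells) >= 2) {
    A <- rbind(rep(1, length(cells)), centers[cells])
    r <- c(1 - sum(frac), parent / 2 - sum(frac * centers[cells]))
    corr <- crossprod(A, solve(tcrossprod(A), r))
    frac <- frac + as.numeric(corr)
  } else {
    frac <- frac / sum(frac)
  }
  list(cells = cells, frac = frac)
}

#' Initial simulator state
#'
#' Densities on the shared relative-size grid for a set of phytoplankton
#' (and optionally zooplankton) species. The default initial condition is
#' a Gaussian cohort centred at relative size 0.5 with width 0.05,
#' normalised to the requested number of cells per species.
#'
#' @param config a [pbe_config()].
#' @param w_stars phytoplankton characteristic sizes.
#' @param zw_stars optional zooplankton characteristic sizes.
#' @param N initial nutrient level (defaults to half capacity, or `NA` for
#'   fixed-uptake runs).
#' @param centre,width centre and standard deviation of the initial cohort
#'   in relative size.
#' @param number initial number of cells per unit volume per species.
#' @param w_weights optional trait weights (for approximating a continuum
#'   of species by a finite assemblage); default 1 per species.
#' @return an object of class `pbe_state`.
#' @export
pbe_state <- function(config, w_stars, zw_stars = numeric(0), N = NULL,
                      centre = 0.5, width = 0.05, number = 1,
                      w_weights = NULL) {
  x <- config$x
  dens <- exp(-(x - centre)^2 / (2 * width^2))
  dens <- dens / sum(dens * config$dx)
  p <- matrix(rep(dens * number, length(w_stars)), ncol = length(w_stars))
  z <- matrix(rep(dens * number, length(zw_stars)), ncol = length(zw_stars))
  if (is.null(N)) {
    N <- if (!is.null(config$chem)) config$chem$N0 / 2 else NA_real_
  }
  structure(list(w_stars = w_stars, zw_stars = zw_stars,
                 p = p, z = z, N = N, t = 0,
                 w_weights = w_weights %||% rep(1, length(w_stars)),
                 zw_weights = rep(1, length(zw_stars)),
                 leak = 0),
            class = "pbe_state")
}

#' @export
print.pbe_state <- function(x, ...) {
  cat(sprintf("pbe_state: t=%.4g, %d phyto + %d zoo species, N=%.5g\n",
              x$t, length(x$w_stars), length(x$zw_stars), x$N))
  invisible(x)
}

# number / biomass summaries (config only needed for the grid widths,
# carried on the state at construction is avoided to keep the state light)
state_moments <- function(state, config) {
  dx <- config$dx
  num <- 0; bio <- 0
  if (length(state$w_stars)) {
    num <- num + sum(state$w_weights * colSums(state$p * dx))
    bio <- bio + sum(state$w_weights * state$w_stars *
                       colSums(state$p * config$x * dx))
  }
  if (length(state$zw_stars)) {
    num <- num + sum(state$zw_weights * colSums(state$z * dx))
    bio <- bio + sum(state$zw_weights * state$zw_stars *
                       colSums(state$z * config$x * dx))
  }
  c(number = num, biomass = bio)
}

total_number <- function(state, config) {
  state_moments(state, config)[["number"]]
}

# stable explicit time step: advection CFL and sink bound combined
pbe_dt <- function(state, config) {
  gp <- config$gp
  a_val <- config$a_fixed %||% monod_uptake(state$N, gp)
  vmax_rel <- max(abs(growth_shape(config$x, gp, a_val)))
  if (length(state$zw_stars) && !is.null(config$a_pz)) {
    vmax_rel <- max(vmax_rel, abs(config$a_pz * config$x^(1 - gp$xi) -
                                    gp$b * config$x^gp$beta))
  }
  sc_max <- max(c(state$w_stars, state$zw_stars)^(-gp$xi))
  v_bound <- min(config$dx) / (vmax_rel + 1e-300)
  sink <- max(config$K + config$m_bg)
  sink_bound <- if (sink > 0) 1 / sink else Inf
  config$cfl * min(v_bound, sink_bound) / sc_max
}

# advance one guild (matrix dens, per-species scale w*^{-xi}) by dt;
# returns list(dens, leak_rate) where leak_rate is the number flux lost
# through the upper boundary (zero for idealised division, which reinjects)
advect_divide <- function(dens, w_stars, config, g_rel, dt) {
  xi <- config$gp$xi
  n <- config$n_cells
  dx <- config$dx
  leak <- 0
  for (s in seq_along(w_stars)) {
    sc <- w_stars[s]^(-xi)
    ps <- dens[, s]
    # upwind fluxes at interior faces; velocity from the upwind cell side
    v <- sc * g_rel  # velocity at cell centres in x
    f_face <- numeric(n + 1)  # faces 1..n+1, flux positive rightward
    vf <- 0.5 * (v[-n] + v[-1])
    f_face[2:n] <- ifelse(vf > 0, vf * ps[-n], vf * ps[-1])
    f_face[n + 1] <- max(v[n], 0) * ps[n]  # outflow at x = 1
    adv <- -(f_face[-1] - f_face[-(n + 1)]) / dx
    rate <- adv - sc * (config$K + config$m_bg) * ps
    if (!config$ds$idealised) {
      rate <- rate + sc * as.numeric(config$division %*% ps)
      ta <- config$top_alloc
      rate[ta$cells] <- rate[ta$cells] +
        2 * f_face[n + 1] * ta$frac / dx[ta$cells]
    } else {
      rc <- config$reinject_cell
      rate[rc] <- rate[rc] + 2 * f_face[n + 1] / dx[rc]
    }
    dens[, s] <- ps + dt * rate
  }
  list(dens = dens, leak = leak)
}

#' Advance the simulator by one explicit step
#'
#' One conservative upwind/Euler step of length `dt` for every species,
#' plus the nutrient update when a chemostat is coupled. Refuses a step
#' that violates the stability bound.
#'
#' @param state a [pbe_state()].
#' @param dt time step; must satisfy the combined advection/sink bound.
#' @param config a [pbe_config()].
#' @return the advanced state.
#' @export
pbe_step <- function(state, dt, config) {
  dt_max <- pbe_dt(state, config) / config$cfl
  if (dt > dt_max) {
    stop2("cfl_violation",
          sprintf("dt = %g exceeds the stability bound %g", dt, dt_max))
  }
  gp <- config$gp
  a_val <- config$a_fixed %||% monod_uptake(state$N, gp)
  g_rel <- growth_shape(config$x, gp, a_val)
  res <- advect_divide(state$p, state$w_stars, config, g_rel, dt)
  state$p <- res$dens
  state$leak <- state$leak + dt * res$leak
  if (length(state$zw_stars)) {
    if (is.null(config$a_pz)) {
      stop2("bad_config", "zooplankton present but a_pz not configured")
    }
    gz_rel <- config$a_pz * config$x^(1 - gp$xi) - gp$b * config$x^gp$beta
    resz <- advect_divide(state$z, state$zw_stars, config, gz_rel, dt)
    state$z <- resz$dens
    state$leak <- state$leak + dt * resz$leak
  }
  if (!is.null(config$chem)) {
    state$N <- max(state$N + dt * nutrient_derivative(state, config), 0)
  }
  state$t <- state$t + dt
  state
}

#' Chemostat nutrient derivative
#'
#' \eqn{dN/dt = \varrho_0 (1 - N/N_0) - \sigma(N, p)} with the consumption
#' \eqn{\sigma = a(N)/\theta \sum_s \omega_s w_{*s}^{1-\xi} \int x^\alpha
#' p_s(x)\,dx} summed over phytoplankton species (weights `w_weights`
#' approximate the trait integral for finite assemblages).
#'
#' @param state a [pbe_state()].
#' @param config a [pbe_config()] with chemostat parameters.
#' @return the time derivative of the nutrient level.
#' @export
nutrient_derivative <- function(state, config) {
  chem <- config$chem
  gp <- config$gp
  a_val <- monod_uptake(state$N, gp)
  cons <- 0
  if (length(state$w_stars)) {
    per_sp <- colSums(state$p * config$x^gp$alpha * config$dx)
    cons <- sum(state$w_weights * state$w_stars^(1 - gp$xi) * per_sp)
  }
  chem$rho0 * (1 - state$N / chem$N0) - a_val / chem$theta * cons
}

#' Run the simulator
#'
#' Explicit integration to `t_end` with automatic step size, recording
#' summary time series and optional checkpoint profiles.
#'
#' @param state initial [pbe_state()].
#' @param t_end end time.
#' @param config a [pbe_config()].
#' @param record_dt interval between recorded summary rows.
#' @param checkpoints times at which full per-species profiles are kept.
#' @param guard abort threshold on any density (blow-up detection).
#' @return list with `series` (data frame `t, N, number, biomass`),
#'   `state` (final), and `checkpoints` (list of states).
#' @export
pbe_simulate <- function(state, t_end, config, record_dt = NULL,
                         checkpoints = numeric(0), guard = 1e12) {
  record_dt <- record_dt %||% (t_end / 400)
  next_rec <- state$t
  next_cp <- if (length(checkpoints)) 1L else 0L
  rows <- list(); cps <- list()
  repeat {
    if (state$t >= next_rec || state$t >= t_end) {
      mom <- state_moments(state, config)
      rows[[length(rows) + 1]] <- c(t = state$t, N = state$N, mom)
      next_rec <- next_rec + record_dt
    }
    if (next_cp > 0 && next_cp <= length(checkpoints) &&
        state$t >= checkpoints[next_cp]) {
      cps[[next_cp]] <- state
      next_cp <- next_cp + 1L
    }
    if (state$t >= t_end) break
    dt <- min(pbe_dt(state, config), t_end - state$t + 1e-15)
    state <- pbe_step(state, dt, config)
    if (max(state$p, if (length(state$z)) state$z else 0) > guard) {
      stop2("blow_up", sprintf("density exceeded %g at t = %g", guard,
                               state$t))
    }
  }
  series <- as.data.frame(do.call(rbind, rows))
  list(series = series, state = state, checkpoints = cps)
}

#' Exponential growth rate from a number time series
#'
#' Least-squares slope of `log(number)` against time over the trailing
#' window, for measuring the population growth rate of a nutrient-rich
#' culture.
#'
#' @param t,number time and total-number vectors.
#' @param window_frac trailing fraction of the series used for the fit.
#' @return the estimated rate.
#' @export
measure_growth_rate <- function(t, number, window_frac = 0.5) {
  keep <- t >= stats::quantile(t, 1 - window_frac)
  tt <- t[keep]; nn <- number[keep]
  if (any(nn <= 0)) stop2("bad_series", "number must stay positive")
  if (any(diff(nn) < -1e-8 * nn[-length(nn)])) {
    stop2("bad_series", "late-time series is not monotone; refusing the fit")
  }
  unname(stats::coef(stats::lm(log(nn) ~ tt))[2])
}

#' Scale transformation of a state
#'
#' Applies the spectrum scale transformation
#' \eqn{p_\lambda(w, w_*) = \lambda^{\gamma+1} p(\lambda w, \lambda w_*)}:
#' every species' trait is relabelled `w_star / lambda` and its relative
#' density multiplied by `lambda^{gamma-1}` (the per-trait density per
#' relative size transforms with two powers fewer). A steady power-law
#' community maps onto itself.
#'
#' @param state a [pbe_state()].
#' @param lam positive scale factor.
#' @param gamma community spectrum exponent.
#' @param bounds optional `c(w_min, w_max)` guard for the transformed
#'   assemblage.
#' @return the transformed state.
#' @export
scale_transform <- function(state, lam, gamma, bounds = NULL) {
  if (lam <= 0) stop2("bad_scale", "lam must be positive")
  out <- state
  out$w_stars <- state$w_stars / lam
  out$zw_stars <- state$zw_stars / lam
  if (!is.null(bounds)) {
    all_w <- c(out$w_stars, out$zw_stars)
    if (length(all_w) && (min(all_w) < bounds[1] || max(all_w) > bounds[2])) {
      stop2("bad_scale", "transformed assemblage leaves [w_min, w_max]")
    }
  }
  fac <- lam^(gamma - 1)
  if (length(state$p)) out$p <- state$p * fac
  if (length(state$z)) out$z <- state$z * fac
  out
}

#' Right-hand side of the population balance equations
#'
#' Instantaneous time derivatives of all densities and of the nutrient for
#' a given state, useful for residual diagnostics (e.g. verifying that the
#' analytic steady state and its scale transforms are numerically steady).
#'
#' @param state a [pbe_state()].
#' @param config a [pbe_config()].
#' @return list with matrices `dp` (and `dz`) and scalar `dN`.
#' @export
pbe_rhs <- function(state, config) {
  gp <- config$gp
  a_val <- config$a_fixed %||% monod_uptake(state$N, gp)
  g_rel <- growth_shape(config$x, gp, a_val)
  # advect_divide applies dens + dt * rate; recover the rate with dt = 1
  res1 <- advect_divide(state$p, state$w_stars, config, g_rel, dt = 1)
  dp <- res1$dens - state$p
  out <- list(dp = dp)
  if (length(state$zw_stars)) {
    gz_rel <- config$a_pz * config$x^(1 - gp$xi) - gp$b * config$x^gp$beta
    dz <- advect_divide(state$z, state$zw_stars, config, gz_rel,
                        dt = 1)$dens - state$z
    out$dz <- dz
  }
  out$dN <- if (!is.null(config$chem)) nutrient_derivative(state, config)
            else 0
  out
}

#' Division-wave bookkeeping ratio
#'
#' Generation-tagged cohort experiment auditing the factor-2 number
#' bookkeeping of the division term: a synchronized sub-threshold cohort
#' (the parent generation) is integrated with zero mortality; divisions
#' remove parents and deposit both daughters into a separate tally field
#' that is frozen at birth (following the daughters further would mix the
#' generations, as the fastest daughters re-divide before the slowest
#' parents have divided). Returns the ratio of total cell number (remaining
#' parents plus daughters) to the initial number once the parent generation
#' is exhausted; the exact value is 2.
#'
#' @param config a [pbe_config()] with non-idealised division and a fixed
#'   uptake coefficient.
#' @param centre,width initial cohort position and width in relative size.
#' @param t_max integration cap.
#' @param done_frac parent-number fraction below which the wave counts as
#'   complete.
#' @return list with `ratio`, the completion time `t_done`, and the
#'   remaining parent fraction.
#' @export
division_wave_ratio <- function(config, centre = 0.5, width = 0.05,
                                t_max = 12, done_frac = 1e-8) {
  if (config$ds$idealised) {
    stop2("bad_config", "generation tagging requires the general division process")
  }
  if (is.null(config$a_fixed)) {
    stop2("bad_config", "use a fixed uptake coefficient (nutrient-rich run)")
  }
  gp <- config$gp
  n <- config$n_cells
  dx <- config$dx
  x <- config$x
  A <- exp(-(x - centre)^2 / (2 * width^2))
  A <- A / sum(A * dx)
  B <- numeric(n)
  n0 <- sum(A * dx)
  g_rel <- growth_shape(x, gp, config$a_fixed)
  K <- config$K
  ta <- config$top_alloc
  gain_of <- function(ps, f_top) {
    g <- as.numeric(config$division %*% ps)
    g[ta$cells] <- g[ta$cells] + 2 * f_top * ta$frac / dx[ta$cells]
    g
  }
  dt <- config$cfl * min(min(dx) / max(abs(g_rel)), 1 / max(K))
  t <- 0
  vf <- 0.5 * (g_rel[-n] + g_rel[-1])
  step_adv <- function(ps) {
    f_face <- numeric(n + 1)
    f_face[2:n] <- ifelse(vf > 0, vf * ps[-n], vf * ps[-1])
    f_face[n + 1] <- max(g_rel[n], 0) * ps[n]
    list(adv = -(f_face[-1] - f_face[-(n + 1)]) / dx, top = f_face[n + 1])
  }
  repeat {
    sa <- step_adv(A)
    A_new <- A + dt * (sa$adv - K * A)
    B <- B + dt * gain_of(A, sa$top)
    A <- A_new; t <- t + dt
    if (sum(A * dx) < done_frac * n0 || t >= t_max) break
  }
  list(ratio = (sum(A * dx) + sum(B * dx)) / n0, t_done = t,
       parent_fraction = sum(A * dx) / n0)
}
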