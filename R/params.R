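#' Physiological growth parameters
#'
#' Bundle of allometric von Bertalanffy growth constants and the Monod
#' half-saturation for nutrient-limited uptake. Cell growth follows
#' \eqn{dw/dt = w_*^{1-\xi}[a (w/w_*)^\alpha - b (w/w_*)^\beta]} where the
#' uptake coefficient \eqn{a} saturates with nutrient as
#' \eqn{a(N) = a_\infty N/(r+N)}. Sizes are dimensionless (measured relative
#' to a reference size), so all exponents act on pure numbers.
#'
#' @param a_inf saturated uptake coefficient \eqn{a_\infty} (per unit time);
#'   must exceed `b` so that growth is feasible in nutrient-rich conditions.
#' @param b metabolic loss coefficient (per unit time).
#' @param alpha uptake allometric exponent; must satisfy `alpha < beta`.
#' @param beta metabolic allometric exponent.
#' @param xi doubling-period exponent: the time to grow from `w_star/2` to
#'   `w_star` scales as \eqn{\tau w_*^\xi}; empirically about 0.15.
#' @param r Monod half-saturation constant (nutrient units).
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(a_inf = 0.7, b = 0.5, alpha = 0.85, beta = 1,
                          xi = 0.15, r = 1) {
  if (!(alpha < beta)) stop2("bad_exponents", "requires alpha < beta")
  if (!(a_inf > b && b > 0)) stop2("bad_uptake", "requires a_inf > b > 0")
  if (!(xi > 0 && xi < 1)) stop2("bad_xi", "requires 0 < xi < 1")
  if (!(r > 0)) stop2("bad_halfsat", "requires r > 0")
  structure(list(a_inf = a_inf, b = b, alpha = alpha, beta = beta,
                 xi = xi, r = r),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "growth_params: a_inf=%g b=%g alpha=%g beta=%g xi=%g r=%g\n",
    x$a_inf, x$b, x$alpha, x$beta, x$xi, x$r))
  invisible(x)
}

#' Chemostat parameters
#'
#' The nutrient pool is replenished toward capacity `N0` at rate
#' \eqn{\varrho(N) = \varrho_0 (1 - N/N_0)} and depleted by phytoplankton
#' uptake with yield `theta` (biomass produced per unit nutrient).
#' In renormalised (infinite-community) calculations the same object holds
#' the hatted quantities \eqn{\hat\varrho_0, \hat N_0}, i.e. the values per
#' unit of the trait-integral factor \eqn{\Xi}.
#'
#' @param rho0 replenishment rate coefficient.
#' @param N0 chemostat capacity (nutrient level at which replenishment stops).
#' @param theta yield: biomass generated per unit of nutrient consumed.
#' @return an object of class `chemostat_params`.
#' @export
chemostat_params <- function(rho0 = 1, N0 = 10, theta = 1) {
  if (!(N0 > 0)) stop2("bad_capacity", "requires N0 > 0")
  if (!(theta > 0)) stop2("bad_yield", "requires theta > 0")
  if (rho0 < 0) stop2("bad_replenishment", "requires rho0 >= 0")
  structure(list(rho0 = rho0, N0 = N0, theta = theta),
            class = "chemostat_params")
}

# ---- division kernels -------------------------------------------------------

# registry of division-rate shapes k(x), nonzero on (xth, 1), diverging at 1
k_shape_fun <- function(name, xth, k_scale, k_power) {
  switch(name,
    quadratic_pole = function(x) {
      out <- numeric(length(x))
      inside <- x > xth & x < 1
      out[inside] <- k_scale * (x[inside] - xth)^2 / (1 - x[inside])
      out[x >= 1] <- Inf
      out
    },
    power_pole = function(x) {
      out <- numeric(length(x))
      inside <- x > xth & x < 1
      out[inside] <- k_scale * (x[inside] - xth)^k_power / (1 - x[inside])
      out[x >= 1] <- Inf
      out
    },
    stop2("unknown_k_shape", paste("unknown division-rate shape:", name))
  )
}

q_shape_fun <- function(name, delta) {
  lo <- (1 - delta) / 2
  hi <- (1 + delta) / 2
  switch(name,
    uniform = function(x) ifelse(x > lo & x < hi, 1 / delta, 0),
    triangular = function(x) {
      out <- numeric(length(x))
      left <- x > lo & x <= 0.5
      right <- x > 0.5 & x < hi
      out[left] <- 4 * (x[left] - lo) / delta^2
      out[right] <- 4 * (hi - x[right]) / delta^2
      out
    },
    stop2("unknown_q_shape", paste("unknown daughter-size shape:", name))
  )
}

#' Cell-division specification
#'
#' Describes the sloppy-size-control division process: cells of species
#' `w_star` may divide once their relative size `x = w/w_star` exceeds the
#' threshold fraction `xth`, at rate \eqn{K(w, w_*) = w_*^{-\xi} k(w/w_*)},
#' and split into two daughters whose sizes (as fractions of the parent) are
#' drawn from the symmetric density `q` supported on
#' \eqn{((1-\delta)/2, (1+\delta)/2)}. The rate shape `k` must diverge at
#' `x = 1` strongly enough that \eqn{\int^1 k = \infty}, guaranteeing no cell
#' outgrows its maximum size; this is probed numerically at construction.
#' With `idealised = TRUE` the division is instead a deterministic split at
#' exactly `w = w_star` into two equal halves.
#'
#' @param xth threshold fraction `w_th/w_star` in (0, 1) below which cells
#'   cannot divide. Must exceed `(1+delta)/2` so that no newborn daughter is
#'   already above the division threshold.
#' @param delta relative half-width of the daughter-size distribution.
#' @param k_shape name of the division-rate shape: `"quadratic_pole"` for
#'   \eqn{k(x) = c (x - x_{th})^2/(1-x)} or `"power_pole"` for a general
#'   exponent.
#' @param q_shape `"uniform"` or `"triangular"` daughter-size density.
#' @param k_scale multiplier `c` of the rate shape.
#' @param k_power exponent for the `"power_pole"` shape.
#' @param idealised if `TRUE`, use the idealised split-at-maximum process.
#' @return an object of class `division_spec` with callable `k` and `q`.
#' @export
division_spec <- function(xth = 0.7, delta = 0.2, k_shape = "quadratic_pole",
                          q_shape = "uniform", k_scale = 4, k_power = 2,
                          idealised = FALSE) {
  if (!(xth > 0 && xth < 1)) stop2("bad_threshold", "requires 0 < xth < 1")
  if (!(delta > 0 && delta < 1)) stop2("bad_delta", "requires 0 < delta < 1")
  if (!((1 + delta) / 2 < xth)) {
    stop2("daughter_above_threshold",
          sprintf("requires (1+delta)/2 < xth but (1+%g)/2 = %g >= %g",
                  delta, (1 + delta) / 2, xth))
  }
  k <- k_shape_fun(k_shape, xth, k_scale, k_power)
  q <- q_shape_fun(q_shape, delta)

  # probe q: unit mass and symmetry about 1/2
  qi <- stats::integrate(q, (1 - delta) / 2, (1 + delta) / 2,
                         rel.tol = 1e-12)$value
  if (abs(qi - 1) > 1e-8) {
    stop2("q_not_normalised", sprintf("daughter density integrates to %g", qi))
  }
  xs <- seq((1 - delta) / 2 + delta / 50, 0.5, length.out = 11)
  if (max(abs(q(xs) - q(1 - xs))) > 1e-10) {
    stop2("q_not_symmetric", "daughter density must satisfy q(x) = q(1-x)")
  }

  if (!idealised) {
    # probe divergence of int_xth^1 k: the tail integral over (1-eps, 1)
    # must keep growing as eps shrinks (log-type divergence or worse)
    i1 <- stats::integrate(k, xth, 1 - 1e-4, rel.tol = 1e-9)$value
    i2 <- stats::integrate(k, xth, 1 - 1e-8, rel.tol = 1e-9)$value
    if (!(i2 > i1 * 1.5)) {
      stop2("k_not_divergent",
            "division rate must satisfy a divergent integral at x = 1")
    }
  }

  structure(list(xth = xth, delta = delta, k = k, q = q,
                 k_shape = k_shape, q_shape = q_shape,
                 k_scale = k_scale, k_power = k_power,
                 w_plus = (1 + delta) / 2, idealised = idealised),
            class = "division_spec")
}

#' @export
print.division_spec <- function(x, ...) {
  if (x$idealised) {
    cat("division_spec: idealised split at w = w* into two equal halves\n")
  } else {
    cat(sprintf("division_spec: k=%s (scale %g), q=%s, xth=%g, delta=%g\n",
                x$k_shape, x$k_scale, x$q_shape, x$xth, x$delta))
  }
  invisible(x)
}

#' Mortality specification
#'
#' Death rate in the scaling form \eqn{M(w, w_*) = w_*^{-\xi} m(w/w_*)}.
#' The shape `m` is either a constant background rate or any nonnegative
#' function of relative size (e.g. the background-plus-predation total
#' returned by [death_rate_powerlaw()]).
#'
#' @param m0 constant background mortality level, used when `m` is omitted.
#' @param m optional function of relative size `x` in (0, 1].
#' @param label short description used when printing.
#' @return an object of class `mortality_spec`.
#' @export
mortality_spec <- function(m0 = 0.1, m = NULL, label = NULL) {
  if (is.null(m)) {
    if (m0 < 0) stop2("bad_mortality", "requires m0 >= 0")
    force(m0)
    m <- function(x) rep_len(m0, length(x))
    label <- label %||% sprintf("constant m0=%g", m0)
  } else {
    probe <- m(seq(0.05, 1, length.out = 20))
    if (any(!is.finite(probe)) || any(probe < 0)) {
      stop2("bad_mortality", "mortality shape must be finite and >= 0 on (0,1]")
    }
    label <- label %||% "custom shape"
  }
  structure(list(m = m, m0 = m0, label = label), class = "mortality_spec")
}

#' @export
print.mortality_spec <- function(x, ...) {
  cat("mortality_spec:", x$label, "\n")
  invisible(x)
}

#' Species assemblage
#'
#' A finite set of species characterised by their maximum cell sizes
#' `w_stars`, together with the community size bounds used in trait
#' integrals and in the renormalisation factor.
#'
#' @param w_stars vector of characteristic (maximum) cell sizes.
#' @param w_min,w_max community bounds; default to the range of `w_stars`.
#' @return an object of class `species_assemblage`.
#' @seealso [make_assemblage()] for log-spaced construction.
#' @export
species_assemblage <- function(w_stars, w_min = min(w_stars),
                               w_max = max(w_stars)) {
  if (any(w_stars <= 0) || w_min <= 0 || w_max <= 0) {
    stop2("bad_sizes", "sizes must be strictly positive")
  }
  if (!(w_min <= min(w_stars) && max(w_stars) <= w_max)) {
    stop2("bad_bounds", "requires w_min <= min(w_stars) <= max(w_stars) <= w_max")
  }
  structure(list(w_stars = sort(w_stars), w_min = w_min, w_max = w_max),
            class = "species_assemblage")
}

#' @export
print.species_assemblage <- function(x, ...) {
  cat(sprintf("species_assemblage: %d species on [%g, %g]\n",
              length(x$w_stars), x$w_min, x$w_max))
  invisible(x)
}

#' Predation specification
#'
#' Zooplankton feed on smaller cells at rate
#' \eqn{S(w, w') = w^\nu s(w/w')}, where `w` is the predator and `w'` the
#' prey size. The preference kernel `s` of the predator/prey size ratio is
#' log-normal in the log ratio: peaked at `ratio_mode`, with logarithmic
#' width `log_width` and amplitude `s0`. A fraction `epsilon` of ingested
#' prey biomass is converted into predator biomass.
#'
#' @param nu foraging allometric exponent; with `xi` it sets the community
#'   spectrum exponent `gamma = 1 + nu + xi`.
#' @param epsilon conversion efficiency in (0, 1].
#' @param ratio_mode preferred predator:prey size ratio.
#' @param log_width width of the preference kernel in log-ratio units.
#' @param s0 kernel amplitude (per unit time).
#' @return an object of class `predation_spec` with callable kernel `s`.
#' @export
predation_spec <- function(nu = 0.85, epsilon = 0.3, ratio_mode = 100,
                           log_width = 1, s0 = 1) {
  if (!(epsilon > 0 && epsilon <= 1)) {
    stop2("bad_efficiency", "requires 0 < epsilon <= 1")
  }
  if (ratio_mode <= 0 || log_width <= 0 || s0 <= 0) {
    stop2("bad_kernel", "kernel parameters must be positive")
  }
  mu <- log(ratio_mode)
  s <- function(y) {
    out <- numeric(length(y))
    pos <- y > 0
    out[pos] <- s0 * exp(-(log(y[pos]) - mu)^2 / (2 * log_width^2))
    out
  }
  structure(list(nu = nu, epsilon = epsilon, ratio_mode = ratio_mode,
                 log_width = log_width, s0 = s0, s = s),
            class = "predation_spec")
}

#' @export
print.predation_spec <- function(x, ...) {
  cat(sprintf(
    "predation_spec: nu=%g epsilon=%g lognormal preference (mode %g, width %g, s0=%g)\n",
    x$nu, x$epsilon, x$ratio_mode, x$log_width, x$s0))
  invisible(x)
}

#' Canonical parameter set
#'
#' The reference configuration used throughout the package examples and
#' tests: growth constants `a = 0.7, b = 0.5, alpha = 0.85, beta = 1`,
#' doubling-period exponent `xi = 0.15`, division threshold at `0.7 w_star`
#' with rate shape \eqn{k(x) = 4 (x-0.7)^2/(1-x)} and daughter sizes uniform
#' on `[0.4, 0.6]` of the parent, constant background mortality `m0 = 0.1`,
#' and a unit-yield chemostat (`rho0 = 1, N0 = 10, theta = 1, r = 1`).
#'
#' @return a list with elements `growth`, `division`, `mortality`,
#'   `chemostat`, and `predation`.
#' @export
canonical_params <- function() {
  list(growth = growth_params(),
       division = division_spec(),
       mortality = mortality_spec(0.1),
       chemostat = chemostat_params(),
       predation = predation_spec())
}
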