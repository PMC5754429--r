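# The four kernel families evaluated in absolute size coordinates.
# All are homogeneous: G_p of degree 1-xi, K and M of degree -xi, Q of -1.

#' Phytoplankton growth rate
#'
#' Mass growth rate \eqn{G_p(w, w_*) = w_*^{1-\xi}[a (w/w_*)^\alpha -
#' b (w/w_*)^\beta]} with uptake coefficient `a_val` (use [monod_uptake()]
#' to obtain it from a nutrient level).
#'
#' @param w current cell size (vectorised).
#' @param w_star maximum cell size of the species.
#' @param gp a [growth_params()] object.
#' @param a_val uptake coefficient; defaults to the saturated value.
#' @return growth rate(s), positive on `(0, w_star]` whenever `a_val > b`.
#' @export
growth_rate <- function(w, w_star, gp, a_val = gp$a_inf) {
  if (any(w <= 0) || any(w_star <= 0)) {
    stop2("bad_sizes", "sizes must be strictly positive")
  }
  x <- w / w_star
  w_star^(1 - gp$xi) * (a_val * x^gp$alpha - gp$b * x^gp$beta)
}

# relative-coordinate growth shape g(x) = a x^alpha - b x^beta
growth_shape <- function(x, gp, a_val) {
  a_val * x^gp$alpha - gp$b * x^gp$beta
}

#' Monod nutrient uptake
#'
#' Saturating uptake coefficient \eqn{a(N) = a_\infty N / (r + N)}.
#'
#' @param N nutrient concentration (vectorised), must be nonnegative.
#' @param gp a [growth_params()] object.
#' @return uptake coefficient(s) in `[0, a_inf)`.
#' @export
monod_uptake <- function(N, gp) {
  if (any(N < 0)) stop2("bad_nutrient", "nutrient must be >= 0")
  gp$a_inf * N / (gp$r + N)
}

# invert a = a_inf N/(r+N); a must be < a_inf
monod_invert <- function(a_val, gp) {
  if (any(a_val >= gp$a_inf)) {
    stop2("uptake_saturated", "uptake coefficient must be below a_inf")
  }
  gp$r * a_val / (gp$a_inf - a_val)
}

#' Doubling period
#'
#' Time for a cell to grow from `w_star/2` to `w_star`:
#' \eqn{T(w_*) = \tau w_*^\xi} with
#' \eqn{\tau = \int_{1/2}^1 du / (a u^\alpha - b u^\beta)}.
#'
#' @inheritParams growth_rate
#' @return doubling time; errors with class `"growth_infeasible"` when
#'   `a_val <= b` (growth stalls before the maximum size is reached).
#' @export
doubling_time <- function(w_star, gp, a_val = gp$a_inf) {
  if (a_val <= gp$b) {
    stop2("growth_infeasible",
          "a_val <= b: growth stalls on [w_star/2, w_star]")
  }
  tau <- stats::integrate(function(u) 1 / growth_shape(u, gp, a_val),
                          0.5, 1, rel.tol = 1e-12)$value
  tau * w_star^gp$xi
}

#' Division rate
#'
#' \eqn{K(w, w_*) = w_*^{-\xi} k(w/w_*)}: zero below the threshold
#' `xth * w_star`, divergent (returned as `Inf`) at `w = w_star`.
#'
#' @param w current cell size (vectorised).
#' @param w_star maximum cell size.
#' @param ds a [division_spec()] object (not idealised).
#' @param gp a [growth_params()] object supplying the exponent `xi`.
#' @export
division_rate <- function(w, w_star, ds, gp) {
  if (ds$idealised) {
    stop2("idealised_division",
          "idealised division has no finite rate function; it is a boundary condition")
  }
  w_star^(-gp$xi) * ds$k(w / w_star)
}

#' Daughter-size density
#'
#' \eqn{Q(w | w') = q(w/w') / w'}: probability density of a daughter size
#' `w` given a parent of size `w_parent`. Symmetric about `w_parent / 2`,
#' zero outside `((1-delta)/2, (1+delta)/2) * w_parent`, unit integral.
#'
#' @param w daughter size (vectorised).
#' @param w_parent parent size at division.
#' @param ds a [division_spec()] object.
#' @export
daughter_density <- function(w, w_parent, ds) {
  if (any(w_parent <= 0)) stop2("bad_sizes", "parent size must be positive")
  ds$q(w / w_parent) / w_parent
}

#' Mortality rate
#'
#' \eqn{M(w, w_*) = w_*^{-\xi} m(w/w_*)} for a scaling mortality shape.
#'
#' @param w current cell size (vectorised).
#' @param w_star maximum cell size.
#' @param ms a [mortality_spec()] object.
#' @param gp a [growth_params()] object supplying `xi`.
#' @export
mortality_rate <- function(w, w_star, ms, gp) {
  w_star^(-gp$xi) * ms$m(w / w_star)
}

#' Predator-prey feeding rate
#'
#' \eqn{S(w, w') = w^\nu s(w/w')} for a predator of size `w_pred` feeding
#' on a prey of size `w_prey`; homogeneous of degree `nu`.
#'
#' @param w_pred predator cell size (vectorised).
#' @param w_prey prey cell size.
#' @param ps a [predation_spec()] object.
#' @export
feeding_rate <- function(w_pred, w_prey, ps) {
  if (any(w_pred <= 0) || any(w_prey <= 0)) {
    stop2("bad_sizes", "sizes must be strictly positive")
  }
  w_pred^ps$nu * ps$s(w_pred / w_prey)
}
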