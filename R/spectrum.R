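# Community-level diagnostics: assembling community spectra from species
# profiles or simulator states, fitting the power-law exponent, the Sheldon
# biomass-per-log-bin flatness, and the profile-collapse audit.

#' Community size spectrum
#'
#' Trait-integrated number density \eqn{p_c(w) = \int p(w, w_*)\,dw_*} on
#' an absolute size grid. For a [solve_coupled_steady_state()] solution the
#' species profiles are stacked over a log-spaced assemblage (trapezoid in
#' log trait, approximating the continuum); for a [pbe_state()] the state's
#' species are summed with their trait weights.
#'
#' @param obj a `community_solution` or a `pbe_state`.
#' @param ... passed to methods.
#' @return data frame with columns `w`, `p_c`, `z_c`.
#' @export
community_spectrum <- function(obj, ...) UseMethod("community_spectrum")

#' @rdname community_spectrum
#' @param assemblage a [species_assemblage()] giving the species over which
#'   to stack (defaults to the one attached to the solution).
#' @param w_grid absolute sizes at which to evaluate the spectrum.
#' @export
community_spectrum.community_solution <- function(obj, assemblage = NULL,
                                                  w_grid = NULL, ...) {
  assemblage <- assemblage %||% obj$assemblage
  if (is.null(assemblage)) {
    stop2("bad_input", "supply a species assemblage to stack over")
  }
  ws <- assemblage$w_stars
  if (length(ws) < 2) {
    stop2("bad_input", "need at least two species for the trait integral")
  }
  w_grid <- w_grid %||% geom_seq(assemblage$w_min * 0.25,
                                 assemblage$w_max, 400)
  lw <- log(ws)
  # trapezoid weights in log trait: integral f(w*) dw* = f w* dlogw*
  wt <- numeric(length(ws))
  wt[1] <- (lw[2] - lw[1]) / 2
  wt[length(ws)] <- (lw[length(ws)] - lw[length(ws) - 1]) / 2
  if (length(ws) > 2) {
    wt[2:(length(ws) - 1)] <- (lw[3:length(ws)] - lw[1:(length(ws) - 2)]) / 2
  }
  ab <- species_abundances(obj, ws)
  gp <- obj$gp
  if (obj$division == "ideal") {
    gz <- zoo_growth_view(obj$a_pz, gp)
    prof_p <- function(x) ifelse(x >= 0.5 & x <= 1,
                                 phi_profile(pmin(pmax(x, 0.5), 1),
                                             obj$mortality, gp, obj$a_hat), 0)
    prof_z <- function(x) ifelse(x >= 0.5 & x <= 1,
                                 phi_profile(pmin(pmax(x, 0.5), 1),
                                             obj$mortality, gz, obj$a_pz), 0)
  } else {
    prof_p <- function(x) psi_profile(x, profile = obj$profile_p)
    prof_z <- function(x) psi_profile(x, profile = obj$profile_z)
  }
  p_c <- numeric(length(w_grid))
  z_c <- numeric(length(w_grid))
  for (s in seq_along(ws)) {
    x <- w_grid / ws[s]
    inside <- x > 0 & x <= 1
    # p(w, w*) = p_norm(w*) * profile(w / w*); dw* weight = w* dlog
    p_c[inside] <- p_c[inside] +
      ab$p_norm[s] * prof_p(x[inside]) * ws[s] * wt[s]
    z_c[inside] <- z_c[inside] +
      ab$z_norm[s] * prof_z(x[inside]) * ws[s] * wt[s]
  }
  out <- data.frame(w = w_grid, p_c = p_c, z_c = z_c)
  attr(out, "gamma") <- obj$gamma
  attr(out, "assemblage") <- assemblage
  class(out) <- c("community_spectrum", class(out))
  out
}

#' @rdname community_spectrum
#' @param config the [pbe_config()] the state was built with.
#' @export
community_spectrum.pbe_state <- function(obj, config, w_grid = NULL, ...) {
  all_w <- c(obj$w_stars, obj$zw_stars)
  w_grid <- w_grid %||% geom_seq(min(all_w) * min(config$x),
                                 max(all_w), 400)
  p_c <- numeric(length(w_grid))
  z_c <- numeric(length(w_grid))
  stack <- function(acc, ws, dens, wts) {
    for (s in seq_along(ws)) {
      x <- w_grid / ws[s]
      inside <- x >= min(config$x) & x <= 1
      d <- stats::approx(config$x, dens[, s], xout = x[inside],
                         yleft = 0, yright = 0, rule = 2)$y
      # density per absolute size: p(w) = (density per x) / w*
      acc[inside] <- acc[inside] + wts[s] * d / ws[s]
    }
    acc
  }
  if (length(obj$w_stars)) {
    p_c <- stack(p_c, obj$w_stars, obj$p, obj$w_weights)
  }
  if (length(obj$zw_stars)) {
    z_c <- stack(z_c, obj$zw_stars, obj$z, obj$zw_weights)
  }
  out <- data.frame(w = w_grid, p_c = p_c, z_c = z_c)
  class(out) <- c("community_spectrum", class(out))
  out
}

#' Fit the community spectrum exponent
#'
#' Least-squares slope of `log(density)` against `log(w)` inside a fit
#' window, sign-flipped so an exact power law \eqn{w^{-\gamma}} returns
#' \eqn{\gamma}. One decade at each end of the assemblage range should be
#' excluded (finite size bounds truncate the ideal power law).
#'
#' @param tab a `community_spectrum` data frame (or any with `w` and a
#'   density column).
#' @param window `c(lo, hi)` absolute-size window for the fit.
#' @param column which density to fit: `"total"` (p_c + z_c), `"p_c"` or
#'   `"z_c"`.
#' @return list with `gamma_hat`, `residual_sd`, `n_points`, `window`.
#' @export
fit_exponent <- function(tab, window = NULL, column = "total") {
  dens <- switch(column,
                 total = tab$p_c + tab$z_c,
                 p_c = tab$p_c,
                 z_c = tab$z_c,
                 stop2("bad_input", "unknown density column"))
  window <- window %||% range(tab$w)
  keep <- tab$w >= window[1] & tab$w <= window[2]
  if (sum(keep) < 10) {
    stop2("bad_fit_window", "need at least 10 grid points in the window")
  }
  if (any(dens[keep] <= 0)) {
    stop2("bad_fit_window", "nonpositive densities inside the fit window")
  }
  fit <- stats::lm(log(dens[keep]) ~ log(tab$w[keep]))
  list(gamma_hat = -unname(stats::coef(fit)[2]),
       residual_sd = stats::sd(stats::residuals(fit)),
       n_points = sum(keep), window = window)
}

#' Sheldon flatness of the biomass spectrum
#'
#' Aggregates biomass per logarithmic size bin,
#' \eqn{B_{bin} = \int_{bin} w\,(p_c + z_c)\,dw}, and returns the maximal
#' relative deviation `max/min - 1` across bins. For an exact
#' \eqn{w^{-2}} spectrum every log bin carries the same biomass and the
#' deviation vanishes.
#'
#' @param tab a `community_spectrum` data frame.
#' @param window absolute-size window to aggregate over.
#' @param bins_per_decade number of logarithmic bins per decade.
#' @return list with `deviation`, `bins` (data frame).
#' @export
sheldon_flatness <- function(tab, window = NULL, bins_per_decade = 8) {
  window <- window %||% range(tab$w)
  keep <- tab$w >= window[1] & tab$w <= window[2]
  w <- tab$w[keep]
  dens <- tab$p_c[keep] + tab$z_c[keep]
  edges <- 10^seq(log10(window[1]), log10(window[2]),
                  by = 1 / bins_per_decade)
  if (length(edges) < 3) stop2("bad_input", "window narrower than two bins")
  # biomass per log size: int w * dens dw = int w^2 * dens dlog(w);
  # bins are integrated between their exact edges (values at the edges by
  # interpolation), so bin values do not depend on grid alignment
  u <- log(w)
  bio_log <- w^2 * dens
  bins <- vapply(seq_len(length(edges) - 1), function(b) {
    ulo <- log(edges[b]); uhi <- log(edges[b + 1])
    sel <- u > ulo & u < uhi
    if (sum(sel) < 2) return(NA_real_)
    uu <- c(ulo, u[sel], uhi)
    yy <- c(stats::approx(u, bio_log, ulo, rule = 2)$y, bio_log[sel],
            stats::approx(u, bio_log, uhi, rule = 2)$y)
    trap(uu, yy) / (uhi - ulo)
  }, numeric(1))
  if (anyNA(bins)) {
    stop2("empty_bins", "empty logarithmic bins inside the window")
  }
  list(deviation = max(bins) / min(bins) - 1,
       bins = data.frame(w_lo = edges[-length(edges)], w_hi = edges[-1],
                         biomass_per_logbin = bins))
}

#' Collapse of within-species profiles
#'
#' The steady state is scale-invariant:
#' \eqn{p(w, w_*) = w_*^{-\gamma-1} f_p(w/w_*)} for one universal scaling
#' function. Rescaling every species' profile by \eqn{w_*^{\gamma+1}} and
#' overlaying on relative size must collapse them onto a single curve;
#' the residual is the maximal pairwise L1 distance of the rescaled
#' profiles (each normalised by its own L1 mass).
#'
#' @param profiles list with one entry per species: `w_star`, `w`
#'   (absolute sizes), `dens` (number density in `w`).
#' @param gamma spectrum exponent used for the rescaling.
#' @param n_grid points of the common relative-size grid.
#' @return list with `residual` and the overlay data frame `overlay`.
#' @export
collapse_profiles <- function(profiles, gamma, n_grid = 200) {
  if (length(profiles) == 0) stop2("bad_input", "no profiles supplied")
  xs <- seq(0.05, 1, length.out = n_grid)
  curves <- lapply(profiles, function(pr) {
    x <- pr$w / pr$w_star
    f <- pr$dens * pr$w_star^(gamma + 1)
    stats::approx(x, f, xout = xs, yleft = 0, yright = 0, rule = 2)$y
  })
  if (length(curves) == 1) {
    return(list(residual = 0,
                overlay = data.frame(x = xs, f = curves[[1]])))
  }
  resid <- 0
  for (i in seq_along(curves)) {
    mi <- trap(xs, abs(curves[[i]]))
    for (j in seq_len(i - 1)) {
      mj <- trap(xs, abs(curves[[j]]))
      d <- trap(xs, abs(curves[[i]] / mi - curves[[j]] / mj))
      resid <- max(resid, d)
    }
  }
  overlay <- data.frame(x = xs)
  for (i in seq_along(curves)) overlay[[paste0("f", i)]] <- curves[[i]]
  list(residual = resid, overlay = overlay)
}
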