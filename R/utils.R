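# Internal numerical helpers shared across modules.

# 16-point Gauss-Legendre nodes/weights on [-1, 1]
.gl16 <- local({
  g <- list(
    x = c(-0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
          -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
          -0.2816035507792589, -0.0950125098376374, 0.0950125098376374,
          0.2816035507792589, 0.4580167776572274, 0.6178762444026438,
          0.7554044083550030, 0.8656312023878318, 0.9445750230732326,
          0.9894009349916499),
    w = c(0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
          0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
          0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
          0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
          0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
          0.0271524594117541)
  )
  g
})

# Vectorised fixed-order quadrature of f over each panel [lo_i, hi_i].
panel_quad <- function(f, lo, hi) {
  stopifnot(length(lo) == length(hi))
  half <- (hi - lo) / 2
  mid <- (lo + hi) / 2
  out <- numeric(length(lo))
  for (j in seq_along(.gl16$x)) {
    out <- out + .gl16$w[j] * f(mid + half * .gl16$x[j])
  }
  out * half
}

# Cumulative integral of f from grid[1] along the grid nodes.
cum_quad <- function(f, grid) {
  n <- length(grid)
  panels <- panel_quad(f, grid[-n], grid[-1])
  c(0, cumsum(panels))
}

# Cumulative integral of tabulated values by local cubic (4-point Lagrange)
# panel integration; order h^4, purely local so exactly scale-covariant.
cum_quad_table <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  if (n < 4) return(cumtrap(x, y))
  for (i in seq_len(n - 1)) {
    j <- if (i == 1) 1:4 else if (i >= n - 1) (n - 3):n else (i - 1):(i + 2)
    xi <- x[j]; yi <- y[j]
    # integrate the Lagrange cubic through (xi, yi) over [x[i], x[i+1]]
    val <- 0
    for (m in 1:4) {
      others <- xi[-m]
      # polynomial prod_{o}(t - o) / prod_{o}(xi[m] - o), integrated
      denom <- prod(xi[m] - others)
      c0 <- -prod(others)
      c1 <- others[1] * others[2] + others[1] * others[3] +
        others[2] * others[3]
      c2 <- -sum(others)
      F <- function(t) c0 * t + c1 * t^2 / 2 + c2 * t^3 / 3 + t^4 / 4
      val <- val + yi[m] / denom * (F(x[i + 1]) - F(x[i]))
    }
    out[i + 1] <- out[i] + val
  }
  out
}

# Cumulative trapezoid on tabulated values.
cumtrap <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-n] + y[-1]) / 2 * diff(x)))
}

trap <- function(x, y) {
  n <- length(x)
  sum((y[-n] + y[-1]) / 2 * diff(x))
}

# Bisection with distinct conditions for bracket failure vs convergence.
# f must be finite at both ends; monotonicity is the caller's concern.
bisect_root <- function(f, lo, hi, tol = 1e-12, max_iter = 200L, ...) {
  flo <- f(lo, ...)
  fhi <- f(hi, ...)
  if (!is.finite(flo) || !is.finite(fhi)) {
    stop2("bisect_nonfinite", "objective not finite at bracket endpoints")
  }
  if (flo == 0) return(list(root = lo, f_root = 0, iterations = 0L))
  if (fhi == 0) return(list(root = hi, f_root = 0, iterations = 0L))
  if (sign(flo) == sign(fhi)) {
    stop2("bisect_no_bracket",
          sprintf("no sign change on [%g, %g] (f: %g, %g)", lo, hi, flo, fhi))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- f(mid, ...)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid; fhi <- fm
    }
    if ((hi - lo) <= tol * max(abs(hi), 1) || it >= max_iter) {
      return(list(root = (lo + hi) / 2, f_root = fm, iterations = it))
    }
  }
}

# classed conditions so callers can distinguish failure modes
stop2 <- function(class, message, ...) {
  stop(structure(class = c(class, "cellspectrum_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

geom_seq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
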