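---
title: "Methods: a trait-based plankton size-spectrum model with explicit cell division"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a trait-based plankton size-spectrum model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellspectrum)
```

## The model

`cellspectrum` implements a size- and species-resolved model of unicellular
plankton. A cell is described by its current size $w$ and by the trait
$w_*$, the maximum size a cell of its species can reach; sizes are
dimensionless (measured against an arbitrary reference size), so that the
allometric exponents act on pure numbers.

**Growth.** Cells grow by von Bertalanffy uptake-minus-metabolism,
constrained by the empirical allometry of the doubling period
$T(w_*) = \tau\, w_*^{\xi}$:
$$\frac{dw}{dt} = G_p(w, w_*) = w_*^{1-\xi}\!\left[a\!\left(\tfrac{w}{w_*}\right)^{\!\alpha} - b\!\left(\tfrac{w}{w_*}\right)^{\!\beta}\right],
\qquad \alpha < \beta,$$
which is homogeneous of degree $1-\xi$. Under nutrient limitation the
uptake coefficient follows the Monod law $a(N) = a_\infty N/(r+N)$, and
the nutrient pool is a chemostat,
$dN/dt = \varrho_0(1 - N/N_0) - \sigma(N, p)$, with consumption
$\sigma$ proportional to the community's total uptake and a yield
$\theta$.

**Division** follows sloppy size control: a cell may divide once its
relative size $x = w/w_*$ exceeds a threshold $x_{th}$, at rate
$K(w,w_*) = w_*^{-\xi} k(x)$, and splits into two daughters whose size
fractions are drawn from a symmetric density $q$ on
$((1-\delta)/2, (1+\delta)/2)$. The rate shape must satisfy
$\int^1 k = \infty$ so that no cell outgrows $w_*$; this is probed
numerically when a `division_spec()` is built, rather than assumed from
the formula. The idealised flavour (`idealised = TRUE`) replaces both
kernels by a deterministic split at exactly $w_*$ into two halves.

**Death** is $M(w,w_*) = w_*^{-\xi} m(x)$. The degree $-\xi$ is not a
convenience: it is the unique scaling under which *all* species can
coexist at one nutrient level, and the predation module shows it emerges
mechanically from feeding on a power-law community.

### Steady states

For the idealised process the within-species profile is the closed form
$$\phi(x) = \frac{a(N)-b}{a(N)x^\alpha - b x^\beta}
\exp\!\left\{\int_x^1 \frac{m(y)}{a(N)y^\alpha - b y^\beta}\,dy\right\},
\qquad x \in [\tfrac12, 1],$$
and the steady nutrient is pinned by
$\int_{1/2}^{1} m/(a(N)x^\alpha - bx^\beta)\,dx = \log 2$ — the condition
that the flux of dividing cells, doubled in number, matches the flux of
newborns. `solve_nutrient_idealised()` offers two routes: bisection on
this integral, and an independent shooting route that integrates the
steady transport ODE downward with `deSolve` and imposes the
flux-doubling boundary condition directly, never touching the closed
form. The two agreeing is one of the package's structural checks.

For sloppy division the steady state is assembled from a survival factor
$e(x)$ (attrition of large cells by division and death), a renewal
density $h(x)$ (production of daughters, with the factor 2 and the $1/y$
weight of the two-daughter bookkeeping), and the cumulative renewal
integral $\Theta(x) = \int_0^x h/e$. The boundary condition
$\int_0^{(1+\delta)/2} h/e\,dx = 1$ fixes the nutrient, and
$$\psi(x) = \frac{g\big(\tfrac{1+\delta}{2}\big)}{g(x)}\, e(x)\, \Theta(x),
\qquad g(x) = a(N)x^\alpha - bx^\beta .$$
Where the model is written down twice in slightly different forms in the
course of the derivation, the package uses throughout the form that
conserves daughter number (two per division) and reduces to the
idealised limit; $\Theta$ is computed as the cumulative integral from 0,
and its consistency with the complementary form ($\Theta((1+\delta)/2) = 1$)
is asserted at the solved root.

The population-growth eigenvalue $\Lambda$ of a nutrient-rich,
mortality-free culture solves the same renewal condition with $m$
replaced by $\Lambda$ itself. `solve_growth_eigenvalue()` performs all
quadratures in absolute size coordinates for each $w_*$ — no scaling
shortcut — and recovers $\Lambda = \ell\, w_*^{-\xi}$ with
species-independent $\ell$ to within $10^{-8}$ (absolute), which is the
dynamic fingerprint of the doubling-period allometry.

### Predation and the coupled community

Zooplankton feed on smaller cells at rate $S(w, w') = w^\nu s(w/w')$.
Inserting trial power-law community spectra $w^{-g}$ into the direct
predation integrals shows (and `scaling_theorem_check()` verifies
numerically, in both directions) that the emergent death rate is
homogeneous of degree $-\xi$ and the zooplankton growth rate of degree
$1-\xi$ **iff** $g = \gamma = 1 + \nu + \xi$. With $\nu = 0.85$ and
$\xi = 0.15$, $\gamma = 2$: biomass per logarithmic size interval is
flat — the Sheldon spectrum. Coexistence of a continuum of species and
the power-law community spectrum are thus the same phenomenon seen from
two sides, and the package's community diagnostics (`fit_exponent()`,
`sheldon_flatness()`, `collapse_profiles()`) probe exactly that
equivalence.

The coupled steady state is closed by four relations: the total
mortality shape $m(x) = m_b(x) + z_0 x^{-\xi}\!\int y^{-\xi-1}s(y)dy$;
the phytoplankton boundary condition, which fixes $\hat N$ (hatted
quantities are per unit of the renormalisation factor
$\Xi = \int w_*^{1-\xi-\gamma}dw_*$, which diverges for an unbounded
community — the chemostat parameters handed to
`solve_coupled_steady_state()` are these renormalised values, and
finite-assemblage results multiply back by the finite $\Xi$); the
chemostat balance, which yields $p_0$; and the zooplankton boundary
condition, which yields $a_{pz}$ and hence
$z_0 = a_{pz}/(\varepsilon \int x^{\gamma-3}s\,dx) - p_0$.

**Why the closing equation is solved by bisection.** The natural
fixed-point map $z_0 \mapsto z_0'$ is *not* a contraction for realistic
parameters: raising $z_0$ raises mortality, which raises both the
required nutrient (depressing $p_0$) and the zooplankton uptake solving
its boundary condition, so the map slope at the root exceeds one and
damped iteration diverges. The default solver therefore brackets the
scalar residual $z_0'(z_0) - z_0$ over the feasible range of $z_0$
(bounded above by nutrient saturation and chemostat capacity) and
bisects; the damped iteration is retained as `solver = "fixed_point"`
with an iteration trace for parameter sets where it does contract.
Infeasibility is reported, not clipped: either no nonnegative $z_0$
balances the system (e.g. at vanishing conversion efficiency), or the
zooplankton pressure runs away before the community balances.

## Numerical choices

* **Quadrature.** Point evaluations (`phi_profile()`,
  `survival_factor_e()`, `renewal_density_h()`) use adaptive quadrature
  with relative tolerance $10^{-11}$. Profile grids use 16-point
  Gauss–Legendre panels between nodes; cumulative integrals of tabulated
  smooth ratios use local 4-point Lagrange panels, which are strictly
  local and therefore exactly scale-covariant — a property the global
  natural spline lacks at the $10^{-7}$ level, enough to mask the
  species-independence of $\ell$.
* **The division pole.** $k(x) = 4(x-x_{th})^2/(1-x)$ diverges at the
  maximum size, so $e(1) = 0$ exactly (set, never computed, to avoid
  NaN from underflow) and the grid carries nodes that approach $x = 1$
  geometrically (the substitution $x = 1 - e^{-u}$), where the
  cumulative hazard is interpolated against $\log(1 - x)$ — in that
  coordinate it is asymptotically linear. Integrands with the kink at
  $x_{th}$ are always split there; an adaptive integrator pushed across
  the kink silently loses about two digits, which is the dominant
  failure mode we found while validating against an independent
  implementation.
* **Steady-state grids.** 512 log-spaced points (plus pole refinement)
  for single-guild solves; 192 for the inner loops of the coupled solve
  and 128 in the heaviest test, where the root is still reproduced to
  $10^{-6}$.
* **Simulator.** Conservative first-order upwind advection on a shared
  geometric relative-size grid of 256 cells (default), explicit Euler
  with $dt = 0.5\,\min(\Delta x/v,\ 1/\max(K+M))$; the nutrient is
  stepped with the same $dt$. Division is a precomputed sparse matrix:
  each parent cell's daughter allocation integrates $Q(w|w')$ over the
  grid cells and is then moment-corrected (a rank-2 least-norm
  adjustment) so every division yields *exactly* two daughters carrying
  *exactly* the parent biomass — the discrete counterpart of the unit
  integral and symmetry of $q$. Flux through the upper boundary is
  treated as certain division (the rate integral diverges there) and
  re-enters as daughters of a maximal parent, so nothing leaks.
  Idealised division is a reinjection boundary condition (top flux
  doubled into the half-size cell), not a numerical delta function.
* **First-order bias and Richardson.** The scheme's error is $O(\Delta
  x)$ (measured: the growth-rate bias halves per grid doubling), so
  dynamic estimates that are compared against quadrature values — the
  exponential growth rate in particular — are Richardson-extrapolated
  over two grids. The raw 256-cell estimate is biased by about 0.6%;
  the extrapolated one agrees with the renewal eigenvalue to about
  $10^{-4}$.
* **Trait integrals.** Finite assemblages are log-spaced with half-step
  end insets (`make_assemblage()`) and stacked by trapezoid in log
  trait. For the sloppy-division profile (continuous in $x$) 64 species
  per decade reproduce the continuum power-law spectrum to $10^{-3}$
  away from the edges; the idealised profile has a genuine jump at
  $x = 1$, so its stacked spectrum converges only at first order in the
  species spacing — fits of the exponent are still accurate, pointwise
  values are not. Fit windows exclude one decade at each end of the
  assemblage range, where the finite bounds truncate the power law.

## What the simulator emulates — and what it does not

The simulator is the package's independent dynamic oracle: it evolves
the same kernels the analytic solvers integrate, from arbitrary initial
densities (default: a Gaussian cohort at relative size 0.5, width 0.05 —
a conventional choice, not model content), optionally coupled to the
chemostat. Passing its checks shows that the analytic steady states are
genuine attractors of the discretised dynamics under the study
conditions: single guild, species-independent kernels, constant
chemostat forcing. It does not demonstrate anything about seasonally
forced resources, density-dependent predation (known to be needed to
stabilise the full predator-prey dynamics; deliberately out of scope
here), mixotrophy, or assemblages sparse enough that the power-law
mortality approximation breaks down. The generation-tagged division-wave
audit (`division_wave_ratio()`) freezes daughters at birth: following
them further necessarily mixes generations, because the fastest
daughters reach the division threshold before the slowest parents have
divided — there is no clean two-generation plateau in the untagged
dynamics, only a trough near $2.003\times$ the initial number.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| $a_\infty$, $b$ | 0.7, 0.5 | saturated uptake and metabolic coefficients (per unit time; absolute time units are free — only $\tau$ is constrained) |
| $\alpha$, $\beta$ | 0.85, 1 | uptake and metabolism allometric exponents |
| $\xi$ | 0.15 | doubling-period exponent |
| $r$ | 1 | Monod half-saturation (nutrient units) |
| $x_{th}$, $\delta$ | 0.7, 0.2 | division threshold fraction; daughter-size half-width ($q$ uniform on $[0.4, 0.6]$) |
| $m_0$ | 0.1 | constant background mortality |
| $\varrho_0$, $N_0$, $\theta$ | 1, 10, 1 | chemostat replenishment, capacity, yield (chosen once; echoed in every output header) |
| $\nu$, $\varepsilon$ | 0.85, 0.3 | foraging exponent (so $\gamma = 2$), conversion efficiency |
| preference kernel | log-normal, mode 100, log-width 1, amplitude 1 | predator:prey size-ratio preference; both required moments finite |

The growth/division constants and $\xi$ are the model's canonical
illustration values; the chemostat and kernel-amplitude values are free
choices fixed once for reproducibility (the model constrains only
combinations of them), made so that the coupled community supports a
positive zooplankton spectrum ($z_0 > 0$) — at these defaults the
idealised coupled solution is $p_0 \approx 0.77$, $z_0 \approx 0.013$,
$\hat N \approx 5.25$.

## Worked example

```{r example, eval = FALSE}
gp <- growth_params()            # a=0.7, b=0.5, alpha=0.85, beta=1, xi=0.15
ds <- division_spec()            # threshold 0.7, daughters uniform [0.4,0.6]
ms <- mortality_spec(0.1)

# steady nutrient and profile for the sloppy-division model
sol <- solve_nutrient_general(ds, ms, gp)
sol$N_star                       # ~4.013 at the canonical chemostat (r = 1)

# the same nutrient found dynamically
cfg <- pbe_config(gp, ds, ms = ms, chem = chemostat_params())
sim <- pbe_simulate(pbe_state(cfg, w_stars = 1, N = 5, number = 2), 400, cfg)
tail(sim$series, 1)              # settles at N ~ 3.994 on the 256-cell grid

# coupled phyto-zoo community and its Sheldon spectrum
sol_c <- solve_coupled_steady_state(predation_spec(),
                                    division_spec(idealised = TRUE),
                                    gp, chemostat_params(),
                                    assemblage = make_assemblage(192, 1, 1000))
fit_exponent(community_spectrum(sol_c), window = c(10, 100))$gamma_hat  # ~2.00
```

## Known limitations

* Stability of the coupled steady state is not analysed; the simulator
  integrates single-guild dynamics (optionally with fixed zooplankton
  uptake) and does not implement the fully dynamic predation feedback.
* The first-order simulator needs Richardson extrapolation for
  quantitative rate estimates; profile shapes are accurate to about 1%
  at 512 cells.
* The renormalised chemostat is implemented as the same functional form
  with per-unit-$\Xi$ parameters; if the resource dynamics renormalised
  differently, the coupled abundances (but not the exponent structure)
  would shift.
* The idealised flavour is periodic rather than convergent by
  construction; its simulator runs are meaningful over whole doubling
  periods only.
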