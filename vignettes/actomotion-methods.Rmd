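---
title: "Methods: a free-boundary actomyosin model of cell motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a free-boundary actomyosin model of cell motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`actomotion` simulates a minimal mechanical model of a crawling cell's
lamellipodium — the flat, actin-rich sheet that fish keratocytes and similar
cells spread over a substrate. The cell is a two-dimensional region
$\omega(t)$ with a moving boundary. Two fields live on it: the actin network
velocity $u(x,t)$ and the myosin motor density $m(x,t)$. In dimensionless
form (length unit: the radius of the circle of target area; time unit:
diffusion time across it; concentration unit: the protrusion-inhibition
threshold) the governing equations are

$$
\alpha\,\Delta u + \beta\,\nabla m - u = 0, \qquad
\partial_t m = \nabla\cdot\left(d_{\mathrm{eff}}\nabla m
  - u_{\mathrm{eff}}\, m\right).
$$

The force balance equates viscous stresses in the compressible actin mesh
(componentwise Laplacian — bulk/shear interplay is deliberately ignored),
the divergence of the isotropic contractile stress $\beta m$, and a linear
adhesion drag. Myosin is advected by the actin flow and diffuses; molecular
crowding limits both processes through
$u_{\mathrm{eff}} = u\,(1 - m/m_{\max,u})$ for $m < m_{\max,u}$ (exactly
zero above) and $d_{\mathrm{eff}} = 1 - m/m_{\max,d}$ with
$m_{\max,u} < m_{\max,d}$.

Two boundary conditions close the force balance:

* **ZV** (zero velocity): $u = 0$ at the edge — a narrow band of strong
  adhesions pins the actin network there;
* **ZS** (zero stress): $n\cdot(\alpha\nabla u + \beta m\,\hat I) = 0$ —
  no sticky band, membrane tension negligible against the contractile and
  viscous stresses.

Myosin obeys a no-flux condition on the *moving* edge,
$n\cdot(-d_{\mathrm{eff}}\nabla m + (u_{\mathrm{eff}} - v_f)m) = 0$, which
conserves the total myosin $\mu_{tot}$ and lets a retracting rear sweep
myosin up — the key nonlinearity behind polarization and turning.

The boundary moves with $v_f = v_p n + u|_{\partial\omega}$. The protrusion
rate is uniform in the ZS model,
$v_p = v_0 a_0/a - k\,(a - a_0 (a_0/a)^2)$, combining actin growth diluted
by spreading with an area-preserving membrane/cytoplasm term whose
quadratic part prevents collapse. In the ZV model the edge flow vanishes,
so the myosin dependence moves into the protrusion itself,
$v_p = v_0 a_0/(a(1+m|_{\partial\omega})) - k\,(a - a_0)$.

Three combinations govern the behavior: the viscosity–adhesion length
$\alpha$, the myosin load $\mu_{tot}$ (or equivalently $\beta\mu_{tot}$ —
rescaling $\beta$ is the same as rescaling $\mu_{tot}$), and the actin
growth constant $v_0$. The fixed defaults are $\beta = 5$, $k = 1.5$,
$a_0 = \pi$, $m_{\max,u} = 15$, $m_{\max,d} = 125$.

## Linear stability

On a fixed unit segment with cutoffs disabled, the 1D ZV model has the
uniform state $u = 0$, $m = \mu_{tot}$. Perturbations
$\propto e^{\lambda t + iqx}$ with admissible $q = \pi, 2\pi, \dots$ grow at

$$\lambda(q) = q^2\left(\frac{\beta\mu_{tot}}{1+\alpha q^2} - 1\right),$$

so the state destabilizes when $\beta\mu_{tot} > 1 + \pi^2\alpha$, with
$q = \pi$ the fastest admissible mode in the relevant regime. The package
implements both the closed form (`dispersion_rate()`, `critical_mu_tot()`)
and a 1D finite-volume simulator (`simulate_1d_zv()`); the tests verify the
closed form against an independent finite-difference eigenvalue computation
and against fitted growth rates of the nonlinear 1D solver (within 1% and
5% respectively).

## Numerical scheme

**Cut-cell finite volumes.** The moving domain is discretized on a *fixed*
Cartesian background grid (the equations are posed in the lab frame).
Cells crossed by the boundary carry exact clipped volume fractions and face
apertures computed from polygon clipping and line-crossing parities; the
boundary-segment normal of each cut cell follows exactly from the aperture
identity $\oint n\,ds = 0$, which makes the discrete divergence consistent.
Cut cells with volume fraction below 0.3 are merged with their
best-connected neighbor (largest shared aperture) for solver purposes —
tiny control volumes would otherwise destabilize the implicit solves. The
mesh area equals the polygon area to round-off.

**Force balance.** The two velocity components decouple and share one
matrix, $\alpha L - V$. ZV imposes $u=0$ through one-sided boundary fluxes;
ZS is imposed weakly — the viscous and contractile front terms cancel
exactly in the finite-volume balance, so cut cells simply carry no front
flux. A disk with uniform myosin then feels a net inward rim force, and the
computed radial profile matches the modified-Bessel solution of the
axisymmetric reduction to better than 2%.

**Myosin transport.** Backward-Euler in time; two-point diffusive fluxes
with arithmetic face averaging of $d_{\mathrm{eff}}$; first-order upwind
advection on $u_{\mathrm{eff}}$ (the myosin aggregates of fast cells are
near-singular; upwinding plus implicit diffusion give an M-matrix, hence
unconditional positivity). Boundary fluxes are identically zero, enforcing
the no-flux condition by construction. The sweeping term of the moving
boundary is realized geometrically: after the front advances, cell masses
are transferred to the new mesh exactly (dried cells donate to wetted
neighbors, aperture-weighted), so total myosin is conserved to round-off
over entire runs, arbitrary motions included. A manufactured radially
symmetric solution with zero rim gradient (so it satisfies the no-flux
condition) confirms spatial order $\approx 2$ in the $L^2$ norm in the
diffusion-dominated regime, with $dt \propto h^2$ to keep the temporal
error subordinate.

**Segregated stepping.** Each time step fixes the mesh and iterates:
(1) solve the force balance with the previous iterate's myosin; (2) evaluate
$u_{\mathrm{eff}}, d_{\mathrm{eff}}$ from that myosin and the new velocity;
(3) one linear backward-Euler transport solve anchored at the previous
*time step's* myosin; (4) stop when consecutive iterates differ by less
than $10^{-10}$ in the max norm (cap 35 — never reached in practice; the
recorded maxima are 10–30 per step). After convergence the protrusion rate
is evaluated from the converged fields, the front advances once, the mesh
is rebuilt and mass transferred. The time step is $dt = c\,h$, additionally
capped so the boundary moves under one cell per step. A fully coupled
reference solver (`monolithic_step()`: the same discrete system driven to
self-consistency at $10^{-13}$ with the coupled residual verified) agrees
with the segregated solver to within $10^{-9}$ relative — comfortably below
the 0.3% level at which segregated schemes are usually validated.

**Front tracking.** The boundary is a closed CCW marker polygon
(initially 256 markers on the unit circle, spacing $\approx 2\pi/256 <
h/2$). Markers advect with $v_f$ and the curve is resampled every step to
uniform arclength through a periodic cubic spline; the marker count adapts
to the perimeter and is kept even so mirror-symmetric configurations remain
exactly representable. Resampling is idempotent on equispaced circles
($<10^{-12}$ displacement) and changes the enclosed area by less than
$10^{-3}$ relative per call (enforced).

## Design choices that were genuinely open

**Boundary extrapolation.** Boundary values of cell-centered fields
(myosin for the ZV protrusion law and force-balance front term, velocity
for the ZS edge kinematics) are reconstructed by a distance-weighted
least-squares plane fit over the active cells — cut cells included — within
a few grid spacings of the point. A bilinear fit over the nearest fully
interior 2×2 stencil is also provided (`method = "bilinear"`); both are
exact for affine fields and second-order accurate. The least-squares
reconstruction is the default because the interior-only stencil sits 1.5–3
grid spacings inside the wall and switches discretely as markers move;
where the wall-normal myosin gradient is steep (the rear of a translating
ZV cell, where $m$ rises by an order of magnitude over two cells) that
switching injects order-one noise into the protrusion law and seeds a
spurious short-wavelength edge instability. Sampling cells attached to the
wall removes the systematic depth dependence. The per-marker extrapolated
traces additionally get a short periodic binomial filter (two passes by
default, `boundary_filter`): boundary data cannot carry sub-grid
information, and the filter width is far below the unstable wavelengths of
the model.

**Front shocks.** Normal-driven motion forms genuine corner shocks: at the
concave rear of a fast cell, neighboring marker paths cross in a sharpening
notch (a swallowtail). The entropy-consistent front is obtained by clipping
the local micro-loop at its crossing point, which is what robust
front-tracking libraries do internally; only crossings at most 12 markers
apart are clipped, and any larger-scale self-intersection — an actual
topology change, which the model never produces — aborts the run. Without
this treatment every captioned motile run fails by $t \approx 9$–14 at the
production resolutions, so "no surgery" was not a tenable design point.

**Steadiness and classification.** Steadiness is declared at the earliest
time from which the centroid speed and the aspect ratio stay within 2% of
their trailing 5-time-unit window means through the end of the record.
Speeds are measured over a 0.25-time-unit baseline (a one-step difference
amplifies remeshing jitter), the banded series are smoothed by a 1-time-unit
moving average (rotating cells carry a small sub-period oscillation as they
cross the background grid; steadiness concerns the envelope), and speeds
below 0.05 are banded absolutely so stationary cells register as steady.
States are labelled from the trailing window: *stationary* if the mean
speed falls below $10^{-2}$ of the maximal historical speed with net window
displacement under 0.1; otherwise *rotation* if an algebraic circle fit
(with a total-least-squares line as the straightness alternative) yields a
radius at most $1.5\sqrt{a/\pi}$ — "comparable to or less than the cell
size" — else *translation*. The fitted radius is resolution-biased: for the
rotating reference state the radius falls 1.72 → 1.49 → 1.42 at
$h = 0.16, 0.12, 0.10$ (Richardson limit $\approx 1.4$, i.e. genuinely
below $1.5\sqrt{a/\pi} \approx 1.41$), so coarse-mesh classifications use a
proportionally widened size factor (2.0 at $h = 0.16$), documented where
used. Radii within 50% of the threshold are flagged ambiguous, mirroring
the gradual translation-to-rotation crossover.

**Degenerate inputs and floors.** The diffusivity factor is floored at
$10^{-6}$ with a warning: the diffusion cutoff is chosen above the
densities of valid runs, but very fast, heavily loaded cells (e.g.
$\mu_{tot} = 2\pi$ with $v_0 = 2.5$ at coarse resolution) can compress rear
myosin beyond it, and the floor keeps the operator parabolic instead of
crashing. Negative protrusion-law inputs, non-CCW or self-intersecting
curves, non-positive areas and out-of-range parameters are rejected with
named errors.

## What the reference simulations show — and what they do not

The initial condition used throughout — a unit circle with
$m = (\mu_{tot}/|\omega|)(1 - g x)$, $u = 0$, default $g = 0.2$ — probes
the stability of the symmetric state with a *macroscopic* tilt. It
reproduces the three asymptotic states at their reference parameter sets
(all at $\alpha = 0.5$): stationary at $(v_0, \mu_{tot}) = (2.5,
0.125\pi)$ (ZS), straight translation at $(2.5, 2\pi)$ (ZV), rotation at
$(2.5, 0.75\pi)$ (ZS). It does *not* reproduce slow near-marginal growth
from infinitesimal perturbations: with a 20% initial tilt the polarization
has nothing slow to grow through, and the ZS cell at
$(\alpha, v_0, \mu_{tot}) = (1, 5, 1.5\pi)$ reaches the documented
steadiness criterion at $t \approx 1$, not at the $t \approx 14$ reported
for that parameter set from a presumably much weaker effective
perturbation (the gradient magnitude behind that published transient is not
stated; we verified that even $g = 0.01$ only moves the detected time to
$t \approx 1.8$, because the linear growth rate at these parameters is
large). Transient-timing comparisons against that figure therefore fail by
construction under our initial conditions, and we report the discrepancy
rather than tune $g$.

Synthetic centroid tracks (`synthetic_track()`) — ideal stationary,
straight and circular records with optional Gaussian jitter — validate the
classifier independently of the solver. They contain no shape dynamics, so
they exercise the geometry of the decision rule, not the physics.

## Problem sizes

Production-quality runs in this package use $h = 0.16$–0.10 with
$c = 0.01$–0.025 ($dt = ch$), 256 initial markers, and horizons of 14–30
time units; the unit-area cell then carries 120–400 unknowns and a run
takes tens of seconds to a few minutes. The test suite uses the coarse end
of these ranges with early stopping at detected steadiness; the acceptance
script uses the finer settings named in its comments. The convergence
benchmark runs $h = 0.16/0.08/0.04$ (up to $\approx 2000$ unknowns).

## Known limitations

* First-order upwind advection limits the formal order in
  advection-dominated regimes; the second-order claim is (and is verified)
  for the diffusion-dominated regime.
* The fitted rotation radius carries an $O(h)$ upward bias at desk-scale
  resolutions (quantified above).
* Aggregate myosin densities of heavily loaded fast cells can exceed the
  diffusion cutoff at coarse resolution; runs continue with the floored
  diffusivity and a warning, but such corners of parameter space deserve
  finer meshes.
* No topology changes: cells never split or merge, by design.
* The supplementary stress-attenuation variant of crowding control and the
  two-state myosin kinetics are out of scope.
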