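---
title: "Models and numerical methods in fibrincap"
author: "fibrincap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in fibrincap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrincap)
```

`fibrincap` models how the fibrin network covering a stabilized venous
thrombus regulates the movement of proteins — above all thrombin, the
enzyme that activates platelets and drives further growth. This vignette is
the package's own account of the models it implements, the parameters that
matter, the numerical choices made, and the limits of what its tests can
show.

## The physical picture

A small wall-attached thrombus is idealised as a composite sphere: an
impermeable core of radius $R_1$ (densely packed activated platelets) under
a permeable fibrin cap extending to $R_2$, immersed in a uniform creeping
flow of speed $U$. Thrombin generated at the core surface spreads by
diffusion through the gel and by advection with the plasma filtering
through the cap. Two material properties control everything: the Darcy
permeability $k$ of the fibrin network (how much flow the cap admits) and
the hindered diffusivity $D$ of the protein in the gel.

## Gel physics

**Darcy permeability.** A clot of length $L$ and cross-section $A$ is
perfused at pressure drop $\Delta P$; the volumetric rate $Q$ is the
ordinary least-squares slope of cumulative outflow volume (mass divided by
a water density of 998 kg/m³) against time, and
$k = Q\mu L / (A\,\Delta P)$. OLS over the full series is used because the
raw measurement is a set of balance readings at arbitrary times; the slope
estimator is unbiased under additive noise, which the tests confirm to
within 2% at 5% noise.

**Volume fraction.** For a gel prepared from $m_f$ grams of desiccated
fibrinogen in $m_w + m_b$ grams of solvent,
$\varphi = 1.25\, m_f\nu_f / (m_f\nu_f + (m_w+m_b)\nu_{wb})$ with specific
volumes $\nu_f = 0.725$ and $\nu_{wb} = 1.02$ cm³/g; the prefactor corrects
for the density difference between polymerized fibrin and fibrinogen. At
4 mg/mL this gives $\varphi \approx 3.5\times10^{-3}$.

**Fiber radius.** The permeability of a three-dimensional random array of
fibres of radius $r_f$ follows the Jackson–James relation
$k = r_f^2\,\tfrac{3}{20\varphi}(-\ln\varphi - 0.931)$, valid for
$\varphi < e^{-0.931} \approx 0.39$. The package inverts it exactly
(`fiber_radius_from_permeability()`), and keeps the forward form in a
single named function so the relation could be swapped for another
fibrous-medium model without touching callers.

**Hindered diffusion.** Two models are provided. The extended Ogston
obstruction model for flexible solutes in networks of thick flexible
fibres, $D/D_0 = \exp(-\alpha\beta s\sqrt{\varphi}(1 + d_h/2r_f))$, with
solute and fiber flexibility factors $\alpha,\beta$ and step-size constant
$s$ carried per probe (thrombin: $d_h = 4.1$ nm, $\alpha = 0.1$,
$\beta = 1$, $s = 17$; Fab IgG: $d_h = 11.2$ nm, $s = 27$). And the
effective-medium model, a product of steric and hydrodynamic factors
$S = \exp(-0.84 f^{1.09})$, $f = \varphi(1+r_s/r_f)^2$ and
$H = (1 + r_s/\sqrt{k} + r_s^2/9k)^{-1}$. For fibrin permeabilities of
1–1000 µm² and nanometre-scale probes, $r_s/\sqrt{k} \ll 1$, so $H$ differs
from 1 by under 1% — hydrodynamic hindrance is negligible in this regime,
and the steric factor alone makes the effective-medium prediction milder
than the obstruction fit. Tortuosity is reported as $D_0/D_\text{gel}$.

## FRAP analysis

Recovery of fluorescence into a uniformly bleached disk of radius $w$ by
free diffusion follows the Soumpasis solution
$f(t) = e^{-2\tau_D/t}\left[I_0(2\tau_D/t) + I_1(2\tau_D/t)\right]$,
$\tau_D = w^2/4D$. The implementation evaluates the exponentially scaled
Bessel functions, so it is stable at arbitrarily small times, where
$f \sim \sqrt{2t/\pi\tau_D}$.

Raw traces are normalized as $f(t) = (I(t)-I_0)/(I_{pre}-I_0)$; the model
$M f(t;\tau_D)$ is fitted by Levenberg–Marquardt (`minpack.lm`), with the
mobile fraction $M$ absorbing the plateau deficit left by probe molecules
bound to or trapped inside fibres. Estimators the figure annotations leave
open are fixed as: $I_{pre}$ the mean of pre-bleach samples, $I_0$ the
first post-bleach sample, $I_\infty$ the mean of the last 10% of the trace;
bleaching is treated as instantaneous with $t = 0$ at its end. Initial
guesses come from the plateau ($M$) and the half-recovery time mapped
through the Soumpasis half-time relation ($\tau_D$); bounds are
$\tau_D \in (0, 10^3]$ s and $M \in [0, 1.05]$, the slight overshoot
tolerating noise and being clipped on report. The model is a pure-diffusion
model: reaction-dominated recoveries (strong binding kinetics) are out of
scope and would need a reaction–diffusion treatment.

## Composite-sphere hemodynamics

Outside the thrombus the flow obeys the Stokes equations; inside the cap,
the Brinkman equations with effective viscosity equal to the fluid
viscosity (kept as a parameter `mu_eff`). With the polar axis along the
far-field flow, the axisymmetric stream functions are

$$\psi_\text{out} = U\sin^2\theta\,(r^2/2 + A/r + Br), \qquad
\psi_\text{cap} = U\sin^2\theta\,(Cr^2 + D/r + E\,b_K(\sigma r) + G\,b_I(\sigma r)),$$

where $\sigma = 1/\sqrt{k}$ is the inverse Brinkman screening length and
$b_K, b_I$ are the decaying/growing radial modes built from the
half-integer Bessel functions $K_{3/2}, I_{3/2}$. The six coefficients
solve the linear system of: no slip at $r = R_1$; continuity of $u_r$,
$u_\theta$, tangential stress and pressure at $r = R_2$; uniform flow at
infinity. Matching both tangential stress and pressure is the standard
closure for Brinkman shells; with `mu_eff = mu` and continuous velocities
it also makes the full normal stress continuous. Two implementation details
matter numerically: the Bessel modes are evaluated in exponentially scaled
form (scaled about $R_1$ for the decaying mode, $R_2$ for the growing one),
so nothing overflows even at $\sigma R_2 \sim 10^3$; and the 6×6 matrix is
column-equilibrated before solving, keeping boundary-condition residuals at
machine precision for $k$ from $10^{-3}$ to $10^6$ µm².

The hemispherical wall-attached geometry seen in vivo is treated by
symmetry as a full sphere in unbounded flow, following the classical
composite-sphere approach; wall effects, pulsatility and non-Newtonian
rheology are outside scope.

The drag is read off the Stokeslet coefficient, $F = -8\pi\mu U B$, which
equals the surface integral of the stress tensor and returns exactly
$6\pi\mu U R$ in the solid-sphere limit; `F_rel` divides by the impermeable
drag at radius $R_2$. Limits behave as they must: $F_{rel} \to 1$ as
$k \to 0$ and $F_{rel} \to R_1/R_2$ as $k \to \infty$, and a cap of
core-radius thickness at $k = 1000$ µm² cuts the force by ≈46% — "almost
half". The creeping-flow description is valid while the local Reynolds
number stays below 1; for a parabolic vessel profile the wall-shear
estimate gives the bound $R^* = \sqrt{\mu R_0/4\rho\bar u}$
(`max_thrombus_radius()`), comfortably above the ~60 µm thrombi the model
is meant for.

An independent check matters here: the test suite re-solves the same
boundary-value problem by linear-superposition shooting of the first-order
radial system (with `deSolve`), using $q = g' - \sigma^2 f'$ as the flux
variable that stays continuous across the cap surface, and requires the
velocity profiles to agree to 0.1%.

## Thrombin transport

Concentration is advanced on a cell-centered spherical $(r,\theta)$ grid,
nondimensionalized by $R_1$, $U$ and the initial concentration:
$\partial_t c + \nabla\cdot(uc) = Pe^{-1}\nabla^2 c$, $Pe = UR_1/D$.
Advective face values use second-order MUSCL reconstruction with the minmod
limiter; diffusion uses central differences; time stepping is explicit
SSP-RK2 (Heun) under a combined advective/diffusive CFL bound with safety
factor `cfl` (default 0.4). SSP-RK2 was chosen over forward Euler because,
as a convex combination of Euler steps, it inherits the limiter's TVD and
positivity properties at the same CFL while restoring second-order
accuracy — with Euler the time error $O(\Delta t) = O(\Delta x)$ caps the
observed convergence order at one, and the measured L¹ orders on smooth
advected profiles are 1.8–1.9 with RK2.

The grid is geometrically stretched in $r$ (ratio `stretch`, default 1.02)
to resolve the thin initial shell and the no-slip layer at the core; cell
volumes and face areas are exact ($r^2\sin\theta$ metric), making the
scheme conservative to roundoff — closed-box runs hold total mass to
$10^{-15}$ relative over $10^4$ steps, and each step's mass change equals
the boundary-flux integral identically. Boundary conditions: zero normal
flux at the core (where the velocity already vanishes); at the outer
boundary (default $10R_1$; doubling it moves surface concentrations by
under 1%), $c = 0$ on inflow faces and zero gradient on outflow faces —
the standard well-posed open-domain closure, chosen where the original
statement of the conditions was ambiguous. The poles need no special
treatment because the polar face areas vanish. Initial condition: a unit
shell of thickness $h$ (default 2 µm) against the core, projected by exact
cell-volume fractions; shells thinner than the first cell are rejected
with advice to refine. Thrombin is released by that shell only — there is
no continuing production term (a source hook exists but defaults off), no
coagulation kinetics, and the geometry is frozen over the tens of
milliseconds simulated.

The diffusion layer — the skin where diffusion outruns advection — is the
depth $\delta$ solving $u_t(R_1+\delta,\theta)\,\delta/D = 1$, found by
bracketing and root-polishing the smallest root; for a linear shear
$u_t = \dot\gamma d$ it reduces to $\delta = \sqrt{D/\dot\gamma}$ exactly.
With the defaults ($R_1 = 20$, $R_2 = 25$ µm, thrombin-like
$D = 95$ µm²/s, $U = 1$ mm/s) it comes out near 5% of the thrombus radius
for a 1000 µm² cap and 10–20% for a 3 µm² cap, with the slower Fab IgG
forming a layer about half as thick.

## Synthetic data: what it emulates, and what it does not

The generators are the package's stand-in for the wet lab, and their
defaults are the study conditions. FRAP traces are Soumpasis recoveries
with a mobile fraction, 27 µm spots, 10 pre-bleach and 200 post-bleach
samples over 12 recovery times, and additive Gaussian noise proportional to
the bleach contrast (2–3% typical). Permeation series are linear Darcy
outflows sampled each minute for ten minutes at three pressure drops. Gel
panels span the preparable 0.2–4.2 mg/mL: $\varphi$ follows the
preparation mass balance, permeability follows a power law in $\varphi$
anchored at 1000 µm² (0.2 mg/mL) and 6 µm² (4 mg/mL), and radii follow by
inverting the fibre relation, landing between 150 and 500 nm and
decreasing with concentration. The 4 mg/mL anchor is the smallest
permeability whose derived radius stays inside that observed band; it
compresses the panel's permeability span to a bit over two decades, a
deliberate trade-off — the radii band and the measured permeability range
cannot both be met across the full concentration sweep by a single smooth
power law through the mass-balance volume fractions.

What passing tests on these inputs shows is that the estimators are
correct and unbiased for data obeying the models' assumptions. What they
cannot show: real traces carry photofading, reaction-limited recovery and
non-Gaussian noise; real gels are heterogeneous, their fibres deform under
pressure below 1 mg/mL (such measurements are rejected, never simulated),
and their measured volume fractions need not follow the nominal
preparation balance.

## Numerical conventions and edge cases

* Units: lengths µm (fiber radii nm), permeability µm², diffusivity µm²/s,
  viscosity Pa·s; SI internally for the permeation arithmetic; the
  transport solver is fully nondimensional.
* $\theta = 0$ points downstream (along the far-field flow) everywhere.
* `R2 == R1` is solved in closed form (classical Stokes sphere), bypassing
  the degenerate cap system.
* The power-law fit $k = a(\varphi-\varphi_0)^b$ is performed in log
  space — residuals in the measured decades are multiplicative — with the
  offset profiled out over $[0, \min\varphi)$ and $\varphi_0 = 0$ always
  tried explicitly so zero-offset laws are recovered exactly.
* Degenerate inputs fail loudly: zero-flow permeation returns 0 flagged
  `degenerate`; non-monotone time series, vanishing bleach contrast,
  out-of-validity $\varphi$, sub-cell shells and stagnation-axis
  diffusion-layer queries are all rejected with explicit messages.
* Problem sizes in the test suite: the transport reference grid is 128×64
  with a 1280-cell 1-D oracle at 10× radial resolution; FRAP recovery
  statistics use 50 seeds per condition; power-law bias uses 200
  replicates. These sizes keep the full suite around a minute on one core
  while leaving the Monte-Carlo medians stable.

## Known limitations

The flow is steady, unbounded and Newtonian around a rigid, impermeable
core — no wall, no pulsatility, no deformation, no embolization mechanics
beyond the drag scalar. Transport has no chemistry: no thrombin
generation, binding or inhibition, and no moving boundary as the thrombus
grows. The FRAP model excludes reaction kinetics, and hydrodynamic
diameters are inputs (no light-scattering analysis). Mapping simulated
nondimensional times to laboratory milliseconds requires the near-thrombus
velocity, which is a user input, not a package inference.
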