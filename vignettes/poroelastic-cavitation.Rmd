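---
title: "Cavitation bubble dynamics in soft porous media: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavitation bubble dynamics in soft porous media: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(porocav)
```

# The physical model

`porocav` simulates the collapse and expansion of a vapor bubble inside a
fluid-saturated, deformable porous solid — think of a gas bubble in brain or
adipose tissue, or in a hydrogel. Two fields interact: the density
$\rho(\boldsymbol{x},t)$ of a compressible single-component liquid–vapor
mixture flowing through the pore network, and the displacement
$\boldsymbol{u}(\boldsymbol{x},t)$ of the linear-elastic solid skeleton.

**Fluid.** Mass conservation for the pore fluid, Darcy flow with density-
dependent viscosity, and a barotropic equation of state $p = F(\rho)$
combine into a nonlinear diffusion equation. The equation of state

$$F(\rho)=p_{\rm sat}+ C\Big(\frac{1}{\rho_c}-\frac{1}{\rho}\Big)
  + C\,\frac{b-\rho_c}{\rho_c^2}\,\frac{\rho-\rho_c}{b-\rho}$$

spans the vapor branch (low $\rho$, pressure below saturation), a soft
mixture branch around $\rho_c$, and a stiff liquid branch whose modulus
diverges at the covolume limit $\rho \to b$. It is strictly increasing, has
$F(\rho_c) = p_{\rm sat}$ exactly, and yields a *continuous* squared sound
speed $F'(\rho)$ — the property that makes the PDE tractable with standard
implicit methods. The mixture viscosity interpolates linearly between the
vapor and liquid values, clamped to $[\mu_v, \mu_l]$ so that transient
Newton iterates outside the physical density range cannot produce negative
or excessive viscosities.

One modelling subtlety: a strictly increasing $F$ admits only one density
with $F(\rho) = p_{\rm sat}$, namely $\rho_c$. The representative vapor
density $\rho_v$ (default 8.8 kg/m³) is therefore an independent input used
in the viscosity law and in initial/bubble conditions, *not* the inverse of
$F$ at saturation.

**Solid.** Quasi-static Biot poroelasticity: total stress
$\sigma = \sigma_{\rm eff} - \alpha p I$, effective stress linear-elastic in
the skeleton strain, porosity evolving with the volumetric strain
$\epsilon_v$ and pressure. With incompressible grains ($K_s^{-1}=0$, the
usual soft-tissue assumption) the coupled system is

$$\alpha\rho\,\partial_t \epsilon_v
  + \Big[\tfrac{W(\rho)}{N} + \phi_0\Big]\,\partial_t\rho
  = \nabla\!\cdot\!\Big(\tfrac{k\,W(\rho)}{\mu(\rho)}\nabla\rho\Big),
  \qquad
  \nabla\!\cdot\!\sigma_{\rm eff} = \alpha\nabla p,$$

where $W(\rho) = \rho F'(\rho)$ is the storage function and
$1/N = (\alpha-\phi_0)/K_s$. Fluid inertia, surface tension and thermal
effects are neglected (the collapse is driven by the static overpressure
between far field and bubble, and resisted by Darcy drag and skeleton
elasticity).

## Reference parameters

The fixed parameter set (`preset_table1()`) describes water in a generic
soft porous material: $\alpha = 1$, $k = 10^{-13}$ m², $\mu_l = 10^{-3}$ and
$\mu_v = 1.3\times10^{-5}$ Pa·s, $C = 1450$ Pa·kg/m³, $p_{\rm sat} = 2339$
Pa, $\phi_0 = 0.01$, $b = 998.5$ kg/m³, $\rho_c = 500$ kg/m³,
$K_s^{-1} = 0$. Elasticity is parameterized by Young's modulus $E$ and
Poisson ratio $\nu$ through $\lambda$, $G$ and the P-wave modulus
$M = \lambda + 2G$; the few-kPa moduli used throughout are typical of brain
or adipose tissue. `E = Inf` selects the rigid skeleton.

Note that at these parameters pore pressures of a few kPa acting on a
skeleton with $M$ of a few kPa produce volumetric strains of order one; the
model remains the small-strain theory throughout, which is an acknowledged
limitation for the softest media rather than an implementation choice.

# Spherical collapse (1D)

Under spherical symmetry the momentum balance integrates to
$M\epsilon_v = \alpha(p - p_L)$, which eliminates the solid unknown and
leaves a single scalar PDE,

$$\big[B\,W(\rho) + \phi_0\big]\,\partial_t\rho
 = \frac{1}{r^2}\partial_r\Big(r^2\,\frac{k W(\rho)}{\mu(\rho)}\,
 \partial_r\rho\Big), \qquad B = \frac1N + \frac{\alpha^2}{M},$$

on $r \in (0, L)$ with symmetry at $r=0$ and an imposed boundary density
$\rho(L) = \rho_L$ (998 kg/m³ by default). The elastic storage $B\,W$ is
what slows the collapse: establishing a pressure gradient requires
deforming the skeleton. Displacement and strain are recovered in closed
form from the density (`displacement()`, `volumetric_strain()`).

```{r spherical}
p <- preset_table1()
grid <- spherical_grid(L = 1e-3, n_cells = 1024)
run <- run_collapse(table1_medium(E = 15e3, nu = 0.45), p$eos, grid,
                    forcing_spec("static", rho_L = 998))
run$collapse_time
```

## Discretization

*Space.* Cell-centered finite volumes with $r^2$-weighted face areas and
arithmetic-mean face mobilities $kW/\mu$. The storage term is written in
conservation form through the closed-form antiderivative
$\Phi(\rho) = B\Psi(\rho) + \phi_0\rho$ with $\Psi' = W$, so the discrete
mass balance (storage change = boundary flux) holds at every accepted step
to the nonlinear-solver tolerance — the tests assert $10^{-8}$ relative and
observe $\sim10^{-12}$. A finite-volume scheme was chosen over high-order
continuous elements precisely for this exact discrete conservation; at the
default 1024 cells the collapse time changes by under 1% on mesh doubling.

*Time.* Backward Euler with a full Newton solve per step (tridiagonal
Jacobian, Thomas algorithm). The step size adapts by three mechanisms:
geometric growth (factor 1.4) after comfortable Newton convergence, halving
on Newton failure, and an interface-CFL cap that limits the bubble
interface to at most half a cell of travel per step. The cap ties the
temporal resolution to the only fast scale in this inertia-free problem
and shrinks proportionally under mesh refinement, so the grid-convergence
test controls the combined space–time error; an embedded error estimator
(step doubling) was evaluated as costing three nonlinear solves per step
for no observable accuracy gain at these tolerances.

*Safeguards.* Newton updates are damped to at most $0.3\,b$ per iteration
and iterates are clipped to the EOS domain $(\varepsilon, b-\varepsilon)$,
$\varepsilon = 10^{-6}$ kg/m³; a persistent failure rejects the step.

*Interface bookkeeping.* The bubble radius is the outermost crossing of
the threshold $\rho^* = \rho_c$ (the midpoint of the mixture branch),
located by linear interpolation between cell centers; collapse is declared
when $R$ drops below two cell widths. The initial profile is a tanh ramp
of width 4 cells between $\rho_v$ and $\rho_L$ — the sharp-interface limit
of the model is recovered as the width shrinks, and the measured collapse
time is insensitive to the regularization at the default resolution.

# The poroelastic Rayleigh–Plesset equation

Integrating the flow equation across the liquid shell $(R, L)$ with a
traveling-wave density profile gives an ODE for the bubble radius:

$$R\dot R\,\frac{L-R}{L} = -\beta, \qquad
\beta = \frac{k\,(p_L-p_B)/(\phi_0\mu_l)}
 {1 + (\rho_l-\rho_v)\,F'(\rho_R)/(\phi_0 M)}.$$

The rigid limit $M\to\infty$ reduces the denominator to 1; any finite $M$
slows the interface. For constant $\beta$ the equation integrates to
$t_c = (R_0^2/2 - R_0^3/3L)/\beta$, and for $L \to \infty$ the solution
collapses onto the universal curve $\hat R = \sqrt{1-\hat t}$ with
$\hat t = 2\beta t/R_0^2$ — a scaling that finite $L$ breaks, visibly
already at $L = 2R_0$. The liquid viscosity $\mu_l$ enters $\beta$ because
the derivation integrates over the liquid region at constant viscosity,
and the small interface-velocity correction to the integrated source is
dropped. During ultrasound forcing $\beta$ is re-evaluated from the
*instantaneous* boundary pressure $p_L(t)$.

The interface density $\rho_R$ is not predicted by the reduction — the
density jumps across the interface, so "the density at the interface" is
ambiguous. It is fixed once by `calibrate_rho_R()`: a scalar root solve
matching the ODE collapse time to a single PDE run (default: $E = 15$ kPa,
$\nu = 0.45$, static collapse — the mid-range stiffness of the sweep), and
the value is then reused unchanged for every other parameter set. On the
liquid branch ($\rho_R > \rho_c$) the ODE collapse time is monotone in
$\rho_R$, so the root is unique; with the reference parameters the
calibration lands near 953 kg/m³ and the ODE then tracks the PDE collapse
times within ~15% across $E \in [5, 50]$ kPa.

Integration uses `deSolve::lsoda` (rtol $10^{-9}$) with event-based
stopping at $R_{\min} = 10^{-4}R_0$ for pure-vapor runs, since the ODE is
singular at $R = 0$. With a non-condensable gas the bubble pressure
$p_B = p_{\rm sat} + p_{g0}(R_0/R)^{3\eta}$ prevents singular collapse and
full ultrasound cycles can be integrated; these runs are stiff near the
minimum radius, hence the implicit solver.

# Near-wall collapse (2D axisymmetric)

The full coupled system is solved in cylindrical coordinates on the
axisymmetric half-plane $[0, 5\,\text{mm}] \times [0, 6.5\,\text{mm}]$ (the
10 mm cut-plane width is interpreted as the full diameter): a 1.2 mm bubble
centered 1.5 mm above a rigid wall, no normal Darcy flux and clamped solid
at the wall ($z=0$), density 998.2 kg/m³ imposed on the outer radial and
top boundaries, total-traction-free lateral/top solid boundaries, and
symmetry at the axis. The imposed-density boundary is applied on the outer
radial and top boundaries (the two boundaries of the axisymmetric model
that correspond to the cut-plane's left/right/top edges).

*Fluid*: the same conservative finite-volume machinery with the
cylindrical metric ($r$-weighted faces). *Solid*: bilinear (Q1) finite
elements for axisymmetric elasticity, 2×2 Gauss quadrature with the radial
weight; the load is the volume integral $\int \alpha p\,\nabla\!\cdot v\,
r\,dr\,dz$, into which all boundary terms cancel exactly for
total-traction-free boundaries. The stiffness matrix is assembled once per
run (one distinct element matrix per radial column) and Cholesky-factored;
each coupling pass is then a cheap triangular solve. The discretization
passes a patch test and reproduces uniaxial compression exactly.

**Stabilized coupling.** A naive staggered scheme — fluid step with frozen
strain rate, then elasticity, iterate — diverges for soft skeletons: with
$M$ of a few kPa, a 1 kg/m³ density change in the liquid moves the local
strain by order one. The cure is an exact split of the coupling term,

$$\alpha\rho\,\partial_t\epsilon_v
 = \underbrace{\tfrac{\alpha^2}{M}W(\rho)\,\partial_t\rho}_{\text{local,
 implicit}} + \alpha\rho\,\partial_t\underbrace{\big(\epsilon_v -
 \tfrac{\alpha p}{M}\big)}_{\epsilon_t,\ \text{staggered}},$$

which absorbs the stiff local pressure response into the fluid storage
(recovering exactly the $B\,W$ term of the spherical reduction) and
iterates only the smooth nonlocal remainder $\epsilon_t$ to a tolerance of
$10^{-6}$ on the strain scale $\alpha F(\rho_L)/M$. In practice 2–8 passes
per step suffice at any stiffness tested. Mass balance is accounted in the
same split form, so the per-step conservation check covers the coupled
run as well.

The vapor region is tracked as the set $\rho < \rho_c$; its volume defines
an equivalent radius for the step-size controller, collapse is the first
time the set is empty, and the collapse point is the volume-weighted
centroid of the last non-empty vapor region.

```{r nearwall}
rigid <- experiment_near_wall(rigid = TRUE)           # ~1 min
soft  <- experiment_near_wall(rigid = FALSE)          # E = 5 kPa, nu = 0.3
c(rigid$collapse_time, soft$collapse_time)
```

# Problem sizes and tolerances

Defaults were chosen as the coarsest discretizations whose headline
quantities are grid-converged to well inside the comparison tolerances:
1024 cells for the 1 mm spherical domain (collapse time moves <1% on
doubling) and 100×65 cells for the near-wall domain (<10% on doubling,
against a 30% comparison band). The test suite exercises the same solvers
on smaller grids and scaled geometries where the checked property is
resolution-independent (exact identities, conservation, orderings,
convergence rates), and at full size only where the quantity itself is the
target. Nonlinear tolerances ($10^{-10}$ relative Newton residual in 1D,
$10^{-9}$ in 2D, $10^{-6}$ coupling) sit orders of magnitude below every
physical comparison made.

# Limitations

* Small-deformation kinematics, used even where the soft-tissue parameters
  produce order-one strains; no fracture, no contact at the wall.
* No fluid inertia: the classical inertial Rayleigh–Plesset dynamics
  (rebound, ringing) are outside the model; collapse here is
  diffusion-limited.
* No surface tension or thermal effects; bubbles are assumed much larger
  than the pore scale.
* The reduced bubble equation inherits the traveling-wave closure; its
  single calibrated constant $\rho_R$ is a fit, not a prediction, and is
  only validated for collapse-type runs at the reference parameters.
* The imposed-density outer boundary idealizes a large saturated
  reservoir; quantitative collapse times for the near-wall geometry are
  reported at the scaled-down 100×65 resolution and carry the
  corresponding discretization bias (both reference times are reproduced
  ~13–15% low).
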