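---
title: "A free-boundary model of checkpoint and TGF-beta blockade in a tumor spheroid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A free-boundary model of checkpoint and TGF-beta blockade in a tumor spheroid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorpde)
```

## The model

`tumorpde` simulates a spherical tumor spheroid occupying $0 \le r \le R(t)$
whose interior is a dense mixture of seven cell populations — cancer cells
$C$, pro-inflammatory M1 macrophages, a pooled immunosuppressive myeloid
population $M_2$ (MDSCs, M2 macrophages, TAMs), dendritic cells $D$, Th1
helper cells $T_1$, cytotoxic CD8$^+$ T cells $T_8$ and regulatory T cells
$T_r$ — together with nine molecular species: IL-2, IL-10, IL-12, the
chemokine CCL2 ($P$), TGF-$\beta$ ($T_\beta$), the checkpoint receptor PD-1
($P_D$), its ligand PD-L1 ($P_L$), and the two therapeutic antibodies $A_1$
(anti-PD-1) and $A_\beta$ (anti-TGF-$\beta$). All densities and
concentrations are in g/cm$^3$, time in days, lengths in cm.

Every species obeys a reaction–diffusion equation; cells additionally advect
with a radial velocity $u(r,t)$ generated by the internal pressure of
proliferation, and the boundary moves with the cells, $dR/dt = u(R,t)$.
Reaction terms follow three conventions: mass-action products for direct
interactions, Michaelis–Menten factors $X/(K+X)$ for receptor-mediated
activation, and inhibition factors $1/(1+X/\hat K)$.

The immunology enters through two feedback loops:

* **Checkpoint inhibition.** The complex $Q = \sigma P_D P_L$ suppresses
  activation and IL-2-driven proliferation of $T_1$ and $T_8$ by
  $1/(1+Q/\hat K_{TQ})$ and converts Th1 cells into Tregs at rate
  $\lambda_{T_1T_r} T_1\, Q/(K_Q+Q)$. The conversion scale
  $\lambda_{T_1T_r}$ is **cancer-specific**.
* **TGF-$\beta$ immunosuppression.** TGF-$\beta$ (secreted by cancer cells,
  the $M_2$ pool and Tregs) blunts CD8 killing of cancer cells through the
  factor $1/(1+\zeta_{T_\beta} T_\beta)$, expands Tregs, and pushes
  macrophages toward the $M_2$ phenotype. The killing-inhibition strength
  $\zeta_{T_\beta}$ is the second **cancer-specific** parameter.

Both antibodies are modelled as continuously infused species with a constant
effective source on the dosing window $[t_0, t_1]$ (arms: control, anti-PD-1,
anti-TGF-$\beta$, combination). Each antibody depletes its target
bilinearly and is itself consumed while blocking; the PD-1 blocking term
$-\mu_{P_DA_1} P_D A_1$ appears identically in the receptor and the antibody
equations, while the TGF-$\beta$ pair carries two independent coefficients
($\mu_{A_\beta T_\beta}$ on the target, $\mu_{T_\beta A_\beta}$ on the drug):
the TGF-$\beta$ turnover flux is orders of magnitude larger than the feasible
antibody supply, so gram-for-gram consumption would make blockade impossible.
The consumption coefficient is deliberately placed near the supply-limited
knee — when Treg expansion drives TGF-$\beta$ production up, the antibody
budget saturates and TGF-$\beta$ escapes the blockade. This is the mechanism
behind the non-monotone response to the anti-PD-1 dose at high anti-TGF-$\beta$
dose in strongly TGF-$\beta$-protected tumors.

### The velocity closure

The combined cell density is constant, $\sum_i X_i \equiv \theta$. Summing
the seven cell equations under this constraint leaves

$$\theta\,\frac{1}{r^2}\frac{\partial (r^2 u)}{\partial r}
  = \sum_i F_i + \sum_i \delta_i \nabla^2 X_i
  - \nabla\!\cdot\!\big(\chi_P (M_1+M_2+T_r)\nabla P\big),$$

so $u$ is recovered by cumulative quadrature of $r^2 \times$ (total cell
source)$/\theta$ with $u(0)=0$. The chemotaxis contribution enters with a
minus sign because each chemotactic cell equation carries
$-\nabla\cdot(\chi_P X \nabla P)$ on its right-hand side. Tumor volume then
grows (or shrinks) at the net relative mass production rate: treatments act
on the volume by changing the balance of cell production and loss.

### Molecular equations not fixed by the headline system

The cytokine, chemokine and receptor equations take
production–degradation form with the producers assigned to their documented
sources: IL-2 by $T_1$; IL-12 by $D$; IL-10 by $M_2$ and $C$; CCL2 by $C$;
PD-1 carried by $T_1$, $T_8$, $T_r$; PD-L1 by T cells, macrophages and
(with its own weight $\lambda_{P_LC}$) cancer cells. Dendritic cells, which
have no printed equation, activate from a constant naive pool under a
saturating tumor signal, $\lambda_D D_0\, C/(K_C+C) - \mu_D D$. All
coefficients live in the parameter file, so alternative forms can be
substituted without code changes.

## Parameters

Units are days, g/cm$^3$ and cm throughout. The printed quantities — the dose
rates $\gamma_{A_1} = 10^{-8}$ and $\gamma_{A_\beta} = 2\times10^{-6}$
g/(cm$^3\cdot$d), the gastric pair $\zeta_{T_\beta} = 4\times10^{6}$ cm$^3$/g
and $\lambda_{T_1T_r} = 10^{3}$ d$^{-1}$, the treatment start days and
horizons of the five cancer scenarios, and the sweep ranges — are used as
printed. Every other constant is a **documented placeholder**, flagged
`# PLACEHOLDER` in `inst/extdata/params_default.yaml`: magnitudes were chosen
by unit and timescale reasoning (antibody half-lives of days, cytokine
half-lives of hours or less, T-cell turnover of ~5 days, tumor volume
multiplying ~20–100-fold over a 45-day mouse experiment), and the free
magnitudes were then calibrated once, using the well-mixed reduction, so the
default model reproduces the published qualitative results: the five
scenario arm orderings, the ~1/3 Treg increase under anti-PD-1 at the
gastric parameters, the monotone laws of the hyperprogression map, and the
dose-map laws. They were not adjusted afterwards. Consequences of this
placeholder status: absolute densities, volumes and efficacy percentages are
indicative only; the signs, orderings and monotone structure are the
calibrated claims.

Preset assignment of the cancer-specific pair: only the gastric values are
printed. The other presets follow the stated relations between scenarios
(colon has a much smaller $\zeta_{T_\beta}$ than melanoma/breast/bladder,
which share one pair; the gastric conversion scale is much larger):
colon $(4\times10^5,\,6)$, melanoma/breast/bladder $(4\times10^6,\,6)$,
gastric $(4\times10^6,\,10^3)$ — all inside the printed sweep ranges.

## Numerics

**Front fixing.** The moving domain is mapped to $\rho = r/R(t) \in [0,1]$
on a fixed uniform mesh ($N = 65$ nodes by default). The transform adds a
pseudo-advection $-\rho \dot R/R\,\partial_\rho$ to every species.

**Time stepping (IMEX).** Molecular species are advanced implicitly in
diffusion and in their linearised loss terms (every loss is proportional to
the species itself, so the stiff degradation and blocking rates — up to
$\sim2\times10^4$ d$^{-1}$ — sit on the tridiagonal diagonal), with explicit
production and pseudo-advection; this is unconditionally stable and
positivity-preserving for them. Cells are advanced fully explicitly
(their reaction rates are mild and their diffusivities are ~10$^{-6}$
cm$^2$/d), which makes the discrete sum over cell updates cancel exactly
against the nodal velocity divergence $\mathrm{div}\,u_j := S_j/\theta$:
the constant-density constraint is preserved to round-off by construction.
A rescaling projection is still applied each step and logged; its magnitude
stays at the $10^{-16}\theta$ level and the tests fail if it exceeds
$10^{-8}\theta$.

**Conversion flux limiter.** At extreme conversion scales
($\lambda_{T_1T_r} \gtrsim 10^4$ d$^{-1}$ in the map sweeps) the explicit
Th1$\to$Treg transfer would overdraw the Th1 pool within one step. The
transferred mass is therefore capped at the pool's post-update content and
credited identically to Tregs: the cell sum is untouched, the limit is
inactive whenever $\Delta t\,\lambda_{T_1T_r} Q/(K_Q+Q) < 1$, and in the
stiff regime it reproduces the quasi-steady behaviour (the whole Th1
activation flux routes to Tregs), which is also the exact limit of the
continuous dynamics.

**Step control.** Default $\Delta t = 10^{-3}$ d with an advective CFL check
($\Delta t\,|w| \le 0.5\,\Delta\rho$); violating steps are rejected and
halved. Defaults resolve the fastest surviving explicit scale
comfortably; the refinement test (halving $\Delta\rho$ and $\Delta t$
changes the day-45 volume by $\sim0.01\%$) bounds the discretisation error.

**Boundary conditions and initial data.** Zero flux for every species at
$\rho = 1$ and symmetry at $\rho = 0$; immune influx is represented by the
interior source terms fed from constant naive pools ($M_0$, $D_0$, $T_1^0$,
$T_8^0$). The default initial state is a uniform 0.1-cm spheroid with cancer
at 80% of $\theta$, the immune populations sharing the remainder in fixed
proportions, and molecules at their production/degradation balance. A
self-consistent alternative — immune species at the drug-free uniform steady
state computed by the well-mixed reduction — is available via
`initial_state(p, init = "steady")`; the fixed-fraction start was chosen as
the default because it mimics an implantation experiment (the interior
composition relaxes to the quasi-steady profile within one to two simulated
weeks, before any treatment starts) and because it makes no solver output
depend on a root-finder. Because the initial data are uniform and the
boundary conditions are zero-flux, the scenario simulations remain uniform
in space; the spatial machinery is exercised (and verified) by perturbed
states in the test suite, and matters once non-uniform initial data or
boundary fluxes are supplied.

**Well-mixed reduction as oracle.** With uniform fields the PDE reduces
exactly to an ODE system in which cells feel a uniform dilution
$g = \sum_i F_i/\theta$ and the radius grows as $dR/dt = gR/3$. The package
integrates this reduction with `deSolve::lsoda` and the test suite requires
the PDE (uniform data, zero flux) to track it to $10^{-3}$ relative over 45
days — a genuine cross-check, since the two paths share no stepping code.

## What the experiments compute

* `run_scenario(preset, arm)` — volume curves for the four arms of the five
  cancer presets; efficacy is
  $(V_\mathrm{control} - V_\mathrm{treated})/V_\mathrm{control}\times 100\%$
  at the final treatment day (dosing runs from the preset's $t_0$ to its
  horizon, so the horizon is the last day of treatment).
* `hyperprogression_map()` — anti-PD-1 efficacy at day 45 over
  $(\zeta_{T_\beta}, \lambda_{T_1T_r}) \in (0, 1.5\times10^6] \times
  (0, 5\times10^4]$ including the zero edges; treatment starts at day 15
  (the hyperprogression scenario's schedule). `sign_boundary()` extracts the
  zero-efficacy curve $\lambda_{T_1T_r} = f(\zeta_{T_\beta})$ and refuses to
  smooth rows with multiple sign changes.
* `efficacy_dose_map()` — combination-therapy efficacy at day 45 over
  $(\gamma_{A_\beta}, \gamma_{A_1}) \in [0, 2\times10^{-6}] \times
  [0, 10^{-8}]$, default start day 14 (the common scenario schedule).
* `treg_comparison()` — tumor-averaged Treg density of the four arms at the
  final day of the gastric preset. The measurement day is not fixed by the
  published comparison; the final day is used and exposed as the `day`
  argument.

Sweep grids default to coarse (6$\times$6 or smaller) so a full map runs in
well under a minute at test resolution ($N = 25$–33, $\Delta t =
2\times10^{-3}$ d); figure-quality grids are a parameter away. The test
suite and the acceptance script state the problem sizes they use.

## Emergent behaviour worth knowing about

Anti-PD-1 blockade lowers $Q$, which releases T-cell activation — but PD-1
and PD-L1 are expressed by the T cells themselves, so the expansion partly
rebuilds $Q$ (a rebound quadratic in T-cell abundance). Where
$\lambda_{T_1T_r}$ is large, the released Th1 flux is immediately converted
to Tregs, which secrete TGF-$\beta$, suppress further activation and, when
$\zeta_{T_\beta}$ is also large, keep CD8 killing disabled: the net effect of
anti-PD-1 is then extra immune mass and less killing — hyperprogression.
Where both parameters are small, the released CD8 response dominates and
efficacy is positive. The combination rescues the response because
anti-TGF-$\beta$ removes both the killing brake and the Treg amplifier.

## Limitations

* All default rate constants except the printed values are calibrated
  placeholders; quantitative outputs should not be read as measurements.
* Dosing is the constant-rate approximation of the experimental schedules;
  pulsed pharmacokinetics are out of scope.
* Naive immune pools are constant; dead cells are removed instantly; the
  geometry is spherically symmetric with no necrotic core or nutrient field.
* The first-order IMEX stepping trades accuracy for robustness; the
  verification suite pins the error at the default resolutions (volume
  errors $\ll$ 1%), but very stiff custom parameterisations should be
  checked against the well-mixed oracle, which is cheap.
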