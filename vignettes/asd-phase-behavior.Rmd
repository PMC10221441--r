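---
title: "Thermodynamics of ASD hydration: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of ASD hydration: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An amorphous solid dispersion (ASD) keeps a poorly soluble drug (API)
molecularly dissolved in a glassy polymer. On contact with water, the ASD
surface absorbs water along a straight *hydration pathway* in the
API/polymer/water composition triangle: the API:polymer ratio stays fixed
while the water content rises. Water plasticizes the surface until the
mixture glass-transition temperature falls to the medium temperature — the
*escape glass transition* (eGT) — at which point the gel layer becomes
mobile enough to dissolve. Whether the surface composition crosses the API
solubility line or the liquid-liquid (amorphous-amorphous) binodal *before*
reaching eGT decides whether the gel layer passivates:

* **LoR Type I** — a fast-crystallizing API whose solubility line is crossed
  inside the gel layer builds a crystalline crust; API and polymer release
  collapse together.
* **LoR Type II** — a slow crystallizer whose binodal is crossed inside the
  gel layer demixes into a glassy API-rich phase that passivates the
  surface while the mobile polymer-rich phase escapes; release becomes
  incongruent (polymer only).

The package computes all three loci from first principles and classifies
the mechanism per drug load.

## Models

**Solubility (SLE).** The crystalline API's mole-fraction solubility solves

$$\ln (x^L_i\gamma^L_i) = -\frac{\Delta h^{SL}_i}{RT}
\Big(1-\frac{T}{T^{SL}_i}\Big)
 - \frac{\Delta c^{SL}_{p,i}}{R}\Big(\ln\frac{T^{SL}_i}{T}
 - \frac{T^{SL}_i}{T} + 1\Big)$$

The heat-capacity term is dropped exactly when the component carries no
$\Delta c^{SL}_p$ (the venetoclax record stores it as absent).

**Liquid-liquid equilibrium.** Coexisting phases satisfy per-component
isoactivity, $x^{L1}_i\gamma^{L1}_i = x^{L2}_i\gamma^{L2}_i$. Tie lines,
the binodal, and path crossings are all roots of this system under
different closure conditions (feed collinearity, a fixed path coordinate,
or a fixed branch coordinate).

**Activity coefficients: PC-SAFT.** The residual Helmholtz energy is the
sum of hard-chain, dispersion and association contributions,
$a^{res}=a^{hc}+a^{disp}+a^{assoc}$, with the standard hard-chain and
dispersion expressions (universal model constants of the perturbed-chain
theory) and the Wertheim association term. Combining rules: arithmetic-mean
segment diameter, geometric-mean dispersion energy corrected by a linear
$k_{ij}(T)=k_{ij,m}T+k_{ij,b}$, and Wolbach-Sandler cross association. The
association strength uses
$\Delta^{A_iB_j} = \sigma_{ij}^3\, g^{hs}_{ij}(d)\, \kappa^{A_iB_j}
(e^{\epsilon^{A_iB_j}/kT}-1)$. Site scheme: "N/N" counts are read as N
donor and N acceptor sites, with only donor-acceptor bonding. The polymer
(PVPVA64) carries $\kappa = 0.02$ with zero self-association energy and
653/653 sites: its self-association strength is exactly zero but it
cross-associates with water and naproxen (induced association). Water's
segment diameter is temperature dependent and feeds every place a water
diameter appears, including cross parameters.

$\gamma_i = \varphi_i(T,P,x)/\varphi^{0,L}_i(T,P)$ with the pure liquid at
the same $T,P$ as reference — for the polymer the hypothetical pure liquid
polymer. The choice of polymer reference cancels from every equilibrium
computed here (isoactivity compares the same reference on both sides).

**Glass transition.** Gordon-Taylor,
$T_g = \sum_i K_i w_i T_{g,i} / \sum_i K_i w_i$, with Simha-Boyer
coefficients $K_i = \rho_{ref}T_{g,ref}/(\rho_i T_{g,i})$ referenced to the
polymer. The equation is invariant under a common rescaling of all $K$, so
the reference choice is presentational. Temperatures are kelvin inside the
equation; reports print Celsius.

## Numerical design

* **Density.** The liquid root of $P(\rho)=P$ is found by a secant
  iteration started at packing fraction 0.45, iterated to a
  machine-precision step so the root does not depend on the warm start; a
  bracketing grid scan (mechanically stable root of largest packing
  fraction) is the fallback. The compressibility factor at the root is
  taken as $P/\rho k_B T$, which is far more accurate at liquid conditions
  ($Z\sim10^{-5}$) than differencing the Helmholtz energy.
* **Chemical potentials.** Residual chemical potentials are fourth-order
  central finite differences of $a^{res}$ in composition at constant
  density. Second-order differences are *not* converged here: the
  association term makes $a^{res}$ extremely stiff in the polymer mole
  fraction (653 sites), with third derivatives of order $10^{11}$. The
  fourth-order stencil at step $10^{-6}$ keeps chemical potentials accurate
  to about $10^{-9}$; an independent Gibbs-Duhem residual test guards this
  choice. Closed-form toy activity models provide solver oracles that avoid
  the equation of state entirely.
* **Association.** The site-fraction equations are solved by Newton (the
  N/N schemes here are symmetric, so donors and acceptors reduce to one
  unknown per component) polished to a residual of $10^{-14}$, with damped
  successive substitution as fallback. The tight tolerance matters because
  the association Helmholtz expression is not stationary in the site
  fractions, and downstream finite differences would otherwise inherit the
  solver error.
* **Equilibrium solvers.** All equilibrium equations are solved in
  log-mole-fraction variables: the polymer's 65 kg/mol molar mass makes its
  mole fractions $O(10^{-5})$, and in venetoclax-system tie lines the
  API-rich phase holds polymer mole fractions around $10^{-57}$ — physically
  nil but needed in log space for the isoactivity algebra. Two regimes are
  distinguished automatically: a *polymer-free conjugate* regime
  (venetoclax-like), where the conjugate polymer content follows from the
  polymer isoactivity in closed form and the Newton runs on two unknowns,
  and a *full ternary* regime (naproxen-like) with three unknowns.
* **Stability analysis.** Tangent-plane distance is minimized by
  Michelsen-style successive substitution from several seeds, each seed's
  support defining the face searched (trials without polymer are iterated
  without polymer, which keeps the substitution stable against the
  polymer's enormous activity-coefficient swings). The naproxen system's
  instability basin near its binodal is only $O(10^{-4})$ deep and escapes
  successive substitution entirely; a quasi-Newton (BFGS) minimization of
  the modified tangent-plane function catches it. Path-binodal crossings
  collect candidate roots from both regimes and keep the smallest crossing
  water content. Where the full-regime Newton cannot be polished, the
  crossing is reported at the stability-boundary bisection estimate
  (resolution 0.5 wt%) with the honest isoactivity residual attached;
  tie lines from the converged solvers carry residuals at or below
  $10^{-8}$.
* **eGT.** Bisection on the water coordinate of the fixed-ratio hydration
  line, bracket [0, 0.999], tolerance $10^{-10}$; the bracket is guaranteed
  monotone because water has by far the lowest $T_g$ and a positive $K$.
* **Crossing-order tolerance.** Crossings within 0.05 wt% water of eGT are
  flagged as sitting at the gel-layer boundary (the 20 wt% naproxen case is
  deliberately near-coincident).
* **Reporting.** Report tables round half-up to one decimal in wt% and
  Celsius, mirroring the conventions of the published hydration tables;
  raw values are kept alongside.

## Choices on genuinely open points

* The spinodal is computed in mole-fraction curvature variables (the basis
  in which the equilibrium equations are stated); the locus itself is
  basis independent, only its parameterization is not.
* `crystallization_propensity` is a user input (`"fast"`/`"slow"`), not
  computed: no in-model quantity decides it, and the classification rule
  needs it only as a switch.
* The hydration path is the straight line of fixed API:polymer ratio. The
  real interfacial path curves as the polymer releases preferentially;
  that curvature is outside the classifier's scope.
* The "tie line at eGT" construction for drug loads that demix before
  escaping the glass: the feed is taken at the path's crossing of the
  (homogeneous-mixture) eGT line, and the tie line through that feed gives
  the phase compositions and lever fractions. This reproduces the reported
  polymer-rich/API-rich endpoint compositions and temperatures.
* The dose-strength helper is the plain product
  `solubility x volume x factor` in mg. In the published worked example the
  printed solubility is the supersaturation *target* concentration (ten
  times the base aqueous solubility), so the example is reproduced with the
  base solubility 0.0429 g/L and factor 10.

## What the packaged parameter set does and does not capture

The shipped `"dohrn2023"` fixture holds the published melting properties,
densities, glass transitions, PC-SAFT pure-component parameters and binary
interaction coefficients for naproxen, venetoclax, PVPVA64 and water, as
printed. Calculations with it emulate the published model system: an
unbuffered water medium at 0.1 MPa, a homopolymer pseudo-component of
65 kg/mol, no ionization, no surfactants, no kinetics. Tests passing
against this fixture demonstrate fidelity of the thermodynamic machinery,
not predictivity for buffered media, other polymer grades, or systems
whose parameters were never fitted.

Two known deviations from the published tables, both geometry
amplification of sub-0.5-wt% differences in a nearly path-parallel
binodal branch: the 0.5 wt%-DL venetoclax binodal crossing computes to
~26 wt% water against a printed 20.5, and the dry venetoclax/PVPVA64
demixing limit computes to ~6.6 wt% API against a figure readout of ~5.
All other venetoclax rows (1 and 2.5 wt% DL crossings, conjugate
compositions, all glass-transition values) and all naproxen rows
reproduce within the printed-table tolerances.

## Problem sizes used in tests

The test suite runs the solvers at the study's own scale: single ternary
systems, path crossings for the six published drug loads, grid oracles at
a few hundred points per dimension, and a drug-load threshold bisection
to 0.1 wt%. These sizes keep the full suite within a desk-scale run while
exercising every solver on the same problems the reported numbers come
from.
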