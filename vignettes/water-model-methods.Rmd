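---
title: "A neural-network polarizable water model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neural-network polarizable water model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the numerical choices, and the design
decisions behind `aquann` — in the spirit of a methods section, so a user can
judge what the package computes and what its tests do and do not demonstrate.

## The model

`aquann` implements a flexible 3-site water force field in which the atomic
partial charges are not constants but smooth functions of the local
environment, evaluated each step by small dense neural networks, together
with an explicit intermolecular charge-transfer (CT) term predicted per
molecule pair.  The total energy is

$$U = \sum_I \left[k_b\!\left((r_{OH_1}-r^0)^2 + (r_{OH_2}-r^0)^2\right)
      + k_a(\theta_I-\theta^0)^2\right]
    + \sum_{i<j}\left[\frac{A_{ij}}{r_{ij}^9}-\frac{B_{ij}}{r_{ij}^6}\right]
    + k_e\sum_{i<j}\frac{q_i q_j}{r_{ij}}
    - k_c\sum_{IJ}\frac{\delta q_{IJ}^2}{\delta q_{IJ}^2+3\,\delta q_0^2},$$

with intermolecular sums excluding intramolecular pairs, direct Coulomb sums
for clusters and Ewald summation for orthorhombic periodic cells.  Harmonic
terms use the convention $U = k\,\Delta^2$ *without* the factor $\tfrac12$;
the shipped SPC/FW constants are therefore half the published values
(identical physics, documented at `spcfw_params()`).

**Descriptors.** Each atom's environment is encoded by interaction-classified
radial functions
$f^{\alpha\beta}_i=\sum_{j\in\beta}e^{-k_f r_{ij}}\,s_c(r_{ij})$ with the
cosine cutoff $s_c(r)=\tfrac12[\cos(\pi r/r_c)+1]$ for $r\le r_c$.  The
interaction class $\beta$ separates neighbor element (O or H) and
intra/intermolecular relation, so no angular terms are needed for charges.
Per atom, 24 slots: for each of three decay parameters
($k_f = 0.5, 1.0, 2.0\ \mathrm{\mathring A^{-1}}$, a geometric ladder that
probes short-, mid- and long-ranged structure; configurable), the centre's
intra- and intermolecular ICFs for classes O and H, plus the intermolecular
ICFs of the two other atoms of the same molecule.  For an O centre those two
sibling atoms are both H, and raw per-atom blocks would swap under an
arbitrary relabeling of chemically identical hydrogens; we therefore store
the smooth symmetric power sums $f_{H_1}+f_{H_2}$ and $f_{H_1}^2+f_{H_2}^2$,
which keeps the full feature vector exactly invariant under H permutation
without sacrificing smoothness (sorting-based orderings would not be
differentiable at crossings).  The pair CT features (36 slots) apply the same
construction to each molecule of an ordered pair restricted to the partner's
atoms, with $r_c$ replaced by the CT cutoff; swapping the pair swaps the two
18-slot halves.

Cutoffs are 4.4 Å for charge features and 5.5 Å for CT.  At 4.4 Å roughly the
first two solvation shells (about 24 molecules at liquid density) are inside
the environment; at 5.5 Å the pair CT of a water dimer has decayed to the
$10^{-5}\,e$ scale.

**Networks.** One network per element (24 inputs) and one for pairs
(36 inputs), each with four Swish hidden layers
($A(x)=x\,\sigma(\beta x)$, $\beta = 3$, near-linear around 0) of width 64 by
default and a linear scalar output.  Inputs and labels are standardized with
statistics stored in the weight archive; the per-slot scale is floored at 2%
of the largest slot spread because near-constant descriptors would otherwise
be amplified into high-curvature input directions, making the predicted
charge — and hence the forces — needlessly rough in configuration space.

**Charge neutrality.** Independent per-atom predictions leave a small net
charge; before any electrostatics all charges are shifted by their mean
$\Delta q=\sum_i q_i/N$.  The coordinate dependence of this shift is
propagated exactly through the force chain rule.

**Charge transfer.** The pair value is antisymmetrized by construction,
$\delta q_{IJ}= s_c(r_{OO};5.5)\cdot\tfrac12[g(F_{IJ})-g(F_{JI})]$, so
$\delta q_{IJ}=-\delta q_{JI}$ holds identically.  The explicit
$s_c(r_{OO})$ gate is needed for energy continuity: when the O–O distance
reaches the cutoff and the pair leaves the CT list, H···O kernel terms inside
the features are still nonzero, so an ungated predictor would jump.  The gate
makes $\delta q\to 0$ smoothly; its gradient is included analytically.
Training labels are divided by the gate so the gated predictor matches them.
The CT energy $-k_c\,\delta q^2/(\delta q^2+3\delta q_0^2)$ is even, zero at
zero, saturates at $-k_c$, and — because of the factor 3 — has its force
magnitude maximal exactly at $\delta q=\delta q_0$, identifying $\delta q_0$
as the reference CT of strongest CT force.

**Forces.** All gradients are analytic:
$\frac{dU}{d\mathbf R}=\frac{\partial \bar U}{\partial \mathbf R}
 +\sum_i\frac{\partial U}{\partial q_i}\frac{dq_i}{d\mathbf F_i}
  \frac{d\mathbf F_i}{d\mathbf R}
 +\sum_{IJ}\frac{\partial U}{\partial \delta q_{IJ}}
  \frac{d\delta q_{IJ}}{d\mathbf R},$
where $\partial U/\partial q_i$ is the electrostatic potential (direct or
Ewald) times $k_e$, network input-gradients come from reverse-mode
backpropagation, and the neutralization shift contributes
$-\frac1N\sum_j dq_j/d\mathbf R$ to every atom's charge derivative.  The
whole chain is validated against central finite differences (relative error
below $10^{-5}$, typically $10^{-8}$) and a work–energy path integral.

## Numerical choices

* **Ewald.** Standard real/reciprocal/self decomposition for orthorhombic
  cells; intramolecular pairs are skipped in real space and removed from the
  reciprocal part by an erf correction.  The splitting parameter and
  reciprocal cutoffs follow from a single accuracy target
  ($10^{-6}$ by default): $\alpha=\sqrt{-\ln\epsilon}/r_c$ and
  $k^{max}_i=\lceil\alpha L_i\sqrt{-\ln\epsilon}/\pi\rceil$.  The result is
  invariant under a twofold change of $\alpha$ within the target, and the
  rock-salt lattice reproduces the Madelung constant 1.747565.
* **van der Waals truncation.** Under periodic boundaries the 9–6 (and the
  baseline's 12–6) interaction is tapered to zero by a $C^1$ cosine switch
  over the outer 15% of the real-space cutoff.  A plain energy-shifted
  cutoff was tried first and rejected: its force discontinuity produced a
  measurable secular NVE drift.  The 9–6 coefficients derive from 12–6
  $\varepsilon/\sigma$ input by matching well depth and minimum position
  ($A=2\varepsilon r_m^9$, $B=3\varepsilon r_m^6$, $r_m=2^{1/6}\sigma$).
* **Minimum image.** Orthorhombic cells only; box lengths must exceed twice
  the largest cutoff.  An exactly-half-box displacement maps
  deterministically to the negative image.
* **Minimization.** BFGS on the analytic gradient, followed by a damped
  Newton polish (finite-difference Hessian of the analytic gradient) to
  reach max-force tolerances of $10^{-6}$ kcal/mol/Å robustly.
* **Dynamics.** Velocity Verlet (NVE) and the BAOAB Langevin splitting (NVT,
  friction 1/ps default); every stochastic path takes an explicit seed.
  Default time step 1 fs; 0.5 fs is recommended for the dynamic-charge
  backend because the charge response adds force curvature.
* **Dimer interaction energy.** `optimize_dimer()` reports
  $E_{int}=U(\text{dimer})-\sum_m U(\text{monomer at its in-dimer
  geometry})$ — the supermolecular interaction energy with monomer
  deformation excluded (for SPC/FW: −7.14 kcal/mol at the minimum, while the
  binding energy relative to relaxed monomers is −6.85).  The acceptor angle
  $\theta_A$ is measured between the acceptor's HOH bisector and the O–O
  axis, the standard experimental convention.

## Surrogate labels and what the tests show

No quantum-chemistry reference data ship with the package.  The
`synthetic_oracle` module generates configurations by seeded SPC/FW cluster
MD and labels them with a smooth, local, rigid-motion-invariant surrogate:
$q_H = 0.41 + 0.05\sum_{O'}e^{-1.5 r_{HO'}}s_c(r_{HO'};4.4)$ (amplitudes in
$e$, decays in $\mathrm{\mathring A^{-1}}$), oxygens balancing their
hydrogens plus the molecule's CT budget, and pair CT
$\delta q = 0.02\,[\sum_{H\in I,O\in J}-\sum_{H\in J,O\in I}]
e^{-2.5 r}s_c(r;5.5)$, which decays to the $10^{-5}e$ scale at a 5.5 Å
hydrogen bond.  These magnitudes mirror condensed-phase water charge ranges,
so error tolerances on the surrogate are meaningful; optional Gaussian noise
(default $\sigma=0.002\,e$) emulates label uncertainty.

The learnability benchmark (500 clusters of 25 molecules; 40% training,
25-cluster validation and remainder-test splits scaling the
8000-train/50-validation protocol of a 20000-configuration pool; up to 200
epochs of minibatch Adam with best-validation restore) is run on *noiseless*
labels: with the default noise the mean-absolute-error floor
$\sigma\sqrt{2/\pi}\approx 0.0016\,e$ already exceeds the 10%-of-label-SD
target, so the noise-free setting is the only well-posed probe of whether the
descriptors and networks can represent the map.  Trained this way the
held-out MAE is $\sim 1$–3% of the label SD with $R^2>0.999$, and models
trained on 25-molecule clusters transfer to 64-molecule clusters within
about 1.1× the same-size error.

What this does *not* show: the surrogate is a radially-structured function
quite similar in form to the descriptors, so these results demonstrate the
pipeline's correctness and data efficiency, not accuracy against real
correlated-wavefunction charges, whose angular and many-body structure is
richer.

## Energy-conservation protocol

The NVE conservation check runs a 16-molecule periodic box (L = 11.2 Å —
gas-like density, since minimum-image validity requires L > 11 Å) for 10 ps
at dt = 0.5 fs, from a minimized configuration equilibrated at 100 K, and
measures drift as the linear-fit slope times the run length over |E(0)|.
The cold, ordered start is deliberate: force inconsistencies (the thing the
oracle exists to catch) produce drift at any temperature, whereas at 298 K
chaotic collision dynamics of the stiff O–H modes ($\omega\,dt\approx0.33$)
cause shadow-energy diffusion of order $10^{-4}$–$10^{-3}$ relative even for
a perfect implementation — we measured this for the fixed-charge baseline
too.  At 100 K the baseline conserves to $\sim 3\times10^{-6}$ and the
dynamic-charge model to $\sim 6\times10^{-5}$ relative.  The residual factor
between them traces to the second-derivative seams of the $C^1$ cosine
cutoff in the descriptor kernels, crossed at thermal rates; making those
kernels $C^2$ would change the published functional form, so this is left as
a documented limitation.

## Problem sizes

The shipped tests use 2–10-molecule clusters for gradient checks, the
16-molecule box for conservation and periodic-gradient checks, 500×25 (train)
and 20×64 (transfer) molecule clusters for learning, and a 10-molecule
droplet for shell statistics — sizes chosen so the full suite runs in
minutes on one core while every code path (features, Jacobians, Ewald,
chain rule, thermostat, training loop) is exercised at full fidelity.

## Known limitations

* Orthorhombic cells only; no barostat (densities vs temperature are out of
  scope), no bond constraints (the model is intentionally flexible), no MPI
  parallelism — single-process by design.
* Charges are a direct map of the environment; there is no self-consistent
  charge equilibration, which is a feature (cost, stability) but means
  long-range polarization beyond the descriptor cutoff is absent.
* Predicted per-molecule net charges are not constrained; only the global
  neutralization shift is applied.
* The dielectric constant and melting point are not computed: both need
  simulation scales (and in the dielectric case, a resolution of the
  polarization-ambiguity of periodic dipoles) outside this package's remit.
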