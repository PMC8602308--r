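---
title: "Transition-state force fields: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-state force fields: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsforge)
```

# The model

`tsforge` treats a stereoselectivity-determining transition state as a
regular molecular-mechanics minimum. This is admissible because the
classical Hessian of a first-order saddle differs from that of a minimum in
exactly one eigenvalue; replacing that single negative eigenvalue with a
stiff positive value $\omega$ turns the saddle into a minimum *without
touching any other curvature or the geometry*. A force field fitted to such
modified quantum reference data can then be conformationally searched with
standard minimization machinery, and the Boltzmann-averaged energy gap
between the ensembles leading to the two enantiomeric products converts
directly into an enantiomeric ratio and excess.

The model rests on a Curtin–Hammett assumption: all pathways to both
products equilibrate rapidly relative to the product-forming step, so the
product ratio depends only on relative TS free energies. Systems where the
product-forming attack outruns isomer equilibration (the package's
validation tooling supports an exclusion tag for such cases) are outside
the model by construction, not by parameterization.

## Energy function

The MM energy is a deliberately compact MM3*-like form:

$$E = \sum_b \tfrac12 k_b (r - r_0)^2
    + \sum_a \tfrac12 k_\theta (\theta - \theta_0)^2
    + \sum_t \tfrac12\!\left[V_1(1{+}\cos\phi) + V_2(1{-}\cos 2\phi)
        + V_3(1{+}\cos 3\phi)\right]$$
$$\quad{} + \sum_{\mathrm{pairs}} \varepsilon\!\left[1.84\times10^{5}
        e^{-12\,r/r^{*}} - 2.25\,(r^{*}/r)^{6}\right]
    + \sum_{\mathrm{pairs}} \frac{1389.35\, q_i q_j}{\varepsilon_d\, r}$$

with $r$ in Å, $\theta$ in degrees, energies in kJ/mol, charges in e, and a
constant dielectric $\varepsilon_d = 1$ by default. Nonbonded sums run over
atom pairs separated by at least three bonds (1-2 and 1-3 excluded, 1-4
counted in full, the MM3 convention) and over pairs in different fragments.
Cross terms (stretch-bend), higher-order bond corrections and bond-dipole
electrostatics present in full MM3 implementations are intentionally
omitted: they are not needed to represent the structure of the fitting
problem, and every published detail the package's statistics depend on
survives the simplification. Combining rules, which the functional form
does not itself dictate, are geometric mean for $\varepsilon$ and
arithmetic mean for $r^*$.

The exp-6 curve has a spurious inner maximum below which it dives to
$-\infty$. The reduced turnover $x_c = r/r^* \approx 0.3096$ where
$dE/dr = 0$ on the repulsive branch is a universal constant of the form; it
is found once by root bracketing and cached. Below $x_c$ the potential
continues as a quadratic wall of reduced stiffness $10^6\,\varepsilon$,
value- and slope-continuous at $x_c$, so minimization cannot collapse
through the hole. The wall stiffness only needs to be "very steep"; its
value is otherwise inconsequential because no physically meaningful
configuration reaches it.

## Derivatives

Gradients are fully analytic (including the standard dihedral gradient
expressions); the Hessian is assembled by central finite differences of the
analytic gradient with a step of $10^{-4}$ Å and symmetrized as
$(H + H^\top)/2$. This trades a constant factor of speed for implementation
transparency at the ≤ 200-atom scale the package targets, and it is the
route the test suite cross-checks against a slower energy-only
finite-difference Hessian.

# Quantum-guided fitting

## The penalty

For each reference structure the residual vector concatenates, with
per-class weights:

* **internals** — bond lengths, angles and torsions of the MM-*relaxed*
  geometry (relaxation started from the reference geometry) minus the
  reference internals; torsion differences are wrapped to $(-180, 180]$;
* **Hessian** — the MM Hessian evaluated *at the reference geometry*,
  projected into the eigenbasis $V$ of the eigenvalue-modified reference
  Hessian, compared against the modified spectrum: diagonal entries target
  $\lambda_i'$, off-diagonal entries target zero. Working in the reference
  eigenbasis makes "compare Hessian eigenvalues" concrete and removes the
  rotational ambiguity of raw Cartesian elements;
* **charges** — force-field-assigned charges (per-type records override
  per-atom values) minus reference charges.

Default class weights — bond 100 Å⁻¹, angle 2 deg⁻¹, torsion 1 deg⁻¹,
Hessian diagonal and off-diagonal 0.03, charge 30 e⁻¹ — bring the classes
to comparable magnitudes on the package's toy fixtures. No theory fixes
them; all are configurable per fit and per structure.

## The replacement eigenvalue $\omega$

$\omega$ defaults to 4184 kJ mol⁻¹ Å⁻² — about 1 kcal/mol at a 0.032 Å
displacement — which is stiff enough to pin the reaction coordinate during
conformational search without numerically dominating the fit. In the
*synthetic* world the generator records the curvature of the mode it
negated (`ts_mode_eigenvalue`), and the recovery tests set
$\omega$ to that value: this makes the generating force field an exact zero
of the penalty, which is what turns parameter recovery into a
well-posed experiment with a known answer. For real quantum references no
such value exists and the default applies.

## Optimizer

Levenberg–Marquardt on the residual vector: forward-difference Jacobian
(relative step $10^{-4}$), damping adapted by a factor of 3, steps accepted
only when the penalty decreases (hence a non-increasing penalty trace),
a Nelder–Mead restart after five consecutive rejections, and convergence
when the relative penalty change stays below $10^{-6}$ for three accepted
iterations (cap: 100 iterations). Positivity-constrained parameters (force
constants, $\varepsilon$, $r^*$) are optimized in log space, so no step can
violate a force-field invariant. Parameters outside the fit vector are
never touched — the suite asserts bit-identity of the untouched records.

# Assembly

Templates declare their stereochemical meaning: each carries the product
configuration (R/S) and allyl isomer (exo/endo) that its pathway yields.
This bookkeeping is authored, not perceived — the package deliberately
contains no CIP machinery, so it stays agnostic about the chemistry encoded
in a template library.

Attachment places the fragment so its attachment bond is collinear with the
anchor's dummy bond at the equilibrium length of the new typed bond (1.5 Å
fallback), then resolves the residual rotation by a 30° scan refined
locally. The scan objective is a soft steric score of the new fragment
against the *original template core only*. Scoring against the full partial
assembly (e.g. its MM energy) would make the final geometry depend on the
order in which sites are filled, destroying the order-independence that
assembly should have; and the attachment torsion does not need to be the
true minimum anyway, because the Monte-Carlo search downstream re-relaxes
every torsion. A global 0.7 Å contact check still covers all atom pairs,
and an assembly where every scan point clashes is an error, not a warning.

# Conformational search

The search is torsional-only Monte Carlo: perturb up to 3 random rotatable
torsions of a random pool member by 30–180°, minimize, keep the candidate
if it lands within the energy window $W$ of the running best, deduplicate.
Two conformers are duplicates only when *both* the superposition RMSD is
below 0.25 Å *and* the energy difference is below 0.1 kJ/mol; mirror-image
conformers of equal energy are therefore kept distinct, as they must be
(the Kabsch superposition excludes reflections). Defaults: 40000 steps for
production use (the conventional figure for this problem class), window
21 kJ/mol ≈ 5 kcal/mol, far above thermal relevance at 298 K.

Two deliberate divergences from the Macromodel-style engine this emulates:
no low-mode (Hessian eigenvector) moves, whose benefit at fixture scale
does not justify the cost; and window-based rather than Metropolis
acceptance, because the goal is *collecting* every thermally relevant
conformer, not canonical sampling. Rotatable bonds exclude ring bonds,
terminal bonds and the forming bond — the reaction coordinate is never
driven.

All randomness flows from the integer seed in `search_options`; a fixed
seed reproduces ensembles bit-wise, and the caller's RNG state is restored.

# Selectivity

Ensemble scores use the overflow-safe log-sum-exp form
$G = E_{\min} - RT\ln\sum_i e^{-(E_i - E_{\min})/RT}$ with
$R = 8.314$ J mol⁻¹ K⁻¹ fixed and $T = 298.15$ K by default — the
temperature is exposed everywhere (including per validation record) because
literature reactions are run at many temperatures and the conversion
between ee and $\Delta\Delta G^\ddagger$ is temperature-dependent. The sign
convention is global: positive $\Delta\Delta G^\ddagger$, and hence
positive ee, means the S product is preferred. The ee carries its sign
internally; printed reports show unsigned ee plus the major configuration,
matching literature convention. Ties ($|ee| < 10^{-9}$) report "racemic".

# Proofreading

Experimental records convert to signed $\Delta\Delta G^\ddagger$ via
$RT\ln[(100+ee)/(100-ee)]$; an experimental ee of 100% is clamped to 99.9%
with a warning because the conversion is singular at 100. A record is
flagged as a suspected misassignment when the predicted and experimental
signs disagree *and* both selectivities are confident:
$\min(|ee_{\mathrm{pred}}|, ee_{\mathrm{exp}}) \ge$ 20% by default. The
threshold is exposed; 20% ee (≈ 1 kJ/mol at 298 K) separates "high but
opposite" from noise-level disagreement. Corrections invert the reported
configuration and are involutive. Reports carry both pre- and
post-correction MUE and R², computed on the non-excluded subset. R² is the
squared Pearson correlation (the coefficient of determination about the
identity line is a stricter alternative; Pearson² is the headline because
it is offset- and scale-invariant, which matches how such validations are
usually quoted).

# The synthetic world

The generators exist so that every algorithm above can be tested against a
known truth:

* `make_toy_ts_system` builds heavy-atom chains (4–20 atoms, one distinct
  type per position so every parameter is addressable) with jittered but
  chemically sensible magnitudes: stretches ~2000 kJ mol⁻¹ Å⁻² around
  1.5 Å, bends ~0.03 kJ mol⁻¹ deg⁻² around 112°, torsion barriers of a few
  kJ/mol, exp-6 wells of ~0.25 kJ/mol at ~3.4 Å, alternating charges.
* `mock_qm_reference` fabricates a "quantum" saddle by negating the
  eigenvalue of the Hessian mode that overlaps the forming-bond stretch.
  The fitting machinery cannot distinguish provenance, and truth is known
  exactly — which is the whole point for recovery experiments.
* `make_validation_fixture` draws true $\Delta\Delta G^\ddagger$ uniformly
  on ±12 kJ/mol, adds Gaussian prediction error (default SD 3.5 kJ/mol,
  chosen so the corrected MUE lands at the few-kJ/mol scale typical of
  well-behaved TSFF validations), and inverts the reported configuration
  for the planted misassignment ids. Planted records are forced to be
  confidently selective, and prediction noise that would turn a
  *non-planted* record into a confident sign mismatch is redrawn (bounded),
  so flagging recovers exactly the planted set for every seed. This
  censoring removes a percent-level tail of the error distribution — far
  inside the tolerance of the generator's statistical checks — and is the
  price of an exactly identifiable planted set.
* `make_mirror_ts_pair` assembles a planar template and its mirror image
  with the same achiral chain ligand: the two transition states are mirror
  images with identical energy landscapes, so any predicted |ee|
  materially above zero is a bug. This is the end-to-end chirality null.

What the synthetic world does **not** emulate: real DFT error structure,
basis-set artifacts, metal-specific valence effects, solvent beyond the
constant dielectric, or vibrational free-energy corrections (ensemble
energies are potential energies, standing proxy for
$\Delta\Delta G^\ddagger$). A green test establishes that the machinery is
correct, not that any particular chemistry is well described; the latter
depends entirely on the quantum reference data supplied to a real fit.

# Numerical choices, in one place

| quantity | value | note |
|---|---|---|
| Coulomb constant | 1389.35 kJ Å mol⁻¹ e⁻² | fixed |
| exp-6 constants | 1.84×10⁵, 12, 2.25 | fixed form |
| exp-6 wall | $x_c \approx 0.3096$, stiffness $10^6 \varepsilon$ (reduced) | collapse guard |
| Hessian FD step | $10^{-4}$ Å | of the analytic gradient |
| minimizer | BFGS, restart loop | RMS gradient ≤ 0.01 kJ mol⁻¹ Å⁻¹, 500 steps |
| $\omega$ | 4184 kJ mol⁻¹ Å⁻² | synthetic world: recorded truth curvature |
| LM | step $10^{-4}$, damping ×/÷3, rel. tol $10^{-6}$×3 | simplex fallback after 5 rejections |
| search | 40000 steps, window 21 kJ/mol | dedupe 0.25 Å ∧ 0.1 kJ/mol |
| thermodynamics | R = 8.314, T = 298.15 K | T exposed everywhere |
| flagging | min ee 20% | exposed |

# Known limitations

* No periodic systems, cutoffs or neighbor lists: all-pairs nonbonded sums
  limit practical size to a few hundred atoms.
* The Hessian is semi-numeric; fits with many parameters pay a Jacobian
  cost linear in the parameter count on top of that.
* Assembly resolves only the new-bond torsion; it does not embed or
  pre-relax the full complex (the conformational search does that).
* Stereochemical labels are trusted template metadata; nothing verifies
  them against the geometry.
* Regioselectivity of unsymmetric allyl termini, kinetic (non-Curtin–
  Hammett) regimes and per-conformer entropy corrections are out of scope.
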