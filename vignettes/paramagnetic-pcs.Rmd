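---
title: "Pseudocontact shifts as structural restraints: models, fitting and refinement in parashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudocontact shifts as structural restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parashift)
```

## The forward model

A paramagnetic centre with an anisotropic magnetic susceptibility shifts
the resonance of a nucleus at distance $r$ by the pseudocontact shift

$$\delta^{PC} = \frac{1}{12\pi r^3}\left[\Delta\chi_{ax}(3\cos^2\theta-1)
 + \tfrac{3}{2}\Delta\chi_{rh}\sin^2\theta\cos 2\Omega\right],$$

with $(r,\theta,\Omega)$ the polar coordinates of the metal$\to$nucleus
vector in the principal axis frame (PAF) of the traceless rank-2 tensor
$\Delta\chi$. The package fixes one unit convention throughout: $\Delta\chi$
in $10^{-32}\,\mathrm{m}^3$, distances in Å, shifts in ppm, so the
prefactor becomes $10^4/(12\pi)$. A purely axial tensor of
$\Delta\chi_{ax}=1$ then produces $+0.5305$ ppm on its $z$ axis at 10 Å.

Internally the same quantity is evaluated in Cartesian form,
$\delta = 3K\,v^{T}\chi v/r^{5}$ with $v$ the metal$\to$nucleus vector and
$\chi$ the full $3\times3$ tensor; the two code paths agree to $10^{-12}$
ppm and the Cartesian form makes the model *linear* in the five
independent tensor components — the key to exact fitting.

Contact shifts, residual anisotropic chemical shifts, and the temperature
dependence of $\Delta\chi$ are out of scope: the model is the point-dipole
PCS only, guarded by a 0.1 Å singularity radius.

### Tensor representations

`dchi_tensor` objects interconvert between the 5-component Cartesian form
and the PAF form ($\Delta\chi_{ax}$, $\Delta\chi_{rh}$, ZYZ Euler angles,
active rotations, degrees — the dominant convention in paramagnetic-NMR
software). On conversion the principal axes are assigned so that
$|\chi_{zz}|\ge|\chi_{yy}|\ge|\chi_{xx}|$. This convention determines
$\Delta\chi_{rh}$ only up to the $x/y$ axis swap, so the *sign* of the
rhombic component reported for a fitted tensor can differ from the sign
used to construct it while describing the identical tensor; no
unique-tensor-representation clamp ($|\Delta\chi_{rh}|\le\tfrac23\Delta\chi_{ax}$)
is enforced, and fitting always works in unconstrained component space.
Degenerate eigenvalues leave the orientation undetermined; conversion then
returns a canonical frame and raises a flag.

## Building PCS datasets

PCS are observed as chemical-shift differences between a paramagnetic
sample and a diamagnetic reference. `compute_pcs_dataset()` joins two
shift tables on `(residue_number, atom_name)` — residue *names* are
deliberately not part of the key, so cosmetically different naming
conventions still match (a mismatch warns). Keys present in only one
table are dropped with a log line and never penalised: near the metal,
paramagnetic relaxation enhancement (PRE) broadens peaks beyond detection,
so absence carries no structural information. Exchangeable imino/amino
protons (H1, H3, H21/H22, H41/H42, H61/H62) can be excluded for D2O
datasets. Pairing tables recorded in different solvents is refused by
default — the tensor itself changes between H2O and D2O solvation — and
permitted only with an explicit flag and a loud warning.

NOESY volumes are calibrated into the three conventional distance-restraint
classes with bounds strong 1.8–3.0 Å, medium 2.0–4.0 Å, weak 2.2–5.0 Å.
The volume thresholds (strong $V \ge 0.5V_{ref}$, medium
$0.1V_{ref} \le V < 0.5V_{ref}$, weak below) are the package's choice,
bracketing the ~2.4 Å reference distance by the $r^{-6}$ intensity law;
only the class *bounds*, not the cutoffs, are standard.

## Fitting tensors and the metal position

At a fixed site the model is linear: `fit_tensor_fixed_position()` solves
the five components by (optionally inverse-variance) weighted least
squares, exactly. Rank below five — e.g. all nuclei on one line through
the site — raises a degenerate-geometry error naming the null-space
dimension. At least five matched observations are required.

The metal position enters nonlinearly, so `fit_position_and_tensors()`
nests the problems: an outer search over the three site coordinates with
an inner exact linear solve per dataset, objective = summed weighted
squared residuals. Because the $r^{-3}$ dependence makes the objective
basin narrow, the outer stage is grid-first: a coarse lattice (default
2 Å spacing over the structure's bounding box inflated by 10 Å) followed
by Nelder–Mead refinement from the best node, polished until the step
falls below $10^{-4}$ Å. A surface flat to within $10^{-12}$ relative
across the box raises a non-identifiability error rather than returning
an arbitrary point. During the position search, observations within 5 Å
of the candidate site are down-weighted by 0.1: the closest shifts are
the most contaminated by unmodelled effects (contact contributions,
first-sphere dynamics). With several datasets the fit shares one site;
each dataset's joint-site Q is compared against a separately-optimised
site and a >2-fold degradation warns that the samples may not share a
binding site. Prochiral pairs (H5′/H5″, H2′/H2″) without
stereo-assignment can be declared ambiguous: each pair's two observations
are assigned to the two atoms in the permutation minimising their
residual sum, re-evaluated between search passes.

Fit quality is the Q-factor
$Q=\sqrt{\sum(\mathrm{obs}-\mathrm{calc})^2 / \sum \mathrm{obs}^2}$ —
no mean-centering, the normalisation used by the standard multi-tensor
fitting tools. Whether published Q values used uniform or $\sigma$
weighting is usually unstated; both are provided, uniform is the default.
`cross_validate()` refits on training folds and evaluates held-out
entries only (leave-one-out, k-fold, or a nucleus holdout such as `"^P"`
that keeps all phosphorus shifts out of training — the cross-validation
protocol used for ³¹P data). `mc_uncertainty()` is a parametric
bootstrap — Gaussian resampling of the PCS about the fitted values,
full refit, SD per parameter — and is labelled as such; jackknife
alternatives would be equally defensible.

## Refinement with PCS restraints

`pcs_energy_grad()` turns any number of datasets with fixed tensors and a
shared site into a flat-bottom pseudo-energy
$E=\sum_d\sum_i k\,\max(0, |\delta^{calc}_i-\delta^{obs}_i|-t)^2$ with
analytic gradients for every restrained nucleus and for the site (the
energy is exactly additive over datasets — the multi-sample contract).
Defaults: tolerance $t=0.05$ ppm, $k=1$ energy·ppm⁻²; both configurable.

In place of a molecular-dynamics engine, `refine_structure()` minimises
geometry + PCS energy by quasi-Newton (L-BFGS) steps using the analytic
gradients, run in short chunks whose accepted energies form a monotone
non-increasing trace. The geometry term is a harmonic template extracted
from a reference structure: atom pairs within 6 Å *inside the same rigid
group* (e.g. one helix) plus sequence-adjacent pairs across groups. This
deliberately mirrors the short-range character of NOE restraints — each
helix is held rigid, the mutual orientation of helices is left to the
PCS. The template is an honest simplification: it has no force field,
no electrostatics, no solvent, and supports method verification at desk
scale, not the production of publication structures. The metal site is a
free variable during refinement, coupled to the coordinates only through
the PCS terms.

`iterate_tensor_structure()` alternates tensor/site refitting on the
current coordinates with restrained minimisation at fixed tensors, the
standard protocol when the structure used for the initial fit is only
approximate. Convergence is declared when, between rounds, the relative
change of $\Delta\chi_{ax}$ and $\Delta\chi_{rh}$ is below 1 %, the PAF
rotation below 2° (computed modulo the 2-fold axis ambiguities of a
symmetric tensor), the site moves less than 0.1 Å and the coordinates
less than 0.05 Å RMSD. These thresholds are the package's choice, set
tighter than typical reported parameter uncertainties. An objective
rising over three consecutive rounds aborts with the trace.

## Ensemble analytics

`bundle_stats()` superposes every model pair by least squares (via
bio3d) on an explicit atom selection — reported in the output, since
published pairwise-RMSD values rarely state theirs — and returns the
mean pairwise RMSD plus, when a metal atom name is given, the metal
spread after superposition on the selection. `interhelical_angle()`
defines each helix axis as the first principal axis of its base-pair
C1′-midpoint series, oriented 5′→3′ along the first strand; this
atom-sparse definition works for both reduced synthetic structures and
real coordinates, and published angle conventions are rarely specified
anyway.

## The synthetic generator, and what it does not emulate

`make_helix()` builds idealised duplexes from a reduced six-atom
nucleotide template (P, C1′, a base-nitrogen proxy, three protons) by
pure helical symmetry (default rise 3.38 Å, twist 36°); paired C1′
midpoints fall exactly on the axis, which makes the helix-axis definition
exact on synthetic data. `make_junction()` assembles helices at
prescribed inter-axis angles and records the ground truth.
`plant_pcs()` evaluates the exact forward model at every proton, adds
Gaussian noise (default 0.02 ppm, a realistic shift-measurement
uncertainty), removes everything inside a PRE blind zone (default 7 Å,
the range where a lanthanide typically quenches peaks), and drops a
further random fraction (default 0.1, unassignable resonances). The
default planted tensor set spans axialities from −3.88 to +1.42 and mixed
rhombicity signs with four distinct orientations, so each emulated metal
produces a very different shift pattern. All randomness flows through
one explicit seed.

What passing tests on these data show: the estimators are exact on exact
data, unbiased under Gaussian noise, and robust to distance-censoring.
What they cannot show: robustness to contact-shift contamination near the
metal, to conformational averaging (the generator is rigid), to
assignment errors, or to realistic nucleotide chemistry — the reduced
atom set has no sugar pucker, grooves or sequence effects. Conclusions
about real spectra require real data.

## The with/without-PCS comparison

`pcs_benefit_experiment()` packages the central methodological claim —
long-range PCS restraints define interhelical geometry that short-range
data leave loose — as a paired, seeded experiment. A two-helix junction
(truth angle 113°) is perturbed by rigid rotations of the second helix
(SD 8°) plus 0.1 Å coordinate jitter, then refined from identical starts
with the local geometry template alone and with template + PCS. Because
the template contains no inter-helix terms beyond chain adjacency, the
no-PCS arm keeps whatever orientation the perturbation produced, exactly
as NOE-only bundles scatter; the PCS arm is pulled back to the planted
geometry. The experiment's restraint weighting differs from the package
defaults by design: tolerance 0 (the planted noise is Gaussian, so a
harmonic term is the matched treatment) and force constant 50, large
enough that the PCS term dominates the soft interhelical mode the
template leaves free. Scored over 20 seeds, the angle SD and the mean
pairwise bundle RMSD are both strictly larger without PCS; a one-sided
variance-ratio test at $\alpha=0.05$ confirms the spread reduction. This
is a scaled-down surrogate run on a harmonic template at desk scale — it
demonstrates the phenomenon's direction, not any particular published
angle spread.

## Binding and RDC auxiliaries

`bound_fraction()` solves the 1:1 mass-balance quadratic in the
cancellation-free form $2LM/(b+\sqrt{b^2-4LM})$, $b=L+M+K_d$ — naive use
of the quadratic formula loses all precision in the tight-binding limit.
At 700 μM : 700 μM and $K_d$ = 300 nM it gives 97.95 % of the metal
bound. `fit_kd_titration()` fits
$s = s_{free} + (s_{bound}-s_{free})\,f_{bound}$ by nonlinear least
squares with $K_d$ on a log scale; the signal is modelled as linear in
the *ligand's* bound fraction, since an oligonucleotide's CD response
reports on the DNA conformation, not the metal. Saturated designs (all
points $\ge 100K_d$) cannot constrain $K_d$ and warn. `max_rdc()`
converts a $\Delta\chi$ tensor into the maximal self-alignment residual
dipolar coupling,
$|D|_{max} = \frac{B_0^2}{15k_BT}\frac{\gamma_a\gamma_b\hbar}{8\pi^2r^3}\cdot 3|\lambda|_{max}$,
attained on a principal axis (CODATA constants, default 298 K, ¹H
gyromagnetic ratios). The spin pair and temperature behind any published
"expect ~X Hz" figure are usually unstated, so the function takes them
explicitly and claims order-of-magnitude comparability only: a ¹H–¹H
pair at 1.8 Å in a 16.44 T field with the largest default tensor gives
5.6 Hz.

## Numerical choices and problem sizes

* Forward model: Cartesian quadratic form; guard radius 0.1 Å; dual-route
  agreement asserted at $10^{-12}$ ppm.
* Linear solves: QR with explicit rank check; no normal equations.
* Outer site search: grid spacing 2 Å default; Nelder-Mead `reltol`
  $10^{-14}$, repeated until the move is below $10^{-4}$ Å.
* Minimisation: L-BFGS-B, chunked (25 iterations per trace point),
  `factr = 10`; a chunk that fails to decrease the energy is rejected and
  terminates the run.
* Test problems are deliberately small — 6–10 bp helices (72–120 atoms),
  8 bp junction pairs (~190 atoms), 20-seed Monte-Carlo loops, 100-seed
  Kd recovery — chosen so the full suite exercises every code path in a
  few minutes on one CPU while still leaving each statistical check
  well-powered.
* Bundle size for final-structure selection is a plain argument
  everywhere; published protocols disagree internally on such counts, and
  no default is asserted.

## Known limitations

The geometry template cannot produce chemically valid structures — it is
a verification harness. The PAF-angle bootstrap SDs become meaningless
near tensor degeneracy (the angles are then undefined). The NMR-STAR
reader handles the assigned-chemical-shift loop only, and the mmCIF
reader the `atom_site` loop only. PCS restraint files with and without
per-observation tolerances are both accepted (the `sigma` column is
optional and defaults to a single value), but per-restraint flat-bottom
widths are not yet plumbed into the energy, which uses one global
tolerance.
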