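# parashift

Pseudocontact-shift (PCS) analysis for lanthanide-bound nucleic acids:
dataset construction from chemical-shift tables, magnetic susceptibility
anisotropy (Δχ) tensor and metal-position fitting, Q-factor validation,
PCS-restrained structure refinement, and the auxiliary binding / RDC
calculations that accompany such studies.

## The problem

A paramagnetic lanthanide ion bound to a DNA or RNA molecule shifts the
resonances of every nucleus in its vicinity by an amount that depends on
the metal–nucleus distance and orientation:

```
δ_PC = 1/(12π r³) · [ Δχ_ax (3cos²θ − 1) + (3/2) Δχ_rh sin²θ cos2Ω ]
```

where (r, θ, Ω) are polar coordinates of the metal→nucleus vector in the
principal axis frame of the traceless susceptibility-anisotropy tensor
**Δχ**, parameterised by its axial (Δχ_ax) and rhombic (Δχ_rh) components.
Package-wide units: Δχ in 10⁻³² m³, distances in Å, shifts in ppm, which
folds the prefactor into 10⁴/(12π).

These long-range shifts are measured as differences between a paramagnetic
sample and a diamagnetic reference (e.g. Lu³⁺), and make excellent global
structural restraints: short-range NOE data define local geometry well but
leave the mutual orientation of helical elements loosely determined, while
PCS from several lanthanides pin them down. `parashift` implements the
full analysis loop for that experiment type, for structural biologists and
NMR spectroscopists working with metal-tagged oligonucleotides:

* **I/O** — PDB / mmCIF structures (multi-model), TSV and NMR-STAR v3
  chemical-shift tables, OpenDX scalar grids for isosurface display,
  NOESY volume → classed distance-restraint calibration.
* **Tensor fitting** — exact weighted linear least squares for the five
  tensor components at a fixed site; nested grid + simplex search for the
  shared metal position across several datasets; Q-factors,
  leave-one-out / k-fold / nucleus-holdout cross-validation, parametric
  bootstrap uncertainties.
* **Refinement** — flat-bottom PCS pseudo-energy with analytic gradients
  for any number of datasets sharing one site, a harmonic geometry
  template, quasi-Newton minimisation, and the iterative
  tensor-refit / structure-refine protocol.
* **Ensemble analytics** — all-pairs superposition RMSD, metal spread,
  interhelical angles from base-pair C1′ midpoints, and a paired
  with/without-PCS refinement experiment.
* **Binding & RDC** — closed-form 1:1 equilibrium, Kd fitting of
  titration curves, maximal self-alignment RDC prediction.
* **Synthetic data** — idealised reduced-atom duplexes and multi-helix
  junctions with planted tensors, Gaussian noise and PRE-style censoring,
  so every stage is testable against known ground truth.

All user-facing functions take and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(parashift)

# a synthetic two-helix junction with a planted metal site and four tensors
junction <- make_junction(list(
  list(n_bp = 8),
  list(n_bp = 8, direction = c(sin(113*pi/180), 0, cos(113*pi/180)), gap = 8)))
site <- c(4, 3, 33.7)
datasets <- plant_pcs(junction, site, noise_sigma = 0.02,
                      blind_radius = 7, missing_fraction = 0.1, seed = 1)

fit <- fit_position_and_tensors(datasets, junction)
fit
#> <pcs_joint_fit> shared site = (4.42, 3.13, 33.66) A, objective = 0.1297
#>   Ce   dchi_ax = +0.979 dchi_rh = +0.541  Q = 0.2914  n = 89
#>   Eu   dchi_ax = +1.378 dchi_rh = +0.632  Q = 0.2722  n = 85
#>   Tm   dchi_ax = -3.885 dchi_rh = -1.505  Q = 0.0925  n = 89
#>   Yb   dchi_ax = -2.686 dchi_rh = -1.244  Q = 0.3123  n = 76
```

The fitted axial/rhombic anisotropies (units 10⁻³² m³) recover the
planted values — Tm, planted at (−3.88, 1.62), comes back as
(−3.885, −1.505); the rhombic sign difference is the reporting
convention, which orders principal axes by eigenvalue magnitude and so
fixes Δχ_rh only up to an x/y axis swap. The shared metal position is
found to ~0.4 Å at this noise level, and the per-metal Q-factors —
`sqrt(Σ(obs−calc)²/Σobs²)` — reflect the 0.02 ppm shift noise against
the many small far-from-metal shifts in the data. On noiseless input the
same call recovers the site to < 0.01 Å and the tensors to 1e-6 relative
(that exactness is what the test suite asserts). `tidy(fit)` returns the
same numbers as a tibble, `autoplot(fit)` draws the
observed-vs-calculated correlation.

The auxiliary calculations print directly:

```r
100 * bound_fraction(700e-6, 700e-6, 300e-9)   # 97.95  (% metal bound)
pcs_forward(dchi_paf(-3.88, 1.62), c(0,0,0), c(0,0,25))  # -0.1317 ppm
max_rdc(dchi_paf(-3.88, 1.62), r = 1.8, B0 = 16.44)      # 5.57 Hz
```

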