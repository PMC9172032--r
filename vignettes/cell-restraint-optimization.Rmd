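---
title: "Restraint-based unit-cell optimization: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based unit-cell optimization: model, algorithms and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfit)
```

## The model

A crystal structure model consists of a unit cell (lengths $a,b,c$ in Å,
angles $\alpha,\beta,\gamma$ in degrees) and atoms at fractional
coordinates $x$. The Cartesian distance between two atoms follows from the
real-space metric tensor

$$G = \begin{pmatrix} a^2 & ab\cos\gamma & ac\cos\beta \\
ab\cos\gamma & b^2 & bc\cos\alpha \\
ac\cos\beta & bc\cos\alpha & c^2 \end{pmatrix},
\qquad d^2 = \Delta x^\top G\, \Delta x .$$

Working through $G$ makes every distance — and therefore the whole
objective — independent of the orthogonalization convention. The
convention (here: $a$ along the first Cartesian axis, $b$ in the first
coordinate plane) only matters when Cartesian coordinates are exported,
e.g. by `write_pdb()`.

In electron diffraction the cell parameters are strongly correlated with
the detector distance, so a model can have good fractional coordinates on
top of a systematically mis-scaled cell. Because bond geometry in organic
molecules is highly conserved, 1,2 and 1,3 distance restraints (SHELX
`DFIX`/`DANG`, targets $\Delta_R$, weights $\sigma_R$ with defaults
0.02/0.04 Å) carry enough information to correct the cell. `cellfit`
minimizes, over the free cell parameters and at *fixed* fractional
coordinates,

$$T(\text{cell}) \;=\; \sum_R \frac{1}{\sigma_R^2}\,
\bigl(d_R^2 - \Delta_R^2\bigr)^2 ,$$

the squared-distance comparison that avoids the modulus and differentiates
cleanly:

$$\frac{\partial T}{\partial \tau} \;=\; \sum_R \frac{2}{\sigma_R^2}
\bigl(d_R^2 - \Delta_R^2\bigr)\; \Delta x^\top
\frac{\partial G}{\partial \tau} \Delta x ,$$

for $\tau \in \{a,b,c,\alpha,\beta,\gamma\}$. A `form = "least_squares"`
switch selects the conventional $\sum \sigma_R^{-2}(d_R-\Delta_R)^2$
instead. For a single restraint both forms attain their minimum at the
same cell along any one-parameter family (a tested property), and for
uniform $\sigma$ the argmin is unaffected by whether "inverse variation"
weighting is read as $1/\sigma$ or $1/\sigma^2$; the switch covers both
readings. Deviation *reports* always use the signed $d-\Delta$ in Å so
they read as geometry deviations.

Angles are degrees at every external interface (including the free-vector
and gradient components); conversion to radians happens exactly once,
inside the metric-tensor code.

## Crystal-system constraints

Optimization respects the declared lattice class by mapping a reduced free
vector onto all six parameters: fixed angles are written bit-for-bit as
90/120 and tied lengths are copied, so constraint satisfaction after
optimization is exact, not approximate:

| system | free parameters | count |
|---|---|---|
| triclinic | $a,b,c,\alpha,\beta,\gamma$ | 6 |
| monoclinic | $a,b,c,\beta$ | 4 |
| orthorhombic | $a,b,c$ | 3 |
| hexagonal | $a,c$ ($a{=}b$, $\gamma{=}120^\circ$) | 2 |
| tetragonal | $a,c$ ($a{=}b$) | 2 |
| cubic | $a$ | 1 |

Tied parameters accumulate their gradient contributions; fixed ones are
absent from the gradient. The monoclinic count is 4: the constraints
$\alpha=\gamma=90^\circ$ leave four parameters genuinely free, although
tool tables sometimes print 3 for this row; we found no parameter that
could consistently be dropped and therefore implement 4.
Rhombohedral/trigonal lattices are handled in the hexagonal setting. A
user can always relax to triclinic ("P1 relaxation") to validate the
assumed crystal system: on a true orthorhombic fixture all six parameters
refine back to angles within $0.05^\circ$ of 90 (tested).

No minimum-image or periodic wrapping is applied: SHELX restraints name
their atom pairs explicitly within the model, so the listed coordinates
are used literally.

## Drivers

**BFGS (default).** Quasi-Newton minimization over the free vector with
the analytic gradient (`stats::optim`), followed by a damped Newton polish
(finite-difference Hessian of the analytic gradient, backtracking line
search) because `optim` does not expose a gradient-norm stopping rule. The
default tolerances — gradient norm $10^{-6}$, and $10^{-4}$ Å / $10^{-3}$°
cell change for the alternation below — sit an order of magnitude below
the method's meaningful precision and are exposed as arguments. Only local
minima are found; invalid trial cells (non-positive-definite metric) are
penalized rather than raised so line searches back off gracefully.

**Hill climbing.** The derivative-free alternative mirrors a systematic
coordinate search: each free parameter is tried at $\pm$ the current step
(initially 0.1 Å or 0.1°), trial cells are scored by the weighted mean
absolute deviation $\sum w_R |d_R - \Delta_R| / \sum w_R$ with $w_R =
1/\sigma_R$, and only the single best strictly-improving modification per
round is kept. A round without improvement halves the step; ten
consecutive improvement-free cycles abort. Whether a halving resets the
no-improvement counter is a genuinely open choice; here halvings *count*
toward the ten, and any accepted improvement resets the counter.
Tie-breaks are deterministic (parameter order $a,b,c,\alpha,\beta,\gamma$,
"+" before "−"), and an epsilon guard ($10^{-9}$ relative) keeps
floating-point near-ties — e.g. a symmetric overshoot around the optimum —
from counting as improvements, which preserves the textbook step schedule
exactly.

Two caveats of this criterion are worth knowing. It is piecewise linear,
so single-parameter moves can stall at kinks or crawl along narrow
diagonal valleys when parameters are strongly coupled through oblique
restraints; a documented `max_rounds` cap (20 000) bounds the runtime and
reports `step_exhausted`. And it is not the BFGS objective: the two
drivers agree to machine precision when the hill climb is forced onto the
smooth squared criterion (`criterion = "objective"`, the setting used by
the driver-agreement tests), while with its native criterion agreement is
only as good as the valley geometry allows.

## Alternating cell and coordinate optimization

Refining coordinates against diffraction data is the job of an external
program (e.g. SHELXL); this package deliberately reproduces only the
*mechanism* of the alternation:

1. optimize the cell at fixed coordinates;
2. refine the coordinates at the fixed new cell;
3. repeat until the cell change drops below tolerance or 25 iterations.

Step 2 is pluggable. The tested default is the internal restraint-only
regularizer: the same objective minimized over the fractional coordinates
of restrained atoms, with unrestrained atoms untouched. Distances fix a
geometry only up to rigid motion, so the gauge is fixed by removing the
net translation (the centroid of the restrained atoms is preserved);
orientation is left to the optimizer's continuity. An external refiner is
invoked through a command template with `{in}`/`{out}` placeholders
receiving and returning RES files; a nonzero exit or unparseable output
stops the iteration with a partial trace and a warning rather than being
swallowed. **The internal mode is not a substitute for data-driven
refinement** — it regularizes geometry against the same restraints the
cell step uses, which is exactly what makes noise-free synthetic fixtures
converge jointly, but on real data an external refiner should close the
loop. A combined mode in which an external score (e.g. wR2) selects cell
modifications is possible only when the refiner reports one (`REM
CELLFIT_SCORE` in its output); with restraints alone there is no such
independent score, so the two-step mode is the default.

## The synthetic-data generator

Every test and validation quantity draws its ground truth from
`generate_fixture()`: a template molecule (planar hexagonal ring, bond
1.39 Å; methane-like tetrahedron, bond 1.54 Å; tetrahedral-angle zigzag
chain) is placed at the centre of a known true cell; 1,2 restraints are
derived from distance-based bonding and 1,3 restraints from pairs sharing
a bonded neighbour, with targets equal to the true distances; the cell is
then perturbed multiplicatively on the system's free parameters (random
sign, full amplitude — "5%" means exactly ±5% per parameter). Optional
Gaussian noise on restraint targets and/or Cartesian coordinates models
imperfect restraint dictionaries and imperfect models. The only randomness
in the package lives here, under an explicit seed that leaves the caller's
RNG stream untouched; the drivers are fully deterministic.

Numerical exactness is engineered in deliberately: fractional coordinates
are quantized to the 8 decimals written into the RES text *before* the
restraint targets are measured, and targets are printed with 17
significant digits, so a zero-noise fixture is satisfied at the true cell
to ~$10^{-26}$ in the objective even after a text round trip. This is what
lets recovery tests assert $10^{-3}$ Å — and often observe $10^{-14}$ Å —
without fighting formatting noise.

What the generator does *not* emulate: diffraction intensities and their
errors, disorder, wrong restraint assignments, libration, or crystal
packing (a single molecule per cell, no symmetry mates). Passing the
recovery tests therefore demonstrates the estimator's correctness and
conditioning, not that a particular real data set will improve.

Two scaling facts shape the chosen study conditions:

* **Noise amplification.** A relative error in a restrained distance maps
  to the same relative error in the cell, so the absolute cell error is
  $\sim \ell \,\sigma_{\text{noise}} / d$ for cell length $\ell$ and
  restraint length $d$. The noisy-recovery study (restraint noise 0.01 Å,
  50 seeds, median error < 0.05 Å) consequently uses a 6–8 Å cell that a
  ~2.5 Å molecule packs realistically — typical small-molecule axes are of
  this order — rather than a sparse 30 Å box, where the same noise must
  produce ~0.12 Å errors for purely geometric reasons.
* **Directional observability.** Restraints inform a cell axis only if
  some restrained pair has a coordinate difference along it. A planar
  ring lying in the $a$–$b$ plane leaves $c$'s gradient identically zero:
  $a$ and $b$ recover while $c$ stays at its starting value. The manifest
  flags such unobservable parameters, and the degeneracy is asserted as a
  property, mirroring the flat-molecule caveat that practitioners must
  weigh before trusting an optimized cell.

## File format

The SHELX reader handles the subset the optimizer needs — `CELL`
(wavelength + six parameters), `SFAC`, `RESI` scoping, `DFIX`/`DANG` with
optional sigma and multi-pair expansion, atom records, continuation lines,
and `+filename` includes — and preserves everything else verbatim, so
`parse → write → parse` is exact (property-tested, including includes and
residue scoping). Restraint references without a `_n` qualifier resolve
inside the residue scope current at their line first, then globally;
ambiguous names are an error rather than a guess. The SHELX
fixed-parameter convention ($|v| \ge 5$ decodes to $v-10$) is honoured;
free-variable arithmetic (FVAR multipliers $\ge 2$) and symmetry-equivalent
references (`$n`) are rejected with explicit messages rather than
mis-resolved — they are out of scope in this version. Writing replaces
only the `CELL` line (plus one provenance comment) and reformats only atom
records whose coordinates were actually changed.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated
fixtures: 5–6-atom molecules with 10–12 restraints, ~120 random
configurations for the gradient–finite-difference comparison across all
six crystal systems, 50 seeds for the noisy-recovery median, and single
fixtures for the closed-form, degeneracy, scheduling and round-trip
checks. These sizes keep the full validation in the tens of seconds while
exercising every code path; the estimator itself is $O(\text{restraints})$
per evaluation and handles larger models without modification.

## Known limitations

* Restraints must span a direction for the cell to be correctable along
  it; flat molecules and missing-wedge geometries limit what can be
  recovered (flagged, not fixed).
* The hill climb's native criterion can stall at kinks; use BFGS (the
  default) when in doubt.
* Only local minima are found; a start within a few percent of the truth
  is assumed, which matches the detector-distance error regime.
* Inorganic/disordered structures with genuinely variable geometry violate
  the conserved-restraint premise; restraint-based cell correction is then
  inappropriate regardless of implementation.
* `SADI`, `FLAT`, `CHIV` and other restraint types pass through unused;
  only explicit distance restraints drive the objective.
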