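# cellfit

Restraint-based optimization of crystallographic unit-cell parameters for
small-molecule structure models, aimed at electron-diffraction (MicroED /
3D ED) data.

## The problem

A diffraction experiment determines the unit-cell constants *a*, *b*, *c*,
α, β, γ together with the reflection intensities. With electrons the
wavelength is extremely short (0.0251 Å at 200 keV), so the diffraction
angles are tiny and the cell parameters correlate almost perfectly with the
detector distance — which is hard to calibrate reliably on a transmission
electron microscope. The result is a structure whose *fractional* model is
good but whose cell (and hence every bond length and angle computed from
it) carries a systematic scale error of a percent or more.

Organic molecules, however, have highly conserved bond geometry. `cellfit`
turns that prior knowledge around: holding the fractional coordinates
fixed, it adjusts the cell so that the inter-atomic distances recomputed
under the trial cell best match idealized 1,2 (bonded) and 1,3
(angle-defining) distance restraints — the SHELX `DFIX` and `DANG`
instructions, with their default weights σ = 0.02 Å and 0.04 Å.

## The objective

For fractional difference Δx of a restrained atom pair, the distance under
a cell with metric tensor *G* is d = √(Δxᵀ G Δx), and the default target
function is

    T(cell) = Σ_R  (1/σ_R²) · (d_R² − Δ_R²)²

summed over all restraints with targets Δ_R. Squared distances avoid the
modulus and give simple analytic derivatives via ∂(d²)/∂τ = Δxᵀ (∂G/∂τ) Δx
for each cell parameter τ; a `form = "least_squares"` switch selects the
conventional Σ σ⁻²(d − Δ)² instead (both share their minima along
one-parameter families). Minimization runs over the *free* parameters of
the declared crystal system only — triclinic 6, monoclinic 4 (a, b, c, β),
orthorhombic 3, hexagonal 2, tetragonal 2, cubic 1 — with fixed angles held
at exactly 90°/120° and tied lengths exactly equal. Two drivers are
provided: BFGS with the analytic gradient (default) and a multi-level hill
climb (±0.1 Å/° steps, best single modification per round, step halving,
abort after ten improvement-free cycles) scored by the weighted mean
absolute deviation. An iterative mode alternates cell optimization with a
coordinate-refinement step (internal restraint-only regularizer, or any
external refiner via a command template), capped at 25 alternations.

## Worked example

Ground truth is known here because the fixture generator builds it: a
tetrahedral molecule placed in a true 10 × 20 × 30 Å orthorhombic cell,
restraints set to the true distances, and the cell then mis-scaled by ±5%
per axis — the signature detector-distance error.

```r
library(cellfit)

fx  <- generate_fixture("orthorhombic", unit_cell(10, 20, 30),
                        molecule = "tetrahedral", seed = 7,
                        cell_perturbation = 0.05)
fit <- cellfit(fx$structure, system = "orthorhombic")
fit
#> cell optimization against 10 distance restraints (orthorhombic system, bfgs driver)
#> start:     unit cell: a=10.5000 b=19.0000 c=28.5000  alpha=90.0000 beta=90.0000 gamma=90.0000  V=5685.7500 A^3
#> optimized: unit cell: a=10.0000 b=20.0000 c=30.0000  alpha=90.0000 beta=90.0000 gamma=90.0000  V=6000.0000 A^3
#> objective 529.366 -> 2.95823e-27; weighted mean |dev| 0.03253 -> 0.00000 A; converged

coef(fit)
#>     a     b     c alpha  beta gamma
#>    10    20    30    90    90    90
```

The perturbed start (10.5, 19.0, 28.5) is pulled back onto the generating
cell; the weighted mean absolute deviation of the restraints drops from
0.033 Å to zero. `summary(fit)` lists per-restraint deviations (d − Δ, in
Å), `residuals(fit)`/`fitted(fit)` expose them numerically, `plot(fit)`
shows the convergence trace, and `write_res(fit$structure, new_cell =
fit$cell, path = ...)` writes a SHELX file with the new cell for further
refinement. Real RES/INS files are read with `read_res()`, including
`RESI` residue scoping and `+filename` restraint includes.

A command-line front end with the same crystal-system flags
(`-xa -xm -xo -xh -xt -xc`) lives at `inst/cli/cellfit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cellfit.R", package = "cellfit"))')" \
    -xo --log trace.csv --report dev.tsv model.res
```

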