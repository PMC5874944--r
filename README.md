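# gridtr

Radiobiological modelling of **grid therapy** (spatially fractionated
radiotherapy, SFRT) — the treatment of advanced bulky tumours through a
perforated block that converts an open megavoltage field into a lattice of
pencil-beam-like high-dose channels. The package is for medical physicists
and radiobiology modellers who want to ask, quantitatively: *which tumours
benefit from a grid field, and how much does the collimator geometry
matter?*

## The model

A radial dose profile `D(r)` under one grid hole (generated by a
parameterised surrogate — plateau, error-function penumbra, ~22%
valley-to-peak — or read from CSV) is decomposed into concentric rings of
0.1 mm; with uniform cell density, ring *i* holds the area fraction
`V_i = (r_{i+1}² − r_i²)/r_max²` of the cells, where `r_max` is half the
hole centre-to-centre spacing. Survival under the grid field is the mixture

    SF_grid = Σ_i V_i · SF(D_i),

with per-ring survival from the linear-quadratic model
`SF(D) = exp(−αD − βD²)` (parameters derived in closed form from a cell
line's SF2 and α/β ratio) or the Hug–Kellerer high-dose model
`SF(D) = exp(−k₁D + k₂(1 − e^(−k₃D)))`. The **equivalent uniform dose**
solves `SF_tumor(EUD) = SF_tumor,grid`, and the **therapeutic ratio**

    TR = SF_normal(grid) / SF_normal(EUD)

measures normal-tissue sparing at iso-tumour-effect (TR > 1 favours the
grid). EUD-matched sweeps over hole diameter and spacing, and bundled
clinical grid-therapy response tables, complete the analysis.

## Worked example

Therapeutic ratio of the reference block (1.0 cm holes, 1.8 cm spacing) at
a 20 Gy peak for a radioresistant tumour (SF2 = 0.5, α/β = 10 Gy):

```r
library(gridtr)
profile <- make_single_hole_profile(grid_geometry(1.0, 1.8), peak_dose = 20)
therapeutic_ratio(profile, cell_lines("radioresistant"))
#> Therapeutic ratio (LQ model), peak dose 19.99 Gy
#>   SF_tumor(grid)   = 0.05668
#>   EUD              = 6.153 Gy
#>   SF_normal(grid)  = 0.01166
#>   SF_normal(EUD)   = 0.004425
#>   TR               = 2.635
```

Read bottom-up: under the grid field 5.7% of tumour cells survive — the
same kill a uniform 6.15 Gy fraction would give — while 1.17% of normal
cells survive, versus 0.44% under that uniform dose. The grid therefore
spares normal tissue by a factor 2.6 at equal tumour effect. Repeating
this for a radiosensitive line (SF2 = 0.2) gives TR ≈ 0.95: spatial
fractionation only pays off for radioresistant tumours.

The bundled clinical records point the same way — reported grid-therapy
response rises with tumour SF2:

```r
fit_linear_response(load_clinical_table(), "sf2")
#> slope 146.0, r 0.47, n 21
```

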