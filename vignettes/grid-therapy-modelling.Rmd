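---
title: "Radiobiological modelling of grid (spatially fractionated) radiotherapy"
author: "gridtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiobiological modelling of grid radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridtr)
```

## The problem

Grid therapy (spatially fractionated radiotherapy, SFRT) treats advanced
bulky tumours by replacing a uniform megavoltage field with a lattice of
pencil-beam-like high-dose channels, formed by a perforated lead or Cerrobend
block (typically 1.0 cm holes on a 1.8 cm hexagonal centre-to-centre
lattice). Tissue directly under a hole receives the full prescription dose
(10–20 Gy in a single fraction); tissue between holes receives only the
valley dose, about 22% of the peak at 5 cm depth for the reference block.
The clinical question this package addresses quantitatively: *which tumours
benefit from such a field, and how does the collimator geometry matter?*

`gridtr` computes, for any combination of tumour radiosensitivity, peak
dose, survival model and hole geometry:

* the surviving fraction of tumour and normal cells under the non-uniform
  grid field,
* the **equivalent uniform dose** (EUD): the uniform single-fraction dose
  producing the same tumour survival as the grid field,
* the **therapeutic ratio** (TR): normal-tissue survival under the grid
  field divided by normal-tissue survival under a uniform field at the EUD.
  TR > 1 means the grid spares normal tissue at iso-tumour-effect.

## The dose model

The paper-scale input is a radial dose profile under a single grid hole at
depth. Transport-calculated profiles are not desk-reproducible, so the
package generates a parametric surrogate with three interpretable knobs
(`profile_model_params()`):

$$D(r) = P\left[v + (1-v)\,\tfrac12\,
  \operatorname{erfc}\!\frac{r-a}{\sigma\sqrt2}\right],$$

a plateau at the peak dose $P$ inside the hole radius $a$, an error-function
penumbra of width $\sigma$ centred on the hole edge (so the dose at $r=a$ is
exactly $P(1+v)/2$), and a flat valley at $v \cdot P$ out to
$r_{\max} = \text{spacing}/2$, the radius of the circular tissue region
attributed to one hole. Defaults are frozen as the *canonical* field:
$v = 0.22$ (the reported valley-to-peak ratio of the 1.0 cm / 1.8 cm block
at 5 cm depth), $\sigma = 1.5$ mm (a typical collimated 6 MV penumbra
scale), sampled every 0.1 mm. Measured profiles can be supplied instead via
`read_profile_csv()` (`r_mm,dose_Gy`).

What the surrogate deliberately does **not** model: depth dependence of the
valley fraction, the dose build-back near $r_{\max}$ from neighbouring holes
(the surrogate is monotone non-increasing), scatter tails, and
geometry-dependent valley/penumbra when the hole diameter or spacing is
swept — in sweeps $v$ and $\sigma$ are held constant, where a transport
calculation would give each geometry its own values. Consequences of these
simplifications are discussed under *Fidelity* below.

## Survival models

**Linear-quadratic (LQ).** $SF(D) = e^{-\alpha D - \beta D^2}$. Cell lines
are specified by their surviving fraction at 2 Gy (SF2) and $\alpha/\beta$
ratio; `derive_lq_params()` inverts $SF2 = e^{-2\alpha - 4\beta}$ in closed
form. Tumours use $\alpha/\beta = 10$ Gy, late-responding normal tissue
SF2 = 0.4 at $\alpha/\beta = 2.5$ Gy. The three radiosensitivity classes are
SF2 = 0.2 (radiosensitive), 0.4 (semisensitive) and 0.5 (radioresistant);
published per-histology SF2 values ship in `cell_lines()`.

**Hug–Kellerer (H-K).** $SF(D) = e^{-k_1 D + k_2(1 - e^{-k_3 D})}$, a
three-parameter model with a shallower high-dose shoulder than LQ (LQ is
known to underestimate survival above ~12 Gy). `fit_hk_params()` ties
$(k_1,k_2,k_3)$ to an LQ line by three constraints:
$k_1 - k_2 k_3 = \alpha$,
$k_2 k_3^2 (\ln 2 - \tfrac12)/(\ln 2)^2 = \beta$, and exact SF2 agreement at
2 Gy. Eliminating $k_1$ and $k_2$ leaves one scalar equation whose unique
positive root is $k_3 = \ln(2)/2 \approx 0.3466$ Gy$^{-1}$ for *every* cell
line — the peculiar $(\ln 2 - \tfrac12)/(\ln 2)^2$ factor in the $\beta$
relation is exactly what makes the 2 Gy crossing consistent. The solver
locates the root by bracketed bisection (`uniroot`, tolerance 1e-14) rather
than a 3-D Newton iteration, because the reduction is exact; residuals of
all three constraints are verified below 1e-9 and an independent 3-D
grid-search + Nelder–Mead minimiser reproduces the same parameters in the
test suite.

A structural consequence worth stating prominently: with this
parameterisation the two models cross at 2 Gy and then separate quickly —
H-K survival exceeds LQ by large factors at 15–20 Gy. LQ/H-K agreement
within ~1% therefore holds only below about 2 Gy, and therapeutic ratios
computed under the two models differ appreciably at high peak dose (about
10–32% at 20 Gy across the three classes on the canonical field, as the
acceptance script measures). Any published claim of near-identity of the
two models at such doses must rest on a different (unstated) H-K fitting
procedure; under the constraint set above, the separation is exact
arithmetic, not a numerical artefact.

## From profile to therapeutic ratio

The disc under one hole is decomposed into concentric rings of 0.1 mm
(`ring_weights()`); with uniform cell density the relative cell number in
ring $i$ is the area fraction $V_i = (r_{i+1}^2 - r_i^2)/r_{\max}^2$, and
each ring is assigned the profile dose at its mid-radius (second-order
accurate; the spec-level statement that rings see "nearly identical dose"
leaves the representative value open, and the midpoint is the natural
choice). The grid survival is the mixture
$SF_{\text{grid}} = \sum_i V_i\,SF(D_i)$.

The EUD solves $SF_{\text{tumor}}(\text{EUD}) = SF_{\text{tumor,grid}}$:
for LQ the unique positive root of
$\beta E^2 + \alpha E + \ln SF = 0$ (both coefficients positive), for H-K a
bracketed bisection of the strictly decreasing survival curve; both are
verified to 1e-9 in dose. Finally
$TR = SF_{\text{normal,grid}} / SF_{\text{normal}}(\text{EUD})$.

Numerical choices: 0.1 mm rings are converged — halving the ring thickness
or the profile sampling step moves any survival fraction by < 0.1%, and the
ring sum agrees with a 20 001-point trapezoid integration of
$SF(D(r))\,2r/r_{\max}^2$ within 0.5% on random profiles. A uniform field
(`valley_fraction = 1`) gives TR = 1 to machine precision for every cell
line, a useful end-to-end identity.

## Geometry sweeps

`sweep_hole_diameters()` and `sweep_spacings()` implement the design study:
vary one geometric parameter, and for each geometry rescale the peak dose by
bracketed root-finding (`match_peak_dose_to_eud()`, forward-verified to
1e-6 Gy) so the tumour EUD stays at the reference value — the EUD of the
canonical 1.0 cm / 1.8 cm field at the widely used 15 Gy prescription. The
sweep tumour defaults to the radioresistant class, since the design question
concerns bulky radioresistant disease; this is configurable. The reported
optimum is the set of designs within 1% of the maximum TR, which avoids
knife-edge ties from discretisation. On the canonical surrogate the
diameter sweep peaks at 1.25 cm (with 1.0 cm close behind) and the spacing
sweep peaks at 1.8 cm; the TR variation across spacings 1.6–2.2 cm is
larger on the surrogate (~16% of the mean) than the ±4% a transport-based
profile set yields, because the constant-valley assumption exaggerates the
effect of enlarging $r_{\max}$.

## Clinical correlation

`load_clinical_table()` bundles per-study total response rates of grid
therapy by histology together with published SF2 values, joined on
histology (one record per study; "SCC of H&N" joins to SCC). Records
missing either field (parotid response unreported; maxillary sinus without
a published SF2) carry `NA` and are excluded from fits; responses reported
only as lower bounds are stored at the bound with a `">"` qualifier.
`fit_linear_response()` regresses response on SF2, or on TR computed at a
15 Gy peak from each record's SF2. Both slopes are positive on the bundled
data — clinically, grid therapy has responded best in radioresistant
(high-SF2) histologies — but with 21 usable study-level records and
heterogeneous doses (10–20 Gy across studies) these fits are descriptive,
not inferential.

## Fidelity and limitations

* The surrogate's sharp penumbra and flat valley overweight the fully
  spared valley region relative to a transport-calculated profile. TRs for
  the radiosensitive and semisensitive classes reproduce reference values
  within ±0.15, while radioresistant TRs run high (e.g. 2.64 at 20 Gy where
  profile-based reference calculations give 2.28) — high-SF2 lines are the
  most sensitive to the valley dose distribution. The 15 Gy semisensitive
  EUD comes out at 4.73 Gy against a reference 4.41 Gy. Supplying a
  measured profile CSV removes this surrogate error.
* The single-hole circular approximation ignores the hexagon/circle
  coverage deficit and inter-hole scatter, as the standard ring-decomposition
  treatment does.
* Single-fraction analysis only: no fractionation, repopulation, or
  chemoradiation scheduling; no organ-specific normal-tissue models.
* Passing property tests on synthetic profiles shows the machinery is
  correct (tiling, inversion, monotonicity, oracle agreement); it does not
  validate the surrogate against any particular machine's measured field.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
every quantity discussed here from scratch: the LQ parameter table, the TRs
of the three classes at 10/15/20 Gy, the 15 Gy EUD, the LQ/H-K TR
disagreement at 20 Gy, and the SF2 = 0.55 TR at 15 Gy, using the canonical
field (90 rings of 0.1 mm on [0, 9] mm). All problem sizes in the test
suite (25–50 random profiles, 1000 parameter round-trips, an 18³
grid-search oracle) were chosen as the smallest sizes at which the checked
tolerances are stable.
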