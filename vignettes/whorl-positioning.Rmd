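---
title: "Positioning the lateral-organ initiation zone: model, geometry, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning the lateral-organ initiation zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whorlpos)
```

## The problem

Conifer embryos initiate a variable number of cotyledons (`n_c`, commonly 2
to 10) in a single whorl around the shoot tip. The whorl's radius — the
distance from the tip at which organs arise — varies roughly three-fold
across embryos, and `n_c` tracks that radius: at a fixed inter-cotyledon
spacing, a larger ring simply fits more organs. Molecularly, the initiation
zone is the trough between two mutually inhibitory expression domains: an
apical HD-ZIP III class factor (`H`) and a basal KANADI class factor (`K`).
`whorlpos` implements a quantitative model of how this trough's distance
from the tip is set, together with the whorl geometry that converts that
distance into a cotyledon count.

## The model

Three species live on the one-dimensional distance-from-tip axis
`x ∈ [0, L]` (one spatial unit = 100 µm, `L = 3` by default):

$$\frac{\partial P}{\partial t} = P_0 \cdot \mathbf{1}(x < s_e) - k_P P + D_P \frac{\partial^2 P}{\partial x^2}$$

$$\frac{\partial H}{\partial t} = prodH \cdot \frac{P^{n_H}}{K_A^{n_H} + P^{n_H}} \cdot \frac{1}{1 + inhH \cdot K} - k_H H + D_H \frac{\partial^2 H}{\partial x^2}$$

$$\frac{\partial K}{\partial t} = prodK \cdot \frac{1}{1 + inhK \cdot H} - k_K K + D_K \frac{\partial^2 K}{\partial x^2}$$

The precursor `P` stands for upstream meristematic patterning (CLV–WUS
class); its steady gradient is exponential with decay constant
`B = sqrt(kP/DP)`. `H` is activated by `P` through Hill kinetics
(cooperativity `nH`, half-activation at `P = KA`) and repressed by `K`;
`K` is produced constitutively and repressed by `H`. The inhibition terms
are linear in the inhibitor, consistent with single small-RNA binding sites
mediating part of the interaction (e.g. miR166 repression of HD-ZIP III
from the basal domain).

Two readouts define the biology:

* the **interface**: the `x` at which the `H` and `K` profiles cross — the
  model's whorl position;
* the **permissive trough**: the region with `H + K < 50`, in which
  PIN1–auxin dynamics can place primordia (with the default `prodK`, the
  uninhibited `K` plateau is 100, so 50 is half of it).

### Parameters and defaults

| symbol | meaning | default |
|---|---|---|
| `P0` | precursor production / apex amplitude | 100 |
| `se` | source extent (spatial units) | 0.1 |
| `kP`, `kH`, `kK` | decay constants (1/time) | 1 |
| `DP` | precursor diffusivity | 0.5 (so `B = √2 ≈ 1.41`) |
| `DH`, `DK` | `H`, `K` diffusivities | 1e-4 |
| `prodH` | apical production | 100 (600 in the inhibition-ladder baseline) |
| `nH` | Hill coefficient | 3 |
| `KA` | dissociation constant | 17.5 (32 in the inhibition-ladder baseline) |
| `inhH` | inhibition of `H` by `K` | 0 (2.4 in the reference pattern) |
| `inhK` | inhibition of `K` by `H` | 1 |
| `domain_length`, `n_grid` | axis and grid | 3 units, 300 points |
| `t_end` | integration horizon | 200 time units |

All quantities are in the model's dimensionless concentration and time
units; only space carries a physical scale (100 µm per unit), which is what
connects the interface position to whorl radii measured in embryos.

## Numerical choices

**Precursor profile.** By default `P` is the closed-form exponential
`P0·exp(-Bx)` with the apex amplitude pinned at `P0` — the exact steady
state in the point-source limit, and the form in which the positioning
theory (dosage factor, decay-length scaling) is stated. An alternative
`p_mode = "pde"` solves the source–diffusion–decay equation with its finite
source and no-flux ends and rescales the profile so the apex equals `P0`.
We made the closed form the default because the amplitude convention
("`P0` is the maximum height of the profile") is then exact rather than
approximate; the finite-source profile has the same basal decay but a flat
top of width `se`, which displaces all positions basally by roughly
`se`/2–`se`. This convention, at 300 grid points, reproduces every
interface position studied here to within 0.05 spatial units (5 µm).

**Integration.** `H` and `K` are integrated by the method of lines
(`deSolve::ode.1D`, lsoda, `rtol = atol = 1e-8`) from `H = K = 0` with `P`
held at its steady profile, to `t = 200` — far beyond the kinetic
relaxation time (`1/k = 1`). Convergence is verified, not assumed: the
maximum time-derivative at the final time, scaled by the concentration
maximum, must be below 1e-6 or the solver raises a non-convergence error
carrying the residual. The pointwise `H`–`K` system is monostable (one
non-negative fixed point at every `P`), so the steady state does not depend
on the initial condition; a test confirms this from a randomized start.

**Boundary conditions.** Zero-flux at both ends for `H` and `K`. At
`DH = DK = 1e-4` the diffusion length is 0.01 spatial units, so the choice
is numerically immaterial; a contract test shows the interface moves by
less than 0.01 units under a zero-Dirichlet basal end.

**Interface and trough extraction.** Crossings and trough edges are located
by linear interpolation between adjacent grid points. A tangential touch of
`H - K` on zero without a sign change is not a crossing; multiple sign
changes (never observed with monotone profiles, which the mutual-inhibition
structure produces) return the most apical crossing with a warning.

**The mean-field oracle.** Because `H` and `K` barely diffuse, the PDE
steady state is, away from the interface, the pointwise fixed point of the
local kinetics. This gives an independent closed-form prediction of the
crossing: at the crossing `H = K = C` with `C(1 + inhK·C) = prodK/kK`; the
Hill occupancy needed there is `h* = C·kH·(1 + inhH·C)/prodH`; if `h* ≥ 1`
no crossing exists (the interface is eliminated), otherwise inverting the
Hill function and the exponential gradient gives
`x = log(P0/(KA·(h*/(1-h*))^{1/nH}))/B`. Every catalog scenario is checked
against this oracle; PDE and oracle agree within 0.05 units throughout.

## Positioning theory

Three closed forms summarise how the precursor gradient sets position:

* `decay_constant(kP, DP) = sqrt(kP/DP)`: the gradient's exponential decay
  constant; a 9-fold change of the rate:diffusivity ratio is needed for a
  3-fold change in position.
* `dosage_factor(B, x) = exp(2·B·x)`: the amplitude fold-change required to
  move a given concentration from `x` to `3x`. The convention is that the
  factor is evaluated at the *lower* position of the pair: on the reference
  gradient (`B = √2`), shifting from 0.6 to 1.8 units requires a 5.46-fold
  amplitude change, while on a steep gradient (`B = 4.71`) shifting from
  0.55 to 1.65 takes a 178-fold change — dosage is an expensive lever on
  steep gradients.
* `decay_for_shift(B1, f) = B1/f`: position is linear in decay length, so a
  3-fold basal shift needs `B1 = 3·B2`.

## Whorl geometry

The inter-cotyledon spacing `λ` is interpreted as the chord distance
between adjacent organ centres on the whorl circle. That anchors the
two-organ whorl at diameter `λ` (radius 55 µm at the spruce spacing
`λ = 110` µm) and gives the circumradius formula
`r = λ/(2·sin(π/n_c))`; the arc interpretation (`r = λ·n_c/2π`) would
predict `r(2) = 35` µm and is rejected by that anchor. The inverse map
`predict_nc` returns the largest count whose chord still reaches `λ`;
whorls too small for two organs are reported as pins (`n_c = 1`, the
ring/pin phenotype; configurable to 0). The ratio `r(10)/r(2) = 3.24` is
independent of `λ` — the observed three-fold radius range is a statement
about angles, not absolute spacing. On a still-domed (hemispherical) tip,
positions along the surface exceed the horizontal radius:
`s = R·asin(r/R)`, up to the quarter-circumference limit.

Two regressions connect the geometry to measurement tables: diameter on
count (`D = (λ/π)·n_c + b`; `λ = π·slope`, intercept `b` = growth beyond
the specification diameter) and per-embryo mean spacing on cotyledon
length, restricted to lengths below 300 µm where the relation is linear
(its intercept estimates the spacing at morphogenesis onset; 145 µm on the
published spruce measurements, reflecting the slightly expanded flattened
stage relative to the 110 µm of the earlier domed stage). Both are ordinary
least squares: the published analyses state only "linear regression", and
OLS is the standard reading.

## The synthetic population

The spruce measurement set (237 embryos) is not publicly deposited, so the
package generates populations with the same statistical structure for
testing the regression machinery:

* counts 2–10 with weights peaked at 5 (the commonly observed count);
* diameter = `(λ/π)·n_c` + a non-negative per-embryo growth offset +
  Gaussian measurement noise (sd 5 µm). Growth offsets are half-normal with
  scale 50 µm: offsets up to ~150 µm, consistent with diameter growth of up
  to 20 %/week over the one-to-two weeks between specification and
  measurement, and chosen so that the spacing estimate remains recoverable
  to within a couple of percent from 20 replicates of 200 embryos. Offsets
  are drawn independently of the count (observed growth does not correlate
  with `n_c`), which is what makes the slope — and hence `λ̂` — unbiased;
* spacing = intercept·(λ/110) + slope·length + noise, lengths uniform on
  20–400 µm. The slope (0.1 µm/µm) is a free parameter: no published value
  constrains it, only the positivity of the trend.

What the generator does *not* emulate: longitudinal growth trajectories of
individual embryos, count-dependent measurement error, and any curvature
of the spacing–length relation beyond the fitted window. Recovery tests on
these populations therefore validate the estimators under the model's own
assumptions, not the field protocol.

## The scenario catalog

`scenario_catalog()` pins the perturbation analyses to explicit parameter
sets: the gradient series from the reference set (crossing near 1.8;
`B`×10/3 via `DP = 0.045`; `KA`×5.6), the inhibition ladder on the
`prodH = 600`, `KA = 32` baseline (`inhH` 0 → 2.4 → 4.9 moving the
interface 1.8 → 0.95 → 0.55), and the experimental set: basal
overexpression (`prodK`×2.2 shifts to 0.41 with a five-fold `H` maximum
drop; ×3 eliminates the interface), apical loss of function (`prodH`/6
eliminates it), basal loss of function (`prodK`×0.1 removes the basal
boundary, leaving an unbounded permissive zone), inhibition-resistant
apical overexpression (`inhH = 0`, `prodH`×100 pushes the `H`-dominated
zone past the 200 µm competence limit), and apical gain of function
(`prodH`×2, a 20 µm basipetal shift, one extra organ at the printed
positions). Verbal dosage descriptions ("strong increase") are pinned to
the stated factors so configurations are reproducible. One entry is
qualitative by design: the three-fold `prodH` reduction is catalogued with
an acropetal-or-eliminated expectation because, from the stated baseline,
the required Hill occupancy exceeds 1 below `prodH ≈ 227` and the
mean-field system admits no crossing at `prodH = 200`.

Changing `B` in scenarios is realised by changing `DP` with `kP` fixed
(either would do; fixing the convention makes configs reproducible).

### The steepness sweep

The sweep over Hill coefficients asks, for each `nH`, how much `inhH` must
change to drive the interface from 1.8 to 0.55, and how wide the trough is
with the interface at 0.95. The published analysis does not state how other
`nH` values were re-baselined; our scheme keeps `KA = 32` and rescales
`prodH` so the no-inhibition crossing matches the `nH = 3` reference
position — which recovers `prodH = 600` exactly at `nH = 3`, making that
row (inhibition ≈ 4.9, width ≈ 0.29) the quantitative anchor. Other rows
are reported with the scheme label: they agree with the published column
for `nH ≤ 4` and diverge above, where the unknown original scheme evidently
differs. Note one structural fact: whenever a crossing exists, the two
profiles meet at `H = K = C` with `2C ≈ 19 < 50`, so a configuration with
an interface always has a trough of positive width — a zero-width trough
can only mean the interface itself is displaced or absent.

## Problem sizes and runtime

All solves use the default 300-point grid to `t = 200`; each takes a
fraction of a second, the full catalog a few seconds, and the recovery
studies use 20 seeded replicates of 200 embryos. These sizes match the
scales at which the reproduced analyses are stated.

## Known limitations

* One spatial dimension only: curvature enters solely through the
  arc-length conversion, and the circumferential patterning of individual
  primordia within the ring (the PIN1–auxin stage) is out of scope.
* No growth of the domain over developmental time; growth appears only as
  the morphometric offset `b`.
* The miR166 pathway is not a separate species: basal small-RNA
  overexpression is proxied by `prodK`, apical resistance by `inhH = 0`.
* The closed-form precursor convention displaces positions by up to ~5 µm
  relative to a finite-source profile; all stated tolerances absorb this,
  but discrete organ-count predictions can step by one when an interface
  sits within that margin of a count boundary (e.g. the reference pattern
  at 0.93–0.95 units straddles the 4/5-organ radius at 93.6 µm).
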