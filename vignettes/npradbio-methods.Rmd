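---
title: "Models and methods in npradbio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in npradbio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npradbio)
```

npradbio models the chain of events that makes high-atomic-number
nanoparticles (gold nanoparticles, AuNPs, or radiolabeled iron-oxide
particles, SPIONs) useful in kilovoltage radiotherapy: where the particles
go in the body and the cell, how energy concentrates around them under
X-ray irradiation, how that energy turns into DNA strand breaks, and how
strand breaks turn into cell killing. Each stage is a small, testable
model; full Monte Carlo radiation transport is deliberately out of scope,
and seeded synthetic generators stand in for transport output and animal
data so the whole pipeline can be exercised on a laptop.

## Whole-body pharmacokinetics

The biodistribution model is a linear mammillary network with first-order
kinetics: a central blood compartment exchanges bidirectionally with 13
systemic organs (tumor, liver, spleen, kidneys, colon, stomach, lungs,
small intestine, muscle, bone, skin, brain, heart), and an alimentary
chain (liver and stomach into the small intestine, small intestine to
colon, colon to a terminal excretion sink) carries material out of the
body. Gut transit is the only elimination route; no urinary pathway is
modeled because the underlying mouse experiments provided no urine data.
The state is the vector $x(t)$ of amounts as fractions of the injected
dose, and

$$\frac{dx}{dt} = A\,x, \qquad
A_{ji} = k_{i \to j}, \quad A_{ii} = -\sum_j k_{i \to j},$$

so every column of $A$ sums to zero and total amount (including the sink)
is conserved identically. The packaged rate table spans almost eight
orders of magnitude, from $1.4\times10^{-5}$ to $896\ \mathrm{h^{-1}}$,
which makes the system stiff; `simulate_biodistribution()` integrates
with `deSolve`'s lsoda using the constant analytic Jacobian, at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ by default. The
test suite holds the solution to within $10^{-8}$ of an independent
matrix-exponential propagation of the same system over 0--100 h.

Two printed rates deserve comment. The tumor row (327.4 h$^{-1}$ out,
40.06 h$^{-1}$ in) implies sub-minute tumor equilibration after an
intratumoral bolus; the package implements the table as printed and makes
no judgement about it. And the "intestine" compartment is the contents of
the small intestine, not the tissue.

Injection is a bolus in either blood (intravenous) or tumor
(intratumoral, the default). The fraction-of-dose state is primary;
percent injected dose per gram (%ID/g) is a *view* obtained with
`to_percent_id_per_gram()` and user-supplied organ masses.
`default_mouse_organ_masses()` ships nominal organ masses for a 21 g
mouse purely for convenience — they are textbook-style values, not
measurements, and any quantitative use should substitute real masses.

### Rate fitting

`fit_transfer_rates()` estimates any chosen subset of the 30 rate
constants by weighted least squares against observed time courses, with
all other rates fixed. Rates are optimized as logarithms (positivity for
free) inside bounds $[10^{-8}, 10^4]\ \mathrm{h^{-1}}$ with
Levenberg--Marquardt (`minpack.lm`). Two numerical choices matter:

* Inside the fit the ODE tolerances tighten to `rtol = 1e-10`,
  `atol = 1e-13`. Faint organs (liver carries only a few $10^{-6}$ of an
  intratumoral dose) otherwise drown the finite-difference Jacobian in
  integration noise and the optimizer stalls at its starting value.
* The finite-difference step (`epsfcn = 1e-8`, i.e. relative steps of
  about $10^{-4}$ in log-rate) is chosen to stand well clear of that
  noise floor while remaining small against the curvature scale.

Joint fits of many rates are allowed but a single injection experiment
rarely identifies them all; the intended use is freeing one or a few
edges, which the suite shows recovers generating values to well under 1%
from noise-free dense data (101 time points over 0--100 h).

## Cellular uptake

Antibody-conjugated particle uptake is a three-compartment linear model:
extracellular medium, membrane-bound, cytoplasm, with binding
(`k_bind`), release (`k_release`), and internalization (`k_int`) rates;
the cytoplasm is absorbing by default, with an optional exocytosis edge
for completeness. The closed system conserves the total amount; an
"infinite bath" flag holds the medium constant for high-volume
incubation. The model is deliberately linear — no receptor saturation —
because the five-point design (1, 3, 6, 12, 24 h) that motivates it
cannot distinguish saturation from rate changes. With membrane and
cytoplasm both observed at those five times, all three rates are
identifiable from noise-free data to well under the 5% the tests assert.
Units are arbitrary but must be consistent; the package never converts
imaging intensity to particle counts, and the membrane compartment is
whatever the measurement calls membrane-bound (surface-bound and early
endosomal signal are not distinguished).

## Shell dosimetry

Energy deposition around a single nanoparticle is scored on concentric
spherical water shells starting at the particle surface: `n` half-open
shells of thickness `d` from inner radius `r0`, typically 100 shells of
10 nm (nanometer range) or 50 shells of 1 µm (micrometer range). Events
are radial `(r, eV)` records; Cartesian event files are reduced to radii
about a declared center. Conventions chosen where the field leaves them
loose:

* Shell intervals are half-open with the lower edge inclusive, so a
  boundary event lands deterministically in the shell whose lower edge
  it sits on.
* Events inside the particle or beyond the grid are *counted* as
  discarded and reported in the profile metadata; silent loss would hide
  mis-registered inputs. Binning therefore conserves energy exactly:
  scored plus discarded equals the input sum.
* The canonical unit is eV per primary photon. Dose in Gy is not
  computed: the dose enhancement ratio (DER) compares identical water
  shells with and without the particle, so shell masses cancel and the
  energy ratio is the dose ratio.

`dose_enhancement_ratio()` masks shells whose reference energy is zero
rather than returning infinities, and `summarize_der()` averages the
valid shells among the first $k$ — exposed as a parameter because "mean
DER in the first shell" can mean either the single first-shell ratio
($k=1$) or a mean over finer sub-shells.

## Strand-break calling and classification

Backbone damage records carry a cell id, strand (1 or 2), base-pair
index, and kind. The calling rules are:

* **Direct breaks**: deposited energy is accumulated per backbone
  position, and a position with at least 17.5 eV becomes one break —
  accumulation before thresholding, because the criterion applies to the
  energy scored in a single backbone, however many hits delivered it.
* **Indirect breaks**: each hydroxyl-radical hit on an unbroken position
  breaks it with probability 0.40. Multiple radical hits on one position
  draw independently but the position breaks at most once. Draws happen
  in sorted position order from the configured seed, so calling is
  reproducible; at $10^5$ seeded hits the break fraction sits within
  half a percent of 0.40.
* **DSB pairing**: two breaks on alternate strands within 10 bp form a
  double strand break. The pairing algorithm is greedy left-to-right
  with each break consumed at most once — the literature states the
  proximity rule but not an algorithm, and for a pure distance-window
  compatibility this greedy matching attains the maximum pairing, which
  the suite verifies against exhaustive enumeration on hundreds of
  random configurations of up to 10 breaks.
* **Complexity**: a DSB whose 10 bp fragment (anchored at its lower
  break) contains exactly one break per strand is simple (DSB$_0$); any
  extra break in the fragment makes it complex (DSB$_*$). Only this
  binary split is implemented. Both the raw break count and the
  exclusive SSB count (breaks not consumed by a DSB) are reported.

## Cell survival models

The classical linear-quadratic model is reinterpreted through DSB
counts: $\alpha D + \beta D^2$ is the expected DSB yield at dose $D$, so
$S = \exp(-p\,\mathrm{DSB})$ with $p$ the per-DSB lethality. On top of
this sit two fitted model classes with a damage-dependent repair
capacity $q(\mathrm{DSB}) = q_0 + k_1\mathrm{DSB} + k_2\mathrm{DSB}^2$:

$$\text{class I: } S = q \cdot e^{-p\,\mathrm{DSB}}, \qquad
\text{class II: } S = q \cdot e^{-p_0\,\mathrm{DSB}_0 - p_*\,\mathrm{DSB}_*}.$$

Parameters are entered on their conventional printed scales ($k_1$ in
$10^{-3}$, $k_2$ in $10^{-5}$, lethalities in $10^{-3}$) so published
tables can be typed verbatim. Two reproduced-as-printed quirks: $q_0 >
1$ makes $S(0) > 1$ (no normalization is applied; a display clamp is the
user's business), and negative $k_2$ drives $q$ — and hence $S$ —
negative beyond roughly 420--450 DSBs for the packaged parameter sets.
Evaluation returns the negative product with a warning rather than
erroring, since the formula admits it.

`fit_survival_params()` fits on log-survival with uniform weights
(survival spans decades; the scale choice is the package's, as the
source literature does not state one), and reports $R^2$ on that scale.
Non-positive survival values, which arise when generating data into the
negative-$q$ regime, are dropped with a warning — they have no
logarithm. Numerical design of the fit:

* Where an iterate drives $q \le 10^{-4}$ at a data point, $\log q$ is
  continued linearly below that floor, keeping the objective smooth
  instead of undefined.
* The default initial guess is a log-linear pre-fit with $k_1 = k_2 = 0$
  (the model is then exactly linear in $\log q_0$ and the lethalities).
  This matters: from generic starting points such as $(1, 1, -1, 5, 5)$
  the class II objective has a competing local minimum with $R^2 \approx
  0.9996$ and wrong-signed parameters, while the pre-fit start converges
  to the generating values essentially exactly.

## Enhancement factors

`ef_dsb()` is the with/without DSB yield ratio; `ef_sf_direct()` the
inverted survival ratio $S_{NG}/S_G$. The closed-form predictions

$$EF_{SF} = e^{p\,\mathrm{DSB}_{NG}(EF_{DSB}-1)}
\quad\text{and}\quad
EF_{SF} = e^{(p_0 a_0 + p_* a_*)\,\mathrm{DSB}_{NG}(EF_{DSB}-1)}$$

follow from the survival models only if the repair factor $q$ is treated
as equal in both conditions and cancelled. That is exact for $q$
constant (asserted to $10^{-12}$ in the tests) but an approximation for
the full class I/II models, so `ef_consistency()` always reports the
prediction, the exact model ratio, and the dropped $q$ ratio side by
side rather than hiding the discrepancy.

## Synthetic data

Every input the pipeline needs can be generated: noisy biodistribution
and uptake time courses, spectrum photon samples, paired emission-event
lists, backbone hits, and survival tables. All generators are pure
functions of their parameters and a seed, and none of them imports from
the fitting code, so recovery tests are never circular. Defaults follow
the study conditions the models were built for: intratumoral unit bolus,
0--100 h sampling for whole-body work, the 1/3/6/12/24 h in-vitro
design, DSB grids of 0--500 in steps of 25, and simple-DSB fractions 0.6
and 0.8 for class II identifiability. Measurement noise defaults to
multiplicative lognormal with CV 0.1 — a standard error structure for
%ID/g-type data; no noise model is stated by the source experiments —
and noisy fractions are clipped at the injected amount, since a measured
retained fraction cannot exceed the dose.

The toy emission generator deserves its caveat repeated: it splits each
interacting photon's electron energy into equal deposits at
exponentially distributed depths with mean range $c\,E^{1.7}$, which has
the right *shape* (monotone-decaying, energy-dependent range) to
exercise shell scoring and DER computation, and no physical validity
whatsoever. Its output is tagged `NON-PHYSICAL TOY`. Likewise the
packaged spectra are coarse Kramers-like placeholder histograms tagged
by kVp, not tube-physics reproductions. Consequently, passing tests
demonstrate that the scoring, calling, and fitting machinery is correct
— energy-conserving, oracle-equivalent, parameter-recovering — not that
any physical DER or enhancement value is reproduced; real values require
track-structure Monte Carlo input, which this package consumes but does
not produce.

## Problem sizes and limitations

The test and acceptance workloads are sized for interactive use: 101
time points for PK fits, $10^4$ events for binning-oracle comparisons,
$10^5$ radical hits for the probability check, DSB grids of 21 points
per a0 level. Each runs in seconds.

Known limitations, by design: linear kinetics only (no saturable
binding, no blood-flow-limited physiology); no radiolabel decay
correction; no dose in Gy; no repair kinetics beyond the $q$ polynomial;
the binary DSB complexity split only; and identifiability of large joint
rate fits is left to the user.
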