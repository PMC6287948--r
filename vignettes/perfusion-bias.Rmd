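---
title: "Indicator-dilution lung perfusion quantification and the repeat-injection bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indicator-dilution lung perfusion quantification and the repeat-injection bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungperf)
```

## The measurement model

A DCE acquisition samples a 3D signal volume every `dt = 1.47` s, 24 times,
with contrast injected 5 s after the scan starts.  Indicator-dilution
theory links the arterial input concentration $C_a(t)$ (read in the
pulmonary trunk) to the concentration in a tissue voxel:

$$C_t(t) = f \,(C_a \ast R)(t), \qquad R(0)=1,\; R \text{ non-increasing},$$

where $f$ is blood flow per unit tissue volume and $R(\tau)$ the residue
function (fraction of tracer still in the voxel $\tau$ seconds after an
idealised instantaneous input).  The three reported parameters are

* **PBF** $= 6000 \cdot \max_t f R(t)$ (ml/min/100ml) — the height of the
  deconvolved tissue response,
* **PBV** $= 100 \cdot \int C_t \,/ \int C_a$ (ml/100ml) — the integral
  ratio over the shared post-arrival window,
* **MTT** $= 60 \cdot \mathrm{PBV}/\mathrm{PBF}$ (s) — the central volume
  theorem.

PBV is taken from the integral ratio rather than $f \int R$ because the
ratio is insensitive to the deconvolution regularisation; on ideal data the
two coincide, and a test asserts the residue area/height MTT agrees with
the central-volume MTT within 15% rather than assuming it.

MRI signal is not linear in concentration.  The package models enhancement
with a one-parameter rational saturation,

$$S = S_0\left(1 + \frac{c}{1 + \beta c}\right),$$

which is monotone, concave, exactly linear at $\beta = 0$, and saturates at
$S_0(1 + 1/\beta)$.  A full spoiled-gradient-echo signal equation would add
sequence parameters the analysis never identifies; one parameter expresses
the only property that matters here — the marginal enhancement of a
concentration increment shrinks as the operating point rises.

## The synthetic phantom

`generate_phantom()` builds two rectangular lungs separated by a
mediastinal gap, a pulmonary-trunk block, and (optionally) scattered
large-vessel voxels at 5× regional PBV/PBF.  Axes are fixed:
x = left→right, y = ventral→dorsal, z = apical→basal.  Its signal chain is
exactly the model above: gamma-variate first-pass AIF (peak amplitude 3 in
relative concentration units, shape 3, time-to-peak 4 s, optional
recirculation bump), per-region tissue curves by discrete convolution,
saturating signal mapping, then seeded Gaussian noise clipped at zero.

Key defaults, chosen once:

| parameter | default | why |
|---|---|---|
| grid | 32×32×16 voxels, 6×6×10 mm | coarse clinical perfusion resolution; ~8000 lung voxels |
| `dt_s`, `n_frames` | 1.47 s, 24 | the acquisition protocol being modelled (≤ 37 s total) |
| `injection_delay_s` | 5 s | protocol: guarantees a pre-bolus baseline |
| `arrival_delay_s` | 3 s | venous transit to the pulmonary trunk; with 1.47 s frames this yields 5 unenhanced frames, and delays 2.4–8.2 s span the 5–8 frame range |
| regional truth | PBV 15 (ventral) / 20 (dorsal) ml/100ml, MTT 5 s | physiological lung blood volume with a gravity-dependent dorsal excess; PBF follows from the central volume theorem |
| `s0`, `noise_sd` | 100, 2 | 2% of baseline, a realistic parenchymal SNR for 1.5 T lung imaging |
| `sat_beta` | 0.3 | the arterial peak (c = 3) is strongly dampened (enhancement 1.6 instead of 3) while dilute tissue (c ≲ 0.5) stays near-linear — the regime that produces the in-vivo bias pattern |
| `steady_state_frac` | 1/80 | one dose fully mixed, as a fraction of the first-pass peak; a compact bolus transits the pulmonary artery one to two orders more concentrated than its post-distribution equilibrium, and this value puts the simulated arterial repeatability in the observed regime (repeat-injection AIF integrals within ~5%) |
| `residual_fraction` | 0 | set per experiment cell by the carryover schedule |

What the generator deliberately does **not** emulate: k-space view sharing
and reconstruction artefacts, breathing motion (acquisitions are modelled
as breath-held), Rician noise statistics (additive Gaussian is used; the
bias mechanism under study does not depend on the noise law, and the noise
model is a documented swap point), per-voxel arrival-time dispersion,
contrast extravasation, and any true physiological response to oxygen.
Passing tests therefore validate the *measurement chain and its biases*,
not organ physiology.

## Numerical choices

**Discrete residue kernel.**  The generator and the deconvolution share the
rectangle-rule discretisation $C_t[i] = dt \sum_j C_a[j]\, fR[i-j]$.  The
residue is the geometric kernel

$$R[k] = (1 - dt/\mathrm{MTT})^k,$$

the exact explicit-Euler discretisation of exponential washout.  It is the
unique one-parameter kernel with height exactly 1 **and** rectangle-rule
area exactly MTT at any `dt`; a sampled `exp(-k·dt/MTT)` would carry ~15%
excess discrete area at `dt = 1.47`, MTT = 5 s, poisoning PBV recovery.
The kernel needs `MTT ≥ dt`, which the spec validator enforces (an MTT
below one frame interval is unresolvable at this sampling anyway).  Frames
are timestamped at the *end* of each interval, so a bolus arriving at time
$t$ first appears in frame $\lfloor t/dt \rfloor + 1$ and the unenhanced
frame count is exact integer arithmetic.

**Deconvolution.**  The convolution matrix is lower-triangular Toeplitz,
$A[i,j] = dt\,C_a[t_{i-j}]$; causality is structural.  It is inverted by
truncated SVD with threshold 0.10 of the largest singular value.  The
canonical bolus-tracking range is 0.1–0.2; at this acquisition's coarse
`dt` the residue-height (PBF) bias is about −3% at threshold 0.10 versus
−5 to −9% at 0.15, so 0.10 is the default and the threshold remains a
configuration knob.  A first-pass AIF rising from near zero makes the
system numerically singular (condition numbers beyond 1e15), which is why
the truncation exists; fully truncated voxels return a zero residue flagged
invalid rather than an error.  Bolus delay between trunk and tissue is
absorbed by the causal system itself (a shifted residue peak), without
explicit delay fitting.

**Arrival detection.**  The trunk-mean curve is thresholded at
`baseline mean + 3·SD`, sustained for two frames, with an expanding
baseline.  Because the SD is estimated from as few as 3–7 frames, its
heavy-tailed sampling error can fire one frame early; the threshold
therefore never drops below 5% of the curve's total enhancement.  A signal
jump inside the first three frames aborts with an insufficient-baseline
error, and a flat series reports that no bolus was detected.

**Concentration conversion.**  The default (`"linear"`) mode is relative
enhancement $(S - S_0)/S_0$ with $S_0$ the per-voxel pre-arrival mean —
deliberately reproducing conventional evaluation software, because its
interaction with saturation *is* the bias under study.  Noise may drive
concentrations negative; they are not clipped.  The `"corrected"` mode
inverts the saturation map ($c = e/(1-\beta e)$, clamped just below the
asymptote) for a known `β` and subtracts the pre-arrival concentration; if
a contrast-free reference baseline is available (the same session's first
injection provides one), it removes a residual plateau exactly.

**AIF detection.**  Candidate voxels are scored by
peak enhancement × earliness (a linear weight in the peak frame: the
pulmonary trunk is the earliest bright structure in a lung bolus pass).
The top 1% of scorers — expanded adaptively if they are too scattered to
form a 10-voxel 6-connected component — seed the selection, and the
component then grows over adjacent candidates scoring at least half the
component median, so the whole vessel is captured rather than only its
extreme voxels.  The AIF is the mean curve over the set; its trapezoidal
post-arrival integral is the PBV denominator.  In the scripted experiment
the phantom's trunk mask is used directly (the geometry is known from the
morphological scan); automatic detection is exercised by its own tests.

**Partitioning.**  Cuts are whole voxel planes.  The two axial cut planes
minimise the maximum pairwise difference of the three slab voxel counts,
and each slab's coronal cut minimises the front/back difference, with ties
broken toward lower plane indices — deterministic, order-free, and
imbalance bounded by one plane's in-lung count.  Vessel exclusion removes
voxels above the 95th in-mask PBV percentile plus a one-voxel dilation.

**Statistics.**  Bland–Altman uses the n−1 SD and ±1.96·SD limits.  The
Wilcoxon signed-rank test drops zero differences, mid-ranks ties, and for
n ≤ 12 computes the two-sided p by full enumeration of all $2^n$ sign
assignments of the observed ranks; larger n uses the normal approximation
with the tie-respecting variance $\sum r_i^2/4$ and no continuity
correction (`stats::wilcox.test` serves as an independent cross-check in
the tests, never as the implementation).  "MAD" here is the median over
the 12 regions of |region median − whole-lung median| — the regional
heterogeneity index as defined in this line of work, *not* the
conventional median absolute deviation from the median.  All tests are
two-sided.

## The repeat-injection experiment

`experiment_design()` encodes the study grid: two injections
`inter_injection_min = 32` minutes apart on each of two days separated by
`inter_day_h = 24` hours, equal doses, elimination half-life
`half_life_h = 1.6` (4.2 h in the renal-impairment variant).  The residual
fraction before each injection is the sum of all earlier doses decayed by
$0.5^{\Delta t/T_{1/2}}$: 0 at day-1/injection-1, $0.5^{1/3} \approx 0.794$
at injection 2, and below $5\times10^{-5}$ per component on day 2.

True perfusion is held fixed across the four cells (subjects get seeded
multiplicative PBV/PBF perturbations, truncated to ±30%).  This is the
central design decision: in vivo, a true oxygen response and the carryover
artefact are confounded; holding truth constant isolates the measurement
bias, so any injection-2 excess is artefact by construction.  A hook for
planting a true physiological effect (editing `region_truth` per cell)
exists for power studies.

The mechanism, step by step: the residual raises every baseline.  In the
trunk, the signal operates high on the saturation curve, so both the
baseline inflation and the bolus enhancement are compressed — the measured
AIF integral barely moves.  In dilute lung tissue the conversion is
near-linear and baseline-referenced, so the same residual perturbs the
measured tissue curve relatively less than the AIF loses — and since PBV
is the tissue/arterial integral ratio and PBF scales with the residue
height against a diminished input, both inflate.  `mechanism_report()`
tabulates every link of this chain (true vs measured AIF peak and
integral, true vs estimated PBV/PBF/MTT, linear vs corrected mode) across
residual levels; the acceptance script reports the resulting numbers, and
nothing in this vignette asserts magnitudes those computations do not
produce.

Because elimination leaves less than 0.005% of a dose after 24 h, the
model predicts *no* day-2 effect from kinetics alone — asserted as a test.
Any day effect observed in vivo must therefore come from mechanisms this
artifact deliberately omits (renal impairment lengthening the half-life,
extravasation into inflamed interstitium, true physiological drift); the
experiment quantifies only the elimination channel and leaves the rest
explicitly unexplained.

## Problem sizes and determinism

The default grid (32×32×16×24, ~8000 lung voxels) makes a full
quantification run take a few seconds; the 10-subject × 4-cell experiment
runs in well under a minute.  These sizes were chosen so that the entire
test suite and the acceptance script re-run the complete analysis from
scratch rather than loading cached results.  Every stochastic step —
phantom noise, subject perturbations, vessel placement — derives from
explicit integer seeds, and identical seeds give bit-identical phantoms,
maps and experiment tables.

## Known limitations

* Concentration units are relative enhancement, not mM: no relaxivity or
  sequence signal equation is modelled, so absolute AIF values are
  arbitrary (all reported ratios are invariant to this choice as long as
  trunk and tissue share the convention).
* The saturation strength and the steady-state-to-peak ratio are effective
  scalar summaries of a richer physical chain (sequence nonlinearity,
  dispersion, distribution volume); they are calibrated to the observed
  regime, not derived from first principles.
* The phantom's geometry is blocky and its regional truth piecewise
  constant (an optional smooth dorsoventral gradient mode exists); there
  is no intra-region texture, airway tree, or partial-volume mixing at
  vessel boundaries.
* Automatic AIF detection assumes the trunk is the earliest bright
  structure; severe pathology that delays or disperses the main bolus
  could defeat the score.
* The Wilcoxon exact mode enumerates up to $2^{12}$ assignments; beyond
  that the normal approximation is used regardless of ties.
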