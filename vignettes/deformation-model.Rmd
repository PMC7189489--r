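---
title: "Modelling the perception of dynamic deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the perception of dynamic deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A vertical bar whose contour undulates sinusoidally looks like a *deforming*
object when the undulation has a low spatial frequency, but like a rigidly
translating wavy edge when the frequency is high. A perfectly *static* bar
in front of a fine, slightly tilted drifting grating also appears to deform:
the moiré intersections between the bar's edge and the grating stripes sweep
along the edge and create spurious local motion. `deformsense` implements a
computational account of both phenomena: deformation is read out by a
higher-order unit that monitors the *spatial pattern* of local motion
direction along the contour.

## The model

The pipeline has three stages.

**V1 motion energy.** The analysis strip near the bar's right edge (0.08°
wide for the deforming bar; 0.16/0.08/0.04° for 6.4/12.9/25.8 cpd gratings;
always 4.97° tall) is convolved with a bank of spatiotemporal filters:
Gaussian-enveloped drifting sinusoidal carriers whose spatial wavelength
equals their square support (= the strip width), sampled over 6 frames
(~100 ms at 60 Hz) with a 0.4 Hz temporal carrier. There are 24 direction
channels in 15° steps (0° = leftward, 90° = downward) and two carrier phases
(0, π). Outputs are half-wave rectified, scaled by a maximum-response
constant and divided by the summed rectified activity across all channels
plus a semi-saturation constant; the two phases are summed after
rectification, which together act as a full-wave rectifier.

**MT direction-selective responses.** Energies are pooled over 4 adjacent
filter positions with Gaussian weights (SD 1.2 position units, stride 1, so
32/64/128 positions become 29/61/125), then weighted by `cos(direction
difference)` across the 24 channels — the cosine's negative lobe implements
motion opponency — and rectified and normalized again with the same
constants.

**Higher-order kernel.** The deformation detector is a template over
position × direction,

$$K(x, \theta) = \sin(2\pi f x + \phi)\,\cos(\theta - \alpha),$$

with preferred direction $\alpha = 0°$ (leftward) so that its positive and
negative spatial lobes match *alternating* leftward/rightward responses
along the contour. Its match to a response map is the zero-mean normalized
cross-correlation (ZNCC) computed jointly over the grid, maximized over 32
kernel phases ($\phi = k \cdot 0.0625\pi$, tiling $[0, 2\pi)$). Kernel
scores are linked to deformation-report proportions by a two-parameter
exponential, $p = a e^{b \cdot \mathrm{NCC}}$, fitted by least squares;
model variants are compared by $r^2$ across kernel spatial frequencies
(0.1–6.4 cpd in octave steps).

## What a run looks like

```{r, eval = FALSE}
library(deformsense)

clip <- render_deforming_bar(deforming_bar_spec(deform_sf = 0.4))
maps <- compute_model_maps(clip)          # energy, pooled, direction
ncc_profile(maps$direction)               # best NCC per kernel frequency

cfg <- run_config(preset = "exp1", seed = 1)
bundle <- run_experiment_preset(cfg)      # 7 conditions, sweeps, observer
attr(bundle$sweeps$direction, "best_f")
```

## Design choices and their rationale

Several quantities needed for a working implementation were genuinely
open; the package fixes them as follows.

**Rendering resolution.** Default 200 px/deg, about seven times the source
display's density. The contour amplitude (0.04°) and the finest filter
wavelength (0.04°) are sub-pixel at display resolution; with linear
coverage anti-aliasing at 200 px/deg the rendered edge locus matches the
closed-form sinusoid to ~10⁻³ px (asserted in tests).

**Contour amplitude in degrees.** An amplitude is a length, not a spatial
frequency; the constant contour amplitude is 0.04° of visual angle.

**Both edges deform in phase.** The bar undulates at constant width. A
single-edge mode is available (`both_edges = FALSE`).

**Filter temporal frequency, taken literally.** 0.4 Hz with a 6-frame
support means well under one carrier cycle inside the window, which looks
like a typo for 0.4 cycles/frame (24 Hz). Both readings were evaluated:
the literal 0.4 Hz reproduces every qualitative signature — left/right
alternation with sign changes at the deformation half-period, and the
*downward* preference for downward drift at high deformation frequency —
while the 24 Hz reading reverses the vertical preference (temporal
under-sampling of the fast carrier aliases the drift direction). The
literal value is therefore the default, exposed as `temporal_freq`.

**One analysis window, not a whole-period average.** Rectified, normalized
energies could be averaged over every 6-frame window in the clip, but over
a full period of an oscillating deformation this cancels the
leftward/rightward structure *exactly*: each edge segment spends equal time
moving each way, so the opponent stage nulls out and every kernel score
collapses to numerical zero. The alternating pattern is a property of a
motion *snapshot*, and the kernel's 32-phase search is what absorbs the
snapshot's arbitrary spatial phase. The default `offset_policy = "single"`
therefore evaluates one window (frames 1–6); `"average"` is available and
the cancellation itself is asserted as a property in the test suite. A
consequence: rendered clips only need 6 frames for the model, although the
default clip length remains 180 frames (the 3 s presentation).

**Normalization constants.** These are free parameters of divisive
normalization; defaults are `max_response = 1`,
`semi_saturation = 0.1`, both exposed. Because responses are normalized
divisively, kernel ZNCC scores are insensitive to the overall scale; the
semi-saturation constant mainly guards the zero-input case.

**Position counts.** A 4.97° strip holds 62 non-overlapping 0.08° filters,
yet the reference filter counts are 64 (and 32/128 at the other strip
widths), on which the pooled counts 61 (29/125) depend. The bank accepts a target count
and shrinks the stride just below the filter size, centering the tiling
span.

**Filter envelope.** Spatial Gaussian with SD = support/4; flat temporal
envelope; kernels are DC-subtracted so a uniform field evokes exactly zero
response. The temporal phase is centered on the window, which makes
opposite-direction kernels exact spatial mirrors; a static stimulus
therefore drives opposite channels identically and the opponent stage is
silent on static input (asserted in tests).

**ZNCC formula.** A cross-correlation denominator written as plain sums of
mean-subtracted terms is identically zero; the standard ZNCC denominator $\sqrt{\sum(K-\mu_K)^2 \sum(I-\mu_I)^2}$ is
implemented, consistent with the quantity's own name. The kernel formulas
use the standard $2\pi$ placements ($\sin(2\pi f x + \phi)$,
$\cos(\theta - \alpha)$ in radians); alternative placements would give a
direction tuning with period 1 radian, incompatible with a 24-direction
design. Normalization is joint (global)
over the grid rather than per-axis.

**Exponential link and fitting.** Two-parameter `a·exp(b·x)` (an additive
offset variant exists behind `offset = TRUE`), fitted unweighted — the data
being 7–21 condition means — with a binomial-weight option. The nonlinear
fit is seeded by a log-linear regression of `log(p + 1e-3)`, making it
deterministic. Constant proportions leave SS_tot = 0, so the fit is flagged
degenerate with `r2 = NA` rather than reporting a misleading 1.

**Synthetic observer.** Reports are Bernoulli with
`p = clamp(a·exp(b·NCC), 0, 1)`, binomially sampled per condition under a
single run seed. The default link (`a = 0.1`, `b = 2.0`) keeps `p` inside
(0, 1) for the NCC range the simulated maps produce, so parameter recovery
is not distorted by clipping. The trial-schedule builders reproduce the
three experimental designs exactly: 2 × 7 × 10 = 140, 4 × 3 × 7 × 5 = 420 and
4 × 2 × 9 × 5 = 360 trials per observer, with per-session balanced,
seeded pseudo-random order.

## What the synthetic data do and do not show

The synthetic observer is generated *from* the model's own direction-map
scores, so sweeps on it demonstrate internal consistency — that the
machinery identifies the generating kernel frequency and recovers the link
parameters under binomial noise (mean error well under 5% at 1000
trials/condition) — not that human observers behave this way. The
corrupted-energy comparison (adding a constant baseline to the
leftward/rightward channels, mimicking edge-driven activity of
vertical-orientation units) shows the direction-map readout is the more
robust predictor *within this construction*. Human proportions can be
supplied as CSV (`read_dataset_csv()`) and swept against simulated maps
with the same functions.

For the moiré stimuli the simulation reproduces the reference structural
counts and produces direction maps dominated by the grating's drift
direction with a weaker spatial modulation at the moiré frequency; kernel
scores at low spatial frequency decline as the grating tilts away from
vertical. The quantitative strength of that modulation depends on details
(bar luminance, window phase) that the package exposes but does not
calibrate against behavioral data.

## Numerical choices

Problem sizes in the tests and the acceptance script follow the model's
reference geometry (200 px/deg, 61 pooled positions, 24 channels); clips rendered for
qualitative checks use 6 frames — exactly the model's analysis window —
because longer clips only repeat the stimulus period. Degenerate inputs are
rejected loudly: amplitudes that push the bar out of the field, gratings
with fewer than 4 px per cycle, strips that leave the frame, clips shorter
than the temporal support, fits on constant predictors. Ties in the
phase search cannot occur off a set of measure zero; the first maximum is
taken. All randomness (observer draws, schedule shuffles, random test
grids) flows from explicit seeds.

## Known limitations

- Speed tuning is not modelled (direction only); no second-order
  (contrast-defined) channels, so the neutral-gray attenuation of the moiré
  illusion is captured only qualitatively through the luminance pathway.
- The kernel is one-dimensional in space (along the contour) with fixed
  preferred direction α = 0°; no α search, no learning.
- Observers are pooled; per-observer fitting is out of scope.
- Compressive deformation and footstep/inchworm-type contrast effects are
  out of scope.
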