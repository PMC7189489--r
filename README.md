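# deformsense

Why does a bar whose contour undulates at a low spatial frequency look like
a *deforming* object, while the same undulation at a high frequency looks
like a rigid wavy edge sliding along? And why does a perfectly static bar
appear to wobble when a fine, slightly tilted grating drifts behind it (the
moiré deformation illusion)? `deformsense` implements a computational
answer for researchers in visual psychophysics and computational
neuroscience: the percept is read out by a higher-order unit that monitors
the **spatial pattern of local motion direction** along the contour.

The model chain:

1. **Stimuli** — rendered luminance movies (cd/m², calibrated deg/px) of a
   deforming bar (contour displacement
   `A·sin(2πf_s y ± 2πf_t t)`) or a static bar over a tilted drifting
   grating, with sub-pixel anti-aliased edges.
2. **V1 motion energy** — a bank of Gaussian-enveloped spatiotemporal
   filters (24 directions in 15° steps, two carrier phases, 6-frame
   support) applied to a narrow strip at the bar's right edge; half-wave
   rectification and divisive normalization.
3. **MT direction-selective responses** — Gaussian spatial pooling over 4
   adjacent positions (SD 1.2, stride 1), opponent cosine direction
   weighting, rectification and normalization.
4. **Kernel readout** — the template
   `K(x, θ) = sin(2πf x + φ) · cos(θ − α)` (α = 0°, leftward) scored
   against energy or direction maps by zero-mean normalized
   cross-correlation (ZNCC), maximized over 32 phases.
5. **Psychometrics** — exponential link `p = a·exp(b·NCC)` between kernel
   scores and deformation-report proportions, r² model comparison across
   kernel frequencies, a seeded synthetic observer, and trial-schedule
   builders for the three experimental designs.

## Worked example

Render a bar deforming at 0.4 cpd, run it through the model, and ask which
kernel frequency matches the MT-stage map:

```r
library(deformsense)

clip <- render_deforming_bar(deforming_bar_spec(deform_sf = 0.4),
                             clip_geometry(n_frames = 6))
clip
#> <stimulus_clip> 1040 x 200 px, 6 frames (5.20 x 1.00 deg @ 200 px/deg, 60 Hz)
#>   luminance range [38.00, 76.00] cd/m^2; kind: deforming_bar

maps <- compute_model_maps(clip)
maps$direction
#> <direction_map> 61 positions x 24 directions, range [0, 0.0964]

ncc_profile(maps$direction)
#>     f   best_ncc argmax_phase
#> 1 0.1 0.08707942     3.141593
#> 2 0.2 0.15121873     4.712389
#> 3 0.4 0.87099660     1.570796
#> 4 0.8 0.12322175     4.712389
#> 5 1.6 0.05982343     4.908739
#> 6 3.2 0.03227008     1.963495
#> 7 6.4 0.01590788     5.301438
```

The direction map correlates with the kernel at **0.4 cpd** — the
deformation frequency of the stimulus — at NCC = 0.87, and with no other
frequency above 0.16: the readout identifies the deformation it was shown.
The `best_ncc` column is the maximum over the 32 kernel phases; the
`argmax_phase` is the phase (radians) where that maximum occurred.

Link kernel scores to (here synthetic) deformation reports:

```r
d <- simulate_observer(0.1, 2, c(0.82, 0.87, 0.87, 0.55, 0.21, 0.08, 0.02),
                       n_trials = 70, seed = 1)
fit_exponential(d)
#> <exp_fit> p = 0.07784 * exp(2.22 * ncc)   r2 = 0.9505
```

With 70 trials/condition the fit recovers the generating parameters
(a = 0.1, b = 2) to within binomial noise, and r² says how much of the
variance in report proportions the kernel score explains.
`run_experiment_preset(run_config("exp1"))` composes the whole chain over
the seven deformation frequencies, including the kernel-frequency r² sweep
for both map types. A thin command-line wrapper over these functions lives
at `inst/scripts/deformsense` (verbs `render-bar`, `render-moire`, `ncc`,
`fit`, `run`, `fixtures`).

See the vignette (`vignettes/deformation-model.Rmd`) for the model's
assumptions, parameter defaults and design rationale.

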