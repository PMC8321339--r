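# frozenframes

Fast perceptual preprocessing for **micro-expression (ME) spotting** in
video.

Micro-expressions are involuntary facial expressions lasting at most half a
second, often a handful of frames. Spotting them normally means running an
expensive frame-by-frame analysis over entire recordings (30 min at 25 fps
is 45 000 frames). A much cheaper cue exists: when a subject conceals an
emotion, they briefly *freeze* — a motionless, concealed pose that precedes
and/or follows the ME. `frozenframes` detects those **frozen frames** with
a few global filtering operations and returns small **groups of frames
(GOFs)** around them, so that a precise (and slow) spotting algorithm only
has to look at a fraction of the video.

The package is aimed at researchers working with ME datasets (CASME II-,
SAMM-, MEVIEW-style corpora: image-sequence directories plus
onset/apex/offset annotation tables) and at anyone building ME spotting
pipelines who needs a cheap, kind-agnostic front end.

## Method

Let `f(x, y, t)` be the luminance sequence restricted to a face region Ω.
Two separable spatio-temporal filters share a spatial Gaussian low-pass
`ρ(x, y)`:

    h(x, y, t) = ρ(x, y) · ψ(t)        (LH: temporal high-pass)
    l(x, y, t) = ρ(x, y) · φ(t)        (LL: temporal low-pass)

with the temporal pair tied by `ψ = dφ/dt`. Writing `G = f ∗ h` and
`F = f ∗ l`, the per-frame **spatial standard deviation** (population
normalization over Ω)

    σ_U(t) = sqrt( 1/|Ω| · Σ_{x,y} ( U(x,y,t) − μ_U(t) )² )

gives two temporal signals: `σ_G`, a motion energy that vanishes exactly
when nothing changes, and `σ_F`, a smooth stillness signal. Because
`ψ = dφ/dt`, local minima of `σ_F` correspond to (near-)zeros of `σ_G` —
frozen frames — while being far more robust to noise than the zeros of
`σ_G` themselves. The detection algorithm is then:

1. partition the video into stationary scenes;
2. crop to the face ROI, apply the LL filter, compute `σ_F(t)`;
3. find local minima of `σ_F`; merge *instabilities* (runs of minima closer
   than `d` frames with values within `τ` of the energy range, replaced by
   their midpoint);
4. keep the `K` minima of smallest value; expand each into a GOF window
   for the downstream spotting algorithm.

Defaults scale with the frame rate: temporal length `max(2, fps/25)`
(2 at 25 fps, 8 at 200 fps), maximal expected ME length `N = 0.32·fps`
frames (8 / 64), instability distance `d = N/4`, `τ = 0.1`, spatial Gaussian
std 9 px for a typical face ROI.

## Worked example

A synthetic 120-frame clip at 25 fps containing one planted motion burst at
frames 50–54 (a low-amplitude ME surrogate), frozen plateaus at 46–49 and
55–58, and sensor noise:

```r
library(frozenframes)

spec <- synthetic_spec(T = 120, bursts = list(list(50, 54, 1.2)),
                       plateaus = list(c(46, 49), c(55, 58)),
                       noise_std = 2, seed = 11)
clip <- generate_sequence(spec)

res <- spot_frozen_frames(clip$stack, config = run_config(25, rho_std = 3))
res
#> spot_result: 1 scene(s), 13 merged minima, selected frames: 58 49 25
head(res$ranked, 4)
#>    t    sigma scene
#> 1 58 19.76413     1
#> 2 49 19.78972     1
#> 3 25 19.93109     1
#> 4  6 19.93905     1
res$gofs[["1"]]
#> gof_set: 3 windows of 5+5 frames, 25% of 120 frames retained
```

The two deepest stillness minima (frames 58 and 49) fall inside the two
frozen plateaus, flanking the planted burst within the `N/2 = 4`-frame
correctness tolerance; the third is a false alarm. The three 10-frame GOF
windows retain 25 % of the clip — a downstream spotting algorithm can skip
the remaining 75 %.

Evaluation utilities (`k_sweep()`, `roc_auc()`, `evaluate_benchmark()`)
score detections against onset/offset annotations: a minimum is *correct*
if it lies strictly within `N/2` frames of the annotated onset or offset,
and the frame-level ROC/AUC is built by sweeping the number of retained
minima `K`.

A command-line front end with `spot`, `evaluate` and `synth` subcommands is
installed under `inst/cli/frozenframes`; templates for running full
CASME II- / MEVIEW-style datasets are in `inst/scripts/`.

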