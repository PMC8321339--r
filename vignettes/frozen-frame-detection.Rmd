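---
title: "Detecting frozen frames for micro-expression spotting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting frozen frames for micro-expression spotting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frozenframes)
```

## The problem and the model

Micro-expressions (MEs) are brief, low-intensity, involuntary facial
expressions. Their short duration (a few frames to half a second) forces
spotting algorithms into expensive frame-by-frame analysis. This package
exploits a complementary, much cheaper cue: a subject concealing an emotion
tends to *freeze* — hold a motionless pose — immediately before and/or
after the ME. Frozen frames are easier to detect than the ME itself,
because detecting the *absence* of motion needs only global, low-resolution
measurements, in the spirit of preattentive human vision (which samples
roughly 13 images per second and fixates for 150–200 ms, i.e. perceives
motion at object scale, not pixel scale).

The detector is a stripped-down motion-energy model. Two separable
spatio-temporal filters share an isotropic spatial Gaussian low-pass
$\rho(x,y)$:

$$h = \rho \cdot \psi \quad \text{(LH pair)}, \qquad
  l = \rho \cdot \phi \quad \text{(LL pair)},$$

where $\phi(t)$ is a temporal low-pass kernel and
$\psi(t) = \mathrm{d}\phi/\mathrm{d}t$ its derivative. For the filtered
sequences $G = f * h$ and $F = f * l$ we track the per-frame spatial
standard deviation (population normalization over the region $\Omega$):

$$\sigma_U(t) = \sqrt{\tfrac{1}{|\Omega|}
  \big\lVert U(\cdot,\cdot,t) - \mu_U(t) \big\rVert^2}.$$

$\sigma_G$ is a motion energy: it is exactly zero on any stretch of
identical frames, and insensitive to global luminance change (a spatially
constant offset never enters a standard deviation). But it is noisy — every
artifact shows up. The key observation is that with $\psi = \phi'$,

$$\frac{\mathrm{d}}{\mathrm{d}t}\,\sigma_F^2(t)
  = \frac{2}{|\Omega|}\,\langle F - \mu_F,\; G - \mu_G\rangle,$$

so frames where the motion response $G$ carries no spatial structure are
critical points of the smooth signal $\sigma_F$. In the regime the method
targets (appearance activity rising above a still baseline), those critical
points are *minima*: stillness can be read off the cheap, noise-robust
low-pass energy instead of hunting zeros of the fragile high-pass energy.

Two caveats, verified numerically in the test suite, are worth stating
plainly:

* the correspondence is a *critical-point* statement. If the appearance
  amplitude of some component crosses zero with nonzero velocity,
  $\sigma_F$ has a genuine local minimum there while $\sigma_G > 0$ — a
  structural false alarm. The oracle tests therefore use non-negative
  activity signals, and on real data false alarms of this kind are
  expected (the top-$K$ selection is what copes with them);
* on a sampled grid a strict minimum of $\sigma_F$ can sit up to half a
  frame from the true stationary point, so $|\sigma_G|$ at the detected
  minimum is bounded by curvature × grid offset, not by machine zero. The
  tests quantify "near zero" against the clip's motion-energy range
  (≤ 15 % of $\max|\sigma_G|$, typically below 3 %) rather than against an
  order statistic like a low percentile, which shrinks faster than the
  grid error at every realistic bandwidth.

## The algorithm and its parameters

`spot_frozen_frames()` runs: scene partition → ROI crop → LL filtering →
$\sigma_F$ → local minima → instability removal → top-$K$ → GOF windows.

| parameter | meaning | default | why |
|---|---|---|---|
| `rho_std` | spatial Gaussian std (px) | 9 | ≈ 1° of visual angle on a face ROI a few hundred px across; scale with face size (the synthetic 64-px faces use 3, the same face-radius/6 ratio) |
| `truncate` | spatial kernel half-width (× std) | 3 | < 0.3 % mass loss before renormalization |
| `phi_kind`, `phi_size` | temporal kernel | box, `max(2, round(fps/25))` | matches the ~13 Hz preattentive sampling rate: length 2 at 25 fps, 8 at 200 fps; must not exceed the shortest expected ME or the smoothing would erase it |
| `N` | maximal expected ME length (frames) | `round(0.32 · fps)` | ≈ 0.32 s upper bound on ME duration: 8 at 25 fps, 64 at 200 fps |
| `tau` | instability threshold (fraction of energy range) | 0.1 | minima within 10 % of the scene's energy range are one oscillation |
| `d` | instability distance (frames) | `round(N/4)` | oscillations within a quarter ME length are not distinct events |
| `K` | minima kept per scene | 3 (< 100 fps), 5 (high fps) | covers the pre- and post-ME freezes plus one false alarm |
| `half_before`, `half_after` | GOF half-widths | 5/5 (25 fps), 16/16 (200 fps) | the method cannot tell whether a freeze precedes or follows the ME, so windows are two-sided |

Numerical conventions, chosen once and used everywhere:

* **boundaries**: reflect (half-sample symmetric) padding in space and
  time. Zero or replicate padding would manufacture energy extrema at clip
  ends, which would pollute the minima list;
* **even-length temporal kernels** center on tap `floor(L/2)+1` (one step
  more past than future);
* **plateau minima** report the first frame of a flat run lower than both
  neighbors, so an exactly frozen plateau contributes one representative
  instead of flooding the list;
* **instability merging** chains *consecutive* minima that satisfy both
  closeness conditions, replaces each chain by its midpoint (rounded
  half-up), and repeats until nothing changes — a single pass can leave a
  fresh midpoint adjacent to a surviving singleton, and iterating makes
  the operation idempotent;
* **ties** in the top-$K$ energy sort break toward the earlier frame;
* reported percentages round half-up (a fully static clip yields an empty
  minima list and a 0 % GOF report, not an error);
* **degenerate inputs**: scenes shorter than the temporal kernel are
  skipped (an error if no scene survives, naming the kernel length); a
  globally constant energy signal has no local minima by definition.

## Evaluation conventions

A detected minimum is *correct* when its distance to the annotated onset
or offset is strictly less than $N/2$ — freezes hug the expression
boundaries, and half the maximal ME length is the alignment slack.
`k_sweep()` reports the percentage of annotated MEs with a correct minimum
among the $K$ lowest-energy detections, for growing $K$.

For the frame-level ROC, the positive class must be fixed before seeing
any detection, so ground-truth-positive frames are the closed annotated
interval $[\text{onset}, \text{offset}]$, and predicted-positive frames
are the union of size-$N$ windows (centered, `[t − N/2, t + N/2 − 1]` for
even $N$) around the $K$ lowest-energy minima; TP/FP/TN/FN are pooled
frame-wise over sequences, the curve is swept over $K = 0..M$ augmented
with (0,0) and (1,1), and the AUC is its trapezoid area.

This convention has a structural consequence worth knowing: a *correct*
detector places its minima a few frames *outside* the ME, so a centered
size-$N$ window can only partly overlap a short ME interval. On the
synthetic benchmark below, pooled TPR saturates around 0.8 however many
minima are added, which caps the AUC near 0.8 even when virtually every
clip is recovered. The per-sequence correctness sweep is the more faithful
summary of detection quality; the frame-level AUC is reported for
completeness and for parameter comparisons, where its biases are constant
across settings.

## The synthetic generator

`generate_sequence()` renders ground-truthed clips so that every stage is
testable without external datasets: a static background with a face
surrogate (smooth Gaussian blob, radius 18 px on a 64×64 frame, contrast
80 over background 100, plus four higher-contrast feature patches),
additive per-frame Gaussian sensor noise, optional global luminance drift,
short low-amplitude **motion bursts** as ME surrogates, exactly frozen
**plateaus**, and ongoing baseline micro-motion everywhere else.

Motion is rendered as **linearized sub-pixel displacement**: translating a
patch $q$ by $\delta$ changes the frame by $-\delta\,\partial_u q$ to
first order, and the generator adds exactly that term with the half-sine
burst profile $\delta(t)$. The reason for linearizing is not convenience
but regime fidelity: an *exact* rigid translation leaves every frame's
spatial statistics unchanged, so after temporal averaging its only trace
in $\sigma_F$ is a second-order motion-blur *dip at peak velocity* — a
translation-only surrogate would put $\sigma_F$ minima at maximum motion,
the opposite of the regime the detector (and the heavy spatial low-pass,
which deliberately crushes sub-pixel translation) is built for. The
appearance-change component that survives the blur is the linear term, and
burst displacement points toward the face centre (a contraction), which
couples positively to the blob and makes each burst a clean positive
excursion of $\sigma_F$.

Baseline micro-motion is a strictly positive "tension" level driving an
inward displacement of all feature patches (1.2 px RMS, smoothed over ~2
frames), plus a smaller zero-mean horizontal wobble. The positivity is
deliberate: a live face is never at its neutral minimum-activity pose
except when deliberately frozen; a zero-mean baseline would constantly
revisit exact neutrality and make ordinary frames as still as frozen
ones, destroying the very contrast the method detects. Inside plateaus
the activity envelope is exactly zero (raised-cosine ramps outside), the
pose is bit-identical before noise, and in `exact_freeze` mode the noise
is suspended there too.

`make_benchmark()` plants one or two bursts per 120-frame clip (4–5
frames, 0.8–1.5 px amplitude), each flanked by a frozen plateau of 3–4
frames immediately before, after, or on both sides (probabilities
0.8/0.1/0.1 — double-sided concealment is the canonical pattern, the
single-sided variants are the robustness minority). Everything is
deterministic from one seed; there are no unseeded entry points.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: head pose rotation and large rigid motion,
lighting changes with spatial structure, compression artifacts, eye
blinks (a notorious false-alarm source), face detection/registration
errors, and the appearance statistics of real skin and facial features.
Results on real corpora depend additionally on the ROI choice (face-crop
versus full frame, which this package leaves to the caller).

## Problem sizes

The automated suite uses sizes chosen to exercise every code path at
interactive speed: the derivative-pair oracle runs 20 seeded 32×32×80
clips; the end-to-end benchmark uses 50 seeded 64×64×120 clips at 25 fps
(noise std 2) and is the same configuration `scripts/acceptance.R`
regenerates from its `--seed`. Full-dataset runs (255 CASME II sequences
at 200 fps, 31 MEVIEW cuts) require the external corpora; ready-made
drivers are in `inst/scripts/`.

## Known limitations

* Pure translational stillness (subject frozen but camera panning
  smoothly) reads as motion; conversely a global luminance flicker reads
  as stillness change only through its interaction with spatial structure.
* The method flags *candidate* neighborhoods; it cannot tell whether a
  freeze precedes or follows its ME, and it never claims the ME interval
  itself — hence the two-sided GOF windows and the structural AUC ceiling
  discussed above.
* Scene partition is a safety net for hard cuts (normalized mean absolute
  difference over 0.1), not a shot-boundary detector; supply explicit cut
  lists for edited footage.
* At very low frame rates the temporal kernel bottoms out at 2 taps, and
  instability merging (with $d = N/4 = 2$) is the main defense against
  noise-induced minima splitting.
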