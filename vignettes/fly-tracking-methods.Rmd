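---
title: "Tracking multiple flies in a backlit arena: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple flies in a backlit arena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrackr)
```

flytrackr turns grayscale video of *Drosophila* on a circular backlit
plate into per-fly trajectories with persistent identities. This
vignette explains the statistical models behind each stage, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the problem left genuine latitude.

## The background model

Backlit plates give a unimodal background: each pixel's fly-free
intensity fluctuates around a single level. We therefore model every
pixel as a Gaussian whose parameters are estimated *robustly* from a
warmup sequence: the location is the temporal median and the scale is
the scaled median absolute deviation,

$$\mu(x,y) = \mathrm{med}_t\, I_t(x,y), \qquad
  \sigma(x,y) = c \cdot \mathrm{med}_t\, |I_t(x,y) - \mu(x,y)|,$$

with $c = 1/\Phi^{-1}(3/4) \approx 1.4826$ so that $\sigma$ is a
consistent estimate of the noise standard deviation under Gaussian
noise. Medians rather than means matter here because flies are present
and moving during warmup; as long as a fly covers a pixel for less
than half the warmup frames, it leaves no trace in the model.

A pixel is declared foreground when its *darkening* exceeds the front
detection threshold:

$$\mu(p) - I(p) > N\,\sigma(p).$$

Flies are dark on a bright plate, which fixes the sign; a config
switch (`polarity`) provides the mirrored and two-sided tests for
other imaging setups. The default `N = 10` reflects a clean backlit
rig — the threshold exists to reject noise, and with screened ambient
light ten robust standard deviations is conservative without costing
detections (fly cores are 50–120 intensity units dark). Two numerical
guards: $\sigma$ is floored at 1 intensity unit (`sigma_floor`), so
noiseless synthetic input cannot make the threshold vacuous, and the
model is only updated every `update_period` frames by exponential
blending with rate `alpha = 0.05`, **restricted to background pixels**.
Freezing foreground pixels is what prevents a fly that stops for
minutes from being absorbed into the background and leaving a phantom
when it moves again. During tracking the frozen set is the union of
the current foreground mask and disks around every live tracker, so a
stopped fly stays protected even if its contrast momentarily drops
below threshold.

## Segmentation and the shape model

Foreground pixels are grouped into 8-connected components (8- rather
than 4-connectivity so that a fly's thin diagonal extremities stay in
one piece). Components are cleaned by a minimum-area rule
$A > \mu_{\text{Areas}} - c\,\sigma_{\text{Areas}}$ with $c = 15$: with
so wide a margin this only strips noise specks, leaving the real
discrimination to the likelihood below.

Each component is summarized by an oriented ellipse via the weighted
covariance

$$W_i = \frac{|I(p_i) - \mu(p_i)|}{\sigma(p_i)}, \quad
  Z = \sum_i W_i, \quad
  \Sigma = \frac{1}{Z}\sum_i W_i (p_i - \bar p)(p_i - \bar p)^\top,$$

with half-axes $a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ and the
orientation of the leading eigenvector, stored modulo $\pi$ in
$(-\pi/2, \pi/2]$ (an ellipse has no head/tail; disambiguation is out
of scope). The brightness weighting makes the fit concentrate on the
dark core — and it is what makes merged blobs splittable, because
raising the local threshold peels the fit back to the cores.

The *shape model* is the population mean and standard deviation of
element areas observed during warmup. One subtlety: the likelihood
compares the **fitted ellipse area** $\pi a b$ to the model, so the
model must be fitted on the same quantity. For a threshold-truncated
Gaussian blob the pixel-count area exceeds $\pi ab$ of the weighted
fit by some 40%, and mixing the two definitions would declare every
normal fly an outlier. The cleaning threshold, by contrast, acts on
pixel counts, where its huge margin makes the distinction immaterial.

## Validation: splitting and discarding by likelihood

Candidate flies are scored with a Laplace-style area likelihood

$$p(x_i) = \exp\!\big(-|\pi a_i b_i - \mu_{\text{Areas}}| \,/\,
  \sigma_{\text{Areas}}\big),$$

and a component whose likelihood falls below $e^{-3}$ (a 3-scale
discrepancy) triggers re-segmentation inside its own region of
interest: the threshold multiplier steps by `dN = 2` for up to
`max_steps = 8` steps — upward if the area is too large (touching
flies), downward if too small (weak artifact). A configuration is
adopted only if its likelihood product improves on the incumbent by
more than 5% — a hysteresis that avoids flip-flopping on marginal
splits. The prior over configurations is uniform: only the per-element
likelihoods and their independence enter the product.

When a raised threshold reveals $k \ge 2$ cores, we do **not** score
the shrunken cores directly: their areas would fail the very test the
split is meant to pass. Instead the original component's pixels are
partitioned by nearest core and one full-extent ellipse is fitted per
part, so split flies are scored at their natural size. On
near-identical synthetic flies $\sigma_{\text{Areas}}$ can collapse
toward zero and make the likelihood hair-triggered, so scoring floors
it at 5% of $\mu_{\text{Areas}}$ (`min_sigma_frac`); real recordings,
with pose and lighting variation, sit well above that floor.

Two overlapping Gaussian-profile flies closer than roughly their
body length leave *no* intensity saddle that any threshold can cut —
the profiles sum. This is why validation alone cannot resolve tight
merges and the tracker has its own merge machinery (below), which is
allowed to probe twice as far up the threshold ladder.

## The plate and reflections

The plate is found by edge detection (Gaussian blur, Sobel gradient,
top-2% magnitude) followed by a circle Hough transform in which each
edge pixel votes along its gradient direction at every candidate
radius. Votes are pooled over 3×3 accumulator cells to absorb
quantization spread; a circle needs a peak holding at least 10% of its
circumference's worth of votes (the noise floor is two orders of
magnitude lower), ties break toward more votes then smaller radius.
Failure — a blank or cluttered frame — degrades to a disabled
full-frame region of interest with a warning, never an error, and a
config override (`plate = c(cx, cy, r)`) bypasses detection entirely.

Specular reflections at the plate wall mimic flies. Detections whose
ellipse lies entirely within a boundary band (`reflection_band = 12`
px) are masked out; a detection merely straddling the band is kept.
When plate detection is disabled the band cannot be placed, and
reflection removal falls to the tracker's stability probation instead
— both paths are exercised in the test suite.

## Tracking: Kalman filters, Hungarian assignment, merges

Each fly carries a six-dimensional state $(x, y, V_x, V_y, \theta,
\omega)$ under a constant-velocity transition (with $dt$ in frames;
frame rate only converts to seconds on output) and a full-state
measurement. Velocity measurements are *not* raw one-frame
differences: they are a recency-weighted moving average of finite
differences over a 5-frame window, with a robustness term that
down-weights differences far from the window median — a single
outlier jump corrects toward the median rather than following the
jump. Angular velocity comes from the same smoother applied to the
unwrapped orientation series (orientation differences taken modulo
$\pi$).

Process and measurement noise are engineering defaults, exposed in the
config: positions $(0.5\,\text{px})^2$, velocities
$(1\,\text{px/frame})^2$, angles $(0.1\,\text{rad})^2$ for $Q$;
the same scales for $R$. They encode "a fly can change speed by about
a pixel per frame per frame" at the reference 4 px/mm, 15 fps imaging
geometry and are not tuned per video.

Identities are assigned by maximizing the total Gaussian score

$$\text{Cost} = \frac{1}{2\pi\sigma_x\sigma_y}
  \exp\!\Big(-\tfrac12\big(\tfrac{x-\mu_x}{\sigma_x}\big)^2
             -\tfrac12\big(\tfrac{y-\mu_y}{\sigma_y}\big)^2\Big)$$

via the Hungarian algorithm on negative log scores (square-padded;
ties broken toward each tracker keeping its incumbent detection).
$\sigma_x, \sigma_y$ come from the predicted covariance diagonal.
Pairs are gated at Mahalanobis distance 4 — with one addition: the
gate scale adds the detection's semi-major axis in quadrature, because
a merged blob localizes the flies inside it only to its own extent,
and a converged tracker's tight gate would otherwise miss the blob
that swallowed its fly. Scores themselves stay on the prediction
errors.

When several trackers share one detection (a merge), resolution
proceeds in order: (1) re-split with a raised threshold — the merge
phase may climb to twice the validation range; (2) if the group is
static, k-means on the component's pixels seeded at the last known
positions, refined by a few EM iterations; (3) otherwise every tracker
in the group takes the shared blob as a measurement with its
covariance inflated 100-fold, so the Kalman prediction dominates but
the estimate stays tethered to the blob. Alternatives — pure coasting,
position-only tethering, and ballistic extrapolation of the
merge-entry velocity — were implemented and measured on the synthetic
crossing scenarios; the weak full measurement produced the fewest
identity errors and no spurious tracks, essentially because it bounds
drift without erasing more information than necessary. Successful
splits use a milder 10-fold inflation since the within-group
assignment is then resolved.

Lifecycle: new trackers are provisional for a 50-frame probation
(at 15 fps) and their rows are buffered — retired provisional
trackers never reach the trajectory table, which is what removes
short-lived reflections. A provisional tracker is retired when its
blob stays gone for more than 2 frames (a 1–2-frame hiccup, e.g. a
brief merge, is tolerated) or when it contests a detection owned by a
mature tracker. A mature tracker missing its fly coasts on the
prediction for up to 15 frames, then waits frozen at its last known
position for up to 450 frames (30 s), then retires with a logged
identity loss. Waiting trackers take no part in assignment — a parked
tracker must not contest a passing fly — and re-acquire only by
proximity re-binding to an unclaimed detection within 20 px.

## Scoring against ground truth

`score_against_truth()` matches output tracks to truth identities
frame by frame (Hungarian on distance, gated at 10 px, with a 1-px
stickiness toward the previous correspondence) and counts swaps,
losses and spurious tracks. A re-match must persist for at least
3 frames to count as a swap: while two flies are merged their
positions are closer together than any matching can discriminate, and
the assignment flickers even when tracking is correct. Persistent
exchanges — the real failure mode — are unaffected by the rule, as the
constructed-exchange test demonstrates.

## The synthetic generator

The generator emulates the reference imaging conditions: a bright
plate of radius 180 px (a 4.5 cm plate at 4 px/mm) on a dark surround,
8 flies (0.12 flies/cm²), 15 fps, additive Gaussian pixel noise
(default sd 2), optional slow sinusoidal illumination drift, and
optional reduced-contrast reflection blobs just inside the wall. Flies
are rendered as anisotropic Gaussian darkening profiles (peak 120
intensity units, profile sds equal to half the nominal half-axes), the
same brightness model the segmentation assumes — which makes
`fit_ellipse`'s recovery targets analytic. Motion is a
heading-persistent random walk with per-fly speeds (~2 px/frame),
specular reflection at the wall, and kinematic pass-through on
contact. Scripted events steer pairs through transversal crossings
(approach directions ~90° apart, speeds capped at physical values) or
stop-and-merge interactions; crossing geometry mirrors how real fly
paths intersect, and a same-direction, same-point merge would carry no
identity information for any position-based tracker.

What the generator does **not** emulate — and hence what green tests
do not certify on real data: fly appearance beyond a smooth ellipse
(wings, legs, grooming postures), appearance differences between
individuals, abrupt jumps and flight, shadows, lens distortion, or
interaction behaviours (chasing, touching) beyond scripted geometric
encounters. Results on the synthetic scenarios bound the *geometric*
difficulty of identity maintenance, not the full biological one.

## Problem sizes and determinism

The shipped tests run the pipeline end to end on 500-frame sequences:
a 4-fly non-interacting recording (320² px) and an 8-fly
forced-crossing scenario at the reference density (400² px, plate
radius 180 px) — sizes chosen so the whole suite completes in a couple
of minutes while still containing tens of genuine occlusion frames.
Every stochastic fixture draws from an explicitly seeded stream; the
generator uses one RNG stream per dataset (seed recorded in the output
metadata) plus a per-frame derived seed for pixel noise, so a dataset
regenerates byte-identically and `track --input --config` output is
reproducible line for line.

## Known limitations

* Identity through a merge rests entirely on motion prediction; two
  flies that meet, travel together, and turn while merged can swap
  with no signal available to prevent it. Appearance-based
  re-identification is explicitly out of scope.
* The validation search assumes one threshold direction per component;
  a blob that is simultaneously too large and contaminated by an
  artifact resolves only as well as the likelihood product allows.
* The plate detector assumes a circular arena; other geometries need
  the manual override.
* The background model is unimodal by design; flickering illumination
  that is bimodal at a pixel violates its assumptions (the robust
  scale absorbs moderate drift only).
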