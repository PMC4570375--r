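# flytrackr

Automated detection, segmentation and identity tracking of multiple
*Drosophila melanogaster* specimens in video recordings of a circular
backlit arena.

Quantitative behavioural work with flies — activity levels, interaction
rates, drug or ageing phenotypes — needs per-individual trajectories
over thousands of frames, which manual annotation cannot deliver
reliably. The hard part is not finding dark blobs on a bright plate but
*keeping each fly's identity* through crossings, overlaps, stops, and
optical artifacts such as reflections at the plate wall. flytrackr
implements a complete pipeline for this problem, together with a
synthetic arena-video generator with ground truth so that every stage
is testable without any recorded footage.

## The method

**Background model.** Each pixel of the fly-free scene is modelled by a
robust Gaussian: location is the temporal median
μ(x, y) = med*t* I*t*(x, y) and scale is the scaled median absolute
deviation σ(x, y) = c · med*t* |I*t*(x, y) − μ(x, y)| with
c = 1/Φ⁻¹(3/4) = 1.4826, so that σ estimates the noise standard
deviation. The model is updated periodically by exponential blending,
but **only at background pixels** — foreground (fly) pixels are frozen,
so a fly that stops never burns a phantom into the model.

**Segmentation.** A pixel is foreground when its darkening exceeds the
front detection threshold: μ(p) − I(p) > N·σ(p), with N = 10 by
default. 8-connected components above a minimum-area threshold
th*min* = μ*Areas* − c·σ*Areas* (c = 15) are fitted with oriented
ellipses by eigendecomposition of the weighted covariance matrix
Σ = (1/Z) Σᵢ Wᵢ (pᵢ − μ)(pᵢ − μ)ᵀ, where Wᵢ = |I(pᵢ) − μ(pᵢ)|/σ(pᵢ);
half-axes are a = 2√λ₁, b = 2√λ₂ and the orientation follows the
leading eigenvector.

**Validation.** Each candidate is scored by the area likelihood
p(xᵢ) = exp(−|π aᵢ bᵢ − μ*Areas*| / σ*Areas*). Low-likelihood
components are re-segmented by locally raising (too large: probably
several touching flies) or lowering (too small: probably an artifact)
the threshold, accepting the configuration that maximizes Π p(xᵢ).

**Tracking.** One Kalman filter per fly with state
(x, y, Vx, Vy, θ, ω) under a constant-velocity model; velocities are
measured by a robust weighted moving average of finite differences,
not raw frame differences. Identities are assigned by the Hungarian
algorithm on the Gaussian score
Cost = (2π σx σy)⁻¹ exp(−½((x−μx)/σx)² − ½((y−μy)/σy)²) between
predicted and detected positions. Merged blobs are re-split with a
raised threshold, resolved by k-means/EM at the last known positions
when static, or ridden out on the prediction with inflated measurement
uncertainty. New trackers face a 50-frame stability probation (at
15 fps), which silently removes reflections and other spurious blobs.

**Metrics.** Identity errors (swaps + losses) are reported per
occlusion event (100·errors/occlusions) and normalized by fly density
and duration (100·errors/(ρ·t)).

## Worked example

Track four flies in a fully synthetic 300-frame recording and score the
result against the generator's ground truth:

```r
library(flytrackr)

cfg <- scene_config(n_flies = 4, seed = 42, width = 320, height = 320,
                    plate_center = c(160, 160), plate_radius = 140)
sq  <- synthetic_sequence(cfg, 300)
res <- track_sequence(sq$frames, pipeline_config(warmup_frames = 60),
                      n_frames = 300)
res
#> fly_tracks: 240 frames tracked, 4 identities, 960 trajectory rows
#>   events: matured=4, spawned=4
res$area_model
#> Area model: mu = 52.47 px^2, sigma = 0.67 px^2 (n = 120, cleaning c = 15)
res$plate
#> Plate ROI: center (160.0, 160.0), radius 140.0 px, band 12 px

s <- score_against_truth(res, sq$truth)
sprintf("swaps: %d  losses: %d  spurious: %d", s$swaps, s$losses, s$spurious)
#> "swaps: 0  losses: 0  spurious: 0"

head(res$trajectories[, c("frame", "track_id", "x_px", "y_px", "status")], 4)
#>   frame track_id     x_px     y_px status
#> 1    60        1 128.2869  48.8837 active
#> 2    60        2 214.7722 115.2879 active
#> 3    60        3 242.7820 158.1954 active
#> 4    60        4 241.2996 229.3893 active
```

The first 60 frames fit the background and the element-area model; the
remaining 240 are tracked. All four identities persist with zero swaps
and zero losses, the fitted mean blob area (52.5 px²) matches the
rendered fly size, and the plate was recovered by the circle Hough
transform at its true center and radius. `plot(res)` draws the
trajectories over the plate outline; `write_trajectories(res, "out.csv")`
exports the standard per-frame CSV.

A shell front end wrapping the same functions lives in
`inst/scripts/flytrack.R`:

```sh
Rscript inst/scripts/flytrack.R simulate --out data/ --frames 500
Rscript inst/scripts/flytrack.R track    --input data/ --output traj.csv
Rscript inst/scripts/flytrack.R evaluate --traj traj.csv --meta meta.yaml --json report.json
```

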