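---
title: "Methods: video-based gait analysis and its validation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based gait analysis and its validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkit)
```

## The measurement problem

Marker-based optical motion capture is the reference standard for gait
analysis but needs a laboratory; a smartphone video processed by a
human-pose-estimation (HPE) model yields 2D landmark trajectories anywhere.
`gaitkit` turns such keypoint trajectories into the standard clinical gait
measures -- heel-strike and toe-off times, temporospatial parameters,
sagittal joint angles -- and quantifies how well they agree with a reference
system. Because HPE output is noisy, occasionally wrong (spikes), and
occluded landmarks are guessed with low confidence ("visibility"), every
stage of the chain has to be explicit about denoising, gaps and failure
modes.

The processing chain is:

1. read keypoints (`read_keypoints()`, `read_mocap_csv()`), with pixel
   image coordinates (origin top-left, y down) and explicit gaps;
2. despike by an acceleration criterion and fill gaps by cubic
   interpolation (`despike_and_fill()`);
3. zero-lag low-pass Butterworth filtering (`lowpass_zero_lag()`);
4. detect heel strikes and toe-offs per side (`relative_ankle_signal()`,
   `detect_events()`), pair them into validated bilateral cycles
   (`pair_bilateral()`);
5. per-cycle temporal and spatial parameters (`temporal_params()`,
   `spatial_params()`), sagittal angles (`joint_angle_series()`,
   `range_of_motion()`);
6. method agreement against a reference (`agreement_report()`:
   MAE, least-squares regression, Bland-Altman limits of agreement).

## Preprocessing model

**Despiking.** The spike statistic is the Euclidean magnitude of the central
second difference of each landmark's position, in units per frame squared.
No universal threshold exists across pixel scales, so the default is robust
and scale-free: 5 times the median absolute second difference of that
landmark's own series (overridable via `preprocess_config()`). Flagged
samples become gaps.

**Gap filling.** Interior gaps no longer than `max_gap_frames` (default 10
frames, about 0.33 s at 30 fps) are filled by a cubic interpolating spline
with FMM end conditions, which reproduces cubic polynomials exactly -- the
property the unit tests pin down. Longer gaps stay open: interpolating
across a long occlusion fabricates motion, and it is better for the
downstream event logic to lose those cycles. Endpoints are never
extrapolated; `extend_edges()` optionally holds the first/last valid sample
so a series can be filtered.

**Filtering.** "Zero-lag" filtering is realised as a forward-backward pass
of an order-4 low-pass Butterworth filter with a 5 Hz cutoff. The two passes
cancel the phase response and square the magnitude response, so the net gain
at frequency $f$ is

$$|H(f)|^2 = \frac{1}{1 + (f/f_c)^{2n}}, \qquad n = 4,\ f_c = 5\ \text{Hz},$$

which the tests check against a 10 Hz tone (gain $\approx 1/257$). Start-up
transients are suppressed by odd-reflection padding plus DC steady-state
initial conditions on each pass; series must be a little longer than the
padding (about 28 samples) to be filterable.

## Event detection

At heel strike the foot is maximally ahead of the body; around toe-off it is
maximally behind. The detection signal is therefore the progression-axis
coordinate of the ankle minus the hip centre (midpoint of the two hips),
oriented so forward is positive: local maxima are heel strikes, local minima
toe-offs. Orientation is inferred from hip drift (overground), foot
orientation (treadmill), or the apparent body-scale change (near-frontal
view); it can be forced.

For a camera placed in front of the walkway the progression axis lies along
the optical axis, so the horizontal image coordinate carries no forward
information. There the signal is the *vertical* image coordinate of the heel
relative to the hip centre: the forward (nearer) foot sits lower in the
image, and the heel is the landmark such cameras see most clearly.

Peaks must have a topographic prominence of at least 25% of the signal's
interquartile range (scale-free, robust to baseline drift), peaks closer
than `min_stride_s` (default 0.6 s, i.e. cadence at most 200 steps/min) are
merged keeping the larger, and strict alternation HS, TO, HS, ... is
enforced by dropping the weaker of two same-type neighbours. Events are
timestamped at the peak sample, so timing error is bounded by one frame
(0.033 s at 30 fps); parabolic sub-frame refinement exists behind the
`refine` flag and is off by default, because the frame bound is the honest
resolution of a 30 fps recording. Whether the underlying peak-picking
convention should place heel strike exactly at the positive peak or at a
zero crossing is a genuinely open choice; the positive-peak reading is
implemented.

Overground bouts are first segmented into straight passes
(`segment_passes()`): runs of consistent smoothed hip-velocity sign lasting
at least 1 s, with a 0.5 s guard band trimmed at each end because steps
adjacent to turns are corrupted by the camera-angle transition.

## Parameters

With $HS_s(k)$ the $k$-th heel strike of side $s$ and $TO$ the toe-offs:
stride time $= HS_s(k{+}1)-HS_s(k)$; step time $=$ time to the next
contralateral strike; stance $= TO_s - HS_s$ within the cycle; swing
$=$ stride $-$ stance (exact by construction); double support is the sum of
the two bilateral-contact intervals in a stride,
$[TO_{\bar s} - HS_s] + [TO_s - HS_{\bar s}]$; cadence $= 60/\text{step
time}$, kept per-cycle so it participates in the all-step analysis.

Step length is the instantaneous heel-to-heel separation along the
progression axis at the striking instant, divided by the calibrated pixel
scale (`calibrate_scale()`, e.g. two floor marks a known 6 m apart). The
instantaneous convention is used for every walking mode: for overground
walking the stance foot is stationary between its strike and the next
contralateral strike, so "contralateral heel at its own preceding strike"
gives the same number; on a treadmill only the instantaneous reading is
defined, since belt-relative displacement is unobservable from a static
camera. Gait speed is step length over step time, an identity the tests
assert. Spatial parameters are refused for near-frontal views (progression
along the optical axis) and need no calibration for 3D capture data
(millimetres). Whether treadmill step length should additionally be
belt-speed-corrected is unknowable from a single static camera; the
instantaneous convention is documented as the package's choice.

## Kinematics

Joint angles come from three-landmark triplets: hip from
shoulder-hip-knee, knee from hip-knee-ankle, ankle from knee-ankle-foot,
with the foot point bound to the toe landmark by default (it gives the
conventional foot-segment direction; configurable to the heel). The interior
angle is computed as `atan2(|cross|, dot)` for stability near 0 and 180
degrees. Hip and knee report flexion $= 180^\circ -$ interior so full
extension reads 0; the sign comes from the triplet's cross-product
orientation, auto-oriented per series so the predominant flexion direction
is positive -- this makes the convention independent of walking direction
and of the image's y-down axis. The ankle reports $90^\circ -$ interior so
the neutral (foot perpendicular to shank) reads 0 with dorsiflexion
positive. Only range-of-motion magnitudes are compared across systems, so
any consistent sign convention reproduces them.

Video angles are computed in the image plane; 3D capture angles in the
sagittal (progression-vertical) plane, by projection before the angle.
Range of motion is max minus min per gait cycle, averaged across cycles
(per-trial max-min would be systematically larger under noise; the
per-cycle reading is the package's documented choice). Angle agreement
between synchronised series is MAE and Pearson correlation.

## Agreement statistics

Cycles from two systems are matched by greedy one-to-one nearest-neighbour
pairing of heel-strike times within 0.25 s (below half the minimum
physiological stride). Differences are signed candidate minus reference.
Two aggregations are reported, because they answer different questions:
`participants_mean` averages a subject's cycles first (how well does the
system measure a person's typical gait?), `all_step` pools every cycle (how
well does it measure a single step?). The report emits, per parameter and
mode: MAE with the SD of absolute differences, the least-squares slope and
intercept of candidate on reference *and* the Pearson correlation -- both
are printed because a single "regression (R)" number is ambiguous between
the two readings -- and the Bland-Altman bias with 95% limits of agreement
$\text{bias} \pm 1.96\,s_d$, where $s_d$ is the sample (n-1) SD of the
differences.

## The synthetic validation model

Real validation recordings pair video with synchronized motion capture;
those are rarely shareable. The generator (`simulate_gait()`,
`simulate_cohort()`) stands in for them with *exact* ground truth. Gait is
kinematically prescribed, not dynamically simulated: periodic hip, knee and
ankle waveforms (two-harmonic shapes scaled to requested ranges of motion,
defaults 29.2/55.6/24.1 degrees) drive a planar thigh-shank-foot chain under
a translating hip. The waveform phase constants were fixed once so that, at
the default stance fraction, the forward excursion of the ankle relative to
the hip peaks at the heel-strike phase and bottoms out at the
stance-fraction phase -- the geometry the detection method relies on; a
piecewise-linear phase warp keeps that anchoring for other stance fractions.

Ground-truth heel strikes are the instants of maximal forward ankle
excursion (computed on the continuous waveforms, not the frame grid);
toe-offs sit at `stance_fraction` through each stride. The requested step
length is honoured by a one-dimensional root solve on the hip waveform
amplitude about its midline, and ground-truth spatial parameters are then
recomputed from the noiseless heel positions at the exact strike instants,
so the stored truth always satisfies the parameter invariants exactly
(`stance + swing = stride`, `speed = length / time`).

Two cameras are modelled. The lateral view is an orthographic projection at
a fixed pixel scale (350 px/m treadmill, 280 px/m walkway -- a 1080p
smartphone framing), with an optional radial quadratic distortion term
(default off) that emulates the wide-angle lenses needed to cover a full
walkway. The near-frontal view is a perspective projection with progression
along the optical axis, which makes spatial parameters degenerate there *by
construction*. Measurement noise is white jitter plus occasional spikes.
Occlusion is stride-periodic: windows whose duty cycle reproduces a target
per-landmark mean visibility ([occlusion_profile()] ships empirical means
for each filming setup, e.g. far knee ~0.27 versus near knee ~0.92 for a
treadmill filmed from the left); occluded samples keep positions -- pose
estimators guess through occlusions -- but with large extra noise and low
visibility, and samples below the visibility floor become gaps.

What the generator does **not** emulate: soft-tissue artefact, pathological
gait phenotypes (festination, freezing, asymmetric timing), autocorrelated
or pose-model-specific estimation bias, lens models beyond the quadratic
term, or out-of-plane motion of the limbs. Tests passing on this generator
therefore demonstrate that the *measurement code* is correct and that the
pipeline degrades in the expected directions (noise up, agreement down;
far side worse than near side; distortion inflating spatial error) -- not
that any specific clinical accuracy will be achieved on real recordings.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: coincident triplet points give NA
angles; zero heel separation excludes the step and flags it; constant
signals yield no events (with a warning); fewer than two strides yields an
empty event set. Ties in peak merging keep the earlier peak. All randomness
flows through one seed; cohorts derive per-subject seeds from the master
seed, so runs are bit-reproducible.

The packaged studies use sizes chosen to make the statistics stable at
interactive cost: a 24-subject treadmill cohort at 30 s per subject and 2 px
jitter for the temporal/agreement checks, 6 subjects for the occlusion
experiment, 4 overground bouts for the step-length and distortion checks,
and 12-20 s single bouts in unit tests.

## Known limitations

* Event timestamps are frame-quantized by design; sub-frame refinement is
  available but off.
* Hip/knee hyperextension reads as negative flexion only through the
  cross-product sign; in a frame where the triplet is exactly collinear the
  sign is undefined (the magnitude is 0, so this is harmless).
* The treadmill step-length convention (instantaneous separation) differs
  from belt-referenced definitions used with instrumented treadmills.
* `agreement_report()` matches cycles through heel-strike anchors; systems
  with clock offsets beyond 0.25 s must be aligned with `trim_sync()` first.
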