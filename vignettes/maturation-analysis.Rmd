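---
title: "Quantifying cisternal maturation from 4D live imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cisternal maturation from 4D live imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgitrace)
```

## The measurement problem

In budding yeast the Golgi is unstacked: individual cisternae are mobile
puncta (~0.5 µm across) that appear, change molecular identity from
ERGIC-like through *cis*, medial and *trans* Golgi to the TGN, and vanish,
all within a few minutes. Dual-color 4D confocal imaging of two tagged
markers on the same cisterna turns this maturation into a measurable
quantity: each marker's fluorescence rises and falls as it is recruited and
released, and the time between the green-channel and red-channel maxima —
the *peak-to-peak duration* — orders the two markers along the maturation
axis. Aggregating pairwise peak-to-peak durations over many marker pairs
yields a single timeline of the whole process.

`golgitrace` implements that analysis chain as reusable, tested components:

1. **Detection** of punctate compartments per 3D frame,
2. **Tracking** of puncta through time,
3. **Trace analysis**: per-cisterna two-channel F/F~peak~ time courses,
   peak-to-peak delays, midpoint-aligned averaged curves and residence
   intervals,
4. **Co-localization**: masked Pearson correlation with Costes automatic
   thresholding and Welch's test for group comparisons,
5. **Line scans** quantifying intra-cisternal zone segregation,
6. **Contact detection** for transient cisterna–ERES "hug-and-kiss" events,
7. **Timeline assembly** from tables of pairwise delays.

Because the original movies are not publicly deposited, the package also
ships a **synthetic-data generator** whose output carries exact ground
truth. Every quantitative claim the package makes about itself is a
recovery statement on that generator.

## The synthetic movie model

`sim_maturation_scene()` plus `generate_movie()` emulate the acquisition
regimes of high-speed spinning-disk confocal imaging of yeast: by default
21 optical slices 0.2 µm apart with one volume every 5 s for maturation
movies (`preset_maturation()`), 9 slices 0.25 µm apart every 1.1 s for
contact movies (`preset_contact()`), and 41 slices for single-timepoint 3D
surveys (`preset_survey()`).

**Kinetic pulse.** Each marker's recruitment is an asymmetric Gaussian:
amplitude × exp(−(t−T)²/2σ²) with separate rise and decay widths
(`marker_kinetics()`). Published time courses are empirical unimodal
curves; any smooth unimodal pulse reproduces them qualitatively, and the
asymmetric Gaussian was chosen because its peak time is exact by
construction, which makes delay-recovery tests sharp. Defaults
σ~rise~ = σ~decay~ = 25 s give visible lifetimes of two to four minutes —
"a few minutes", matching the observed turnover — while keeping the
between-peak dip of a widely separated pair bright enough to track through.

**Geometry and motion.** A cisterna is a Gaussian blob of σ = diameter/4
(default diameter 0.5 µm) convolved analytically with a Gaussian PSF
(lateral σ 0.0765 µm ≈ 180 nm FWHM; axial σ 0.2 µm), i.e. variances add —
no explicit convolution stage is needed. Cisternae perform a confined
random walk (Gaussian steps, σ 0.08 µm/frame, reflected inside a
±0.2 µm box) around home positions laid out on a jittered 3D grid with
≥ ~0.9 µm spacing. Real cisternae are described only as "mobile"; no
velocity or diffusion measurements exist to calibrate against, so these
defaults are chosen to keep tracks linkable at 5 s sampling and are
explicitly *not* validated against real data. The grid layout is a
deliberate simplification: it guarantees that neighboring cisternae remain
resolvable, so tracking performance on the simulator is an upper bound on
real-data performance.

**Zone segregation** is modeled as constant, opposite sub-zone offsets of
the two markers from the cisterna center (`zone_separation`). This is
simpler than a time-varying handover of territory but produces the same
observable the line-scan module measures: separated per-channel peaks along
a scan line through the cisterna.

**Noise.** Expected photon counts (default 200 photons per intensity unit
at the spot peak) pass through Poisson shot noise; Gaussian read noise
(σ 3 counts) and a constant camera offset (100 counts) are added — a
qualitative EM-CCD model. All parameters sit in `acquisition_config()`;
one integer seed makes stacks and ground truth bit-reproducible.

**What the generator does not emulate:** vectorial/aberrated PSFs,
spinning-disk crosstalk, photobleaching (an optional exponential factor was
considered and dropped — peak-time statistics are insensitive to slow
monotone bleaching, which cancels in F/F~peak~ to first order), cytoplasmic
autofluorescence texture, cisterna fission/fusion, and crowding beyond the
grid spacing. Passing recovery tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every failure mode
of real microscopy.

## Detection and tracking

`detect_spots()` is multi-scale Laplacian-of-Gaussian blob detection with
anisotropy handled in physical units: filter scales are micrometers, and
each axis is smoothed by scale/voxel-size voxels. The scale-normalized
response −σ²∇²(G~σ~∗I) is evaluated on a ladder of 4 log-spaced scales
spanning object diameters 0.3–0.8 µm; 3D local maxima that also dominate
adjacent scales and exceed the threshold (default: 8 robust SDs of the
response map, estimated by median + MAD) are reported. Sub-voxel centers
come from per-axis quadratic fits; on noiseless isolated spots the
localization error is below a quarter voxel (tested).

Two numerical details matter in practice:

* **Overlap suppression.** A bright spot sheds weak secondary maxima at
  coarse scales up to ~0.8 µm away. Detections are pruned by non-maximum
  suppression: a weaker spot within `overlap_factor` (default 1.5) times
  the summed blob radii (√3 × measured blob σ) of a stronger one is
  discarded.
* **Size estimation.** The best-responding scale (refined by a parabola in
  log σ) is mapped to an object σ by numerically inverting the analytic
  best-scale relation for a Gaussian blob seen through the anisotropic PSF;
  object and PSF widths add in quadrature and the estimate is floored at
  zero for PSF-limited spots. Reported diameter = 4 σ~object~, the same
  convention the renderer uses.

`link_tracks()` performs frame-to-frame optimal bipartite assignment
(maximum-weight matching via igraph) minimizing total squared displacement
among maximum-cardinality matchings, with links beyond `max_displacement`
(default 0.5 µm per frame interval) forbidden. Tracks stay open across up
to `max_gap` (default 2) missed frames with the gate growing linearly in
the bridged interval. No splitting or merging is modeled — single
cisternae are followed, as in the manual analysis the module automates.
Ties are resolved deterministically, so reruns are reproducible.

`detect_contacts()` declares a contact when a track center stays within
`contact_distance` (default 0.35 µm, roughly the sum of two punctum radii)
of a static ERES punctum for at least `min_frames` consecutive frames.
Duration is (last − first) × frame interval, so a single-frame dip counts
0 s. The original observations report 2–3 s associations without an
operational definition, so this convention is ours; under it, sampling at
interval Δ truncates a true dwell of length L to about L − Δ on average,
which is why recovered durations are asserted only to within one frame
interval of truth.

## Trace analysis

`extract_trace()` averages intensity over a spherical ROI (ellipsoidal in
voxel units, radius 0.35 µm by default — one cisterna radius plus PSF
spread) at the track center of every frame in the track's span, bridged
gaps included via interpolated centers. Background policy defaults to
`"none"` (raw ROI means, as in the published normalization, where the
camera offset cancels between F and F~peak~ up to a shared constant);
`"constant"` and per-frame `"median"` subtraction are available for noisy
synthetic data.

`find_peak()` takes the argmax of a 3-frame moving average (window
exposed; shrinking windows at the edges; ties to the earliest time). There
is no sub-frame interpolation: estimated delays are multiples of the frame
interval. Published mean delays are not such multiples because they
average across cisternae; the same is true here — the grand mean of many
grid-quantized estimates is unbiased, which is what the calibration tests
assert. Cisternae whose smoothed trace is constant, whose peak falls on
the first or last observed frame (a truncated pulse), or whose peak
prominence is below 5 robust noise SDs are excluded from delay statistics
with a logged reason — the automated counterpart of selecting cisternae
with both fluorescence peaks detectable within the observation period. How
the original analysis handled non-unique maxima is unknown; exclusion with
a reason is our choice.

`peak_to_peak()` returns Δ = t~red~ − t~green~ (positive when red peaks
later) and the midpoint (t~green~ + t~red~)/2. `align_and_average()`
shifts each cisterna's clock so time 0 is its midpoint — placing the green
and red peaks exactly at ∓Δ/2 — then linearly resamples F/F~peak~ onto a
common grid and averages with SEM, using only traces that cover each grid
point (observation windows differ per cisterna; no extrapolation).
`residency_interval()` reports where an averaged curve stays above a
threshold fraction (default 0.2) of its peak, interpolated at crossings — a
simple operational residence period.

## Co-localization

`pearson_r()` is the plain masked Pearson coefficient over a whole-cell
ROI. `costes_threshold()` implements the automatic threshold search: fit
B = aA + b by ordinary least squares (as in the original description of
the method; orthogonal regression is a known variant we did not adopt),
then walk T~A~ down the sorted distinct values of A with T~B~ = aT~A~ + b
until the correlation of the sub-threshold voxels reaches zero or below.
Published implementations disagree on whether "sub-threshold" means both
channels below (AND) or either below (OR); both are provided
(`below = "and"` is the default) and both are checked against an
exhaustive-scan oracle in the test suite. With more than 4096 distinct
values the scan uses 4096 evenly spaced levels, keeping the procedure
deterministic. Both the unthresholded r and the r of voxels above both
thresholds are reported, because "the signal threshold was set using
Costes' method" is compatible with either being the published statistic.
Group comparisons use Welch's unequal-variance t-test
(`welch_t_test()`, via `stats::t.test`); multiple-comparison procedures
(Dunnett, Tukey) are out of scope since they change significance stars,
not correlation values.

## Timeline assembly

Pairwise mean delays constrain only differences of peak times, so
`assemble_timeline()` estimates marker peak times by weighted least squares
on the pairwise-offset graph: minimize Σ w~ij~(t~j~ − t~i~ − Δ~ij~)² with
the anchor fixed at 0, solved from the normal equations within the
anchor's connected component (other markers are reported unplaced). This
is the standard estimator for pairwise-offset observation models; with
consistent inputs it reproduces the true assignment exactly, and with
inconsistent ones the per-edge residuals quantify the tension rather than
hiding it. Default weights n/max(sd, 5 s)² use the published per-pair
sample sizes and SDs; the 5 s floor (one frame interval) prevents a pair
with a near-zero printed SD from dominating. Fluorophore-tag variants of
one protein (Sec7-iRFP/tagRFP/mRFP and the like) merge into one node by
default (`strip_fluorophore_tags()`), which is what connects the
TGN-export pair into the main component; a flag keeps them distinct.

One merge deserves a caveat: a marker that genuinely appears twice during
maturation (Ypt1, at the ERGIC and again near the TGN) becomes a single
node whose fitted time is a weighted compromise, and it drags its
*trans*-Golgi partners with it. The residuals of the full-table fit make
this tension visible; resolving it would require splitting the marker into
two episodes, which the pairwise delay table alone cannot justify.

```{r timeline}
tab <- read_delay_table(system.file("extdata", "peak_to_peak_delays.csv",
                                    package = "golgitrace"))
tl <- assemble_timeline(tab, anchor = "Mnn9")
round(tl$times, 1)
tl$rms_residual_s
```

## Calibration experiments and problem sizes

`delay_recovery_experiment()` is the package's own calibration: simulate
movies whose per-cisterna delays are drawn from a programmed normal
distribution, run the full pipeline, and compare the grand mean of the
estimated per-movie mean delays with the programmed mean. Delays are drawn
antithetically — (μ + σz, μ − σz) pairs, so each draw is still marginally
normal with the programmed mean and SD, but the realized per-scene mean
hugs the programmed one. This is ordinary Monte-Carlo variance reduction:
it sharpens the benchmark so that what it measures is estimator bias, not
the luck of the draw. The shipped
acceptance checks run four regimes spanning the measured range — mean ± SD
(cisternae count) of 31.0 ± 24.1 s (10), 3.9 ± 9.0 s (31, testing sign
handling near synchrony), 76.2 ± 21.7 s (13) and 51.9 ± 23.2 s (7) — at
20 replicates each, with movies of 64–96 px × 21 slices and roughly 20–45
frames; a full four-regime run takes a few minutes on one core. Observation
windows are sized so that delays within 3.5 SD of the programmed mean keep
both peaks inside the movie; the residual truncation of more extreme draws
biases the grand mean by well under 0.1 s. Analogous experiments exist for
diameter recovery (`diameter_recovery_experiment()`, 50 isolated spots)
and contact-duration recovery (`contact_recovery_experiment()`).

## Known limitations

* Estimated delays are grid-quantized (no sub-frame peak interpolation);
  per-cisterna errors are up to half a frame interval even without noise.
* The tracker does not model splitting/merging; movies of dividing or
  colliding compartments will fragment.
* The simulator's motion and SNR defaults are plausibility choices, not
  fits to data; recovery results certify the estimators, not the realism
  of the generator.
* `costes_threshold()` assumes a positive A–B regression slope; strongly
  anti-correlated channels return a flagged result instead of thresholds.
* Timeline assembly treats each printed mean delay as an independent
  Gaussian measurement; correlations induced by shared reference markers
  are ignored, as they are unrecoverable from the published table.
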