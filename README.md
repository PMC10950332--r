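# golgitrace

Quantitative analysis of Golgi cisternal maturation from multi-channel 4D
(xyz + time) live-cell fluorescence microscopy, for cell biologists studying
membrane traffic in budding yeast and similar systems with unstacked,
mobile Golgi cisternae.

In these data a single cisterna is a ~0.5 µm punctum that lives for a few
minutes while its molecular identity matures (ERGIC → *cis* → medial →
*trans* Golgi → TGN). Imaging two tagged markers on the same cisterna gives
two unimodal fluorescence pulses, and the core statistic is the
**peak-to-peak duration**

&nbsp;&nbsp;&nbsp;&nbsp;Δ = t(F<sup>red</sup><sub>peak</sub>) − t(F<sup>green</sup><sub>peak</sub>),

the time between the channel maxima of the F/F<sub>peak</sub>-normalized
traces, positive when the red marker peaks later. Per-cisterna traces are
aligned at the midpoint (t<sub>green</sub> + t<sub>red</sub>)/2 before
averaging, and a global maturation timeline is inferred from many pairwise
Δ's by weighted least squares on the pairwise-offset graph
(min Σ w<sub>ij</sub>(t<sub>j</sub> − t<sub>i</sub> − Δ<sub>ij</sub>)²,
anchor fixed at 0).

The package covers the full chain:

* `sim_maturation_scene()`, `sim_contact_scene()`, `generate_movie()`,
  `generate_coloc_phantom()` — ground-truthed synthetic spinning-disk
  movies (asymmetric-Gaussian marker kinetics, confined random-walk
  motion, Gaussian object ⊗ PSF rendering, Poisson + read noise);
* `detect_spots()` — multi-scale Laplacian-of-Gaussian detection on
  anisotropic voxel grids, sub-voxel centers, PSF-corrected diameters;
* `link_tracks()`, `detect_contacts()` — optimal bipartite linking with
  gap closing; transient cisterna–ERES contact ("hug-and-kiss") events;
* `extract_trace()`, `find_peak()`, `peak_to_peak()`,
  `align_and_average()`, `residency_interval()` — F/F<sub>peak</sub>
  traces, delays, midpoint-aligned mean ± SEM curves, residence periods;
* `pearson_r()`, `costes_threshold()`, `welch_t_test()` — masked Pearson
  co-localization with Costes automatic thresholding;
* `profile_along_line()`, `segregation_metrics()` — line scans and
  intra-cisternal zone-segregation metrics;
* `read_delay_table()`, `assemble_timeline()`, `order_markers()` — global
  timeline from pairwise delays (a transcribed table of measured marker
  pairs ships in `inst/extdata/peak_to_peak_delays.csv`);
* `analyze_movie()`, `run_pipeline()`, `write_stack()`/`read_stack()` —
  the end-to-end pipeline and calibrated TIFF + JSON-sidecar I/O.

## Worked example

Simulate a two-marker movie whose red-minus-green delays are drawn from
N(31.0, 24.1²) s — the distribution measured for an ERGIC marker maturing
into a *cis*-Golgi marker — and recover the delay statistics with the full
detect → track → trace → summarize pipeline:

```r
library(golgitrace)

scene <- sim_maturation_scene(n_cisternae = 10, delay_mean = 31,
                              delay_sd = 24.1, seed = 1)
cfg <- scene$config; cfg$seed <- 1
movie <- generate_movie(cfg, scene)
res <- analyze_movie(movie)

head(res$pairs, 3)
#>   track t_green_peak t_red_peak delta_s midpoint_s
#> 1     1           80        125      45      102.5
#> 2     2           75        105      30       90.0
#> 3     3           75        115      40       95.0

res$summary
#> maturation_summary: n = 10 cisternae
#>   peak-to-peak delay: 32.0 +/- 15.7 s (mean +/- SD), SEM 4.96 s

mean(movie$truth$cisternae$delta_true_s)  # realized ground truth
#> [1] 31
```

All ten simulated cisternae are recovered, and the estimated mean delay
(32.0 s) matches the realized ground-truth mean (31.0 s) to within the
5 s frame interval; `res$excluded` lists any track dropped from the
statistics together with the reason.

Assembling the global timeline from the bundled pairwise-delay table,
anchored at the *cis*-Golgi reference marker Mnn9:

```r
tab <- read_delay_table(system.file("extdata", "peak_to_peak_delays.csv",
                                    package = "golgitrace"))
assemble_timeline(tab, anchor = "Mnn9")
#> timeline anchored at Mnn9 = 0 s (weighted RMS residual 5.3 s)
#>  Sys1  Imh1  Grh1  Apl6  Ypt1 Emp46  Erd2  Rer1  Gea1  Sed5  Mnn9  Vrg4  Mnn2
#> -39.3 -38.7 -38.5 -33.5 -19.6 -18.8 -16.4 -14.4  -6.0  -1.2   0.0  11.9  18.3
#>  Gnt1 Sec21  Gea2  Sec7  Tlg2  Gga1 Ypt32
#>  28.7  37.9  58.7  62.9  68.0  78.7 114.8
```

Negative times are markers peaking before Mnn9 (the ERGIC/pre-*cis*
group), positive times the medial/*trans*/TGN progression, with the
TGN-export marker Ypt32 last. The RMS residual quantifies the tension
between overlapping measurements (see the methods vignette,
`vignettes/maturation-analysis.Rmd`, for why the merged
twice-appearing marker Ypt1 drags Sys1/Imh1/Apl6 early).

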