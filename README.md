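# cardiomorph

Quantification of *Drosophila* heart tube closure and cardioblast migration
from time-lapse annotations.

During heart tube formation, two contralateral rows of 52 cardiac
progenitors (cardioblasts) migrate toward the dorsal midline and enclose a
lumen. `cardiomorph` is for researchers who have per-frame luminal outlines
and/or nuclear centroid tracks (e.g. from semi-automatic or neural-network
segmentation) and want the standard dynamic readouts, plus a
female-versus-male comparison at the embryo level. It does **not** segment
images: it consumes annotations.

## What it computes

**Tissue level.** Per-frame luminal area *a*, perimeter *p*, circularity

&nbsp;&nbsp;&nbsp;&nbsp;*c*(*t*) = 4π·*a*(*t*) / *p*(*t*)²,

and maximum anterior-posterior / medial-lateral lengths (caliper-axis
construction). Time is registered to the last frame at which the ML luminal
extent exceeds 80 μm, and the closure rate constant *k* (hr⁻¹) comes from
fitting the registered areas with a decaying exponential

&nbsp;&nbsp;&nbsp;&nbsp;*a*(*t*) = *A*·e^(−*kt*).

**Cell level.** From nuclear tracks (time origin: last frame with mean
contralateral nuclear distance > 65 μm): migration speed (OLS slope of
displacement vs time), oscillation period (first autocorrelation peak of
the medial velocity, parabolically refined), and the decomposition of each
trajectory into medial (toward midline) and lateral steps, with
net medial step = medial − lateral amplitude.

**Statistics.** Embryonic means compared with two-sided Mann-Whitney tests
(exact for small tie-free groups, corrected normal approximation
otherwise), summarised as mean, s.d. and s.e.m.

**Validation.** A first-class synthetic generator produces closing-lumen
polygon series, oscillatory contralateral tracks, whole two-group cohorts
with ground-truth tables, and rendered image stacks for kymographs.

## Worked example

```r
library(cardiomorph)

# a synthetic embryo closing at k = 1.4 hr^-1 with 5% area noise
series <- gen_lumen_series(lumen_sim_params(k_true = 1.4, seed = 1))
fit <- closure_rate_pipeline(series)
fit
#> <closure_fit> sim_lumen: A = 978.6 um^2, k = 1.397 hr^-1 (rmse 27.4, 237 frames)
glance(fit)
#> # A tibble: 1 x 5
#>   A_um2 k_per_hr  rmse n_frames_fit converged
#>   <dbl>    <dbl> <dbl>        <int> <lgl>
#> 1  979.     1.40  27.4          237 TRUE
```

The recovered `k_per_hr` of 1.40 is the generating rate: registration found
the threshold crossing, and the exponential fit ran on the 237 post-origin
frames. On the cell side:

```r
tracks <- gen_tracks(track_sim_params(mode = "ratchet", n_per_row = 52,
                                      medial_step = 1.9, lateral_step = 0.8,
                                      period = 1.7, seed = 1))
embryo_oscillation_summary(tracks)
#> # A tibble: 1 x 8
#>   embryo_id  sex     n_cardioblasts speed_um_hr period_min medial_amp_um
#>   <chr>      <chr>            <int>       <dbl>      <dbl>         <dbl>
#> 1 sim_tracks unknown            104        44.0       1.50          1.97
#> # i 2 more variables: lateral_amp_um <dbl>, net_medial_step_um <dbl>
```

All 104 cardioblasts (52 per row) are analysed; the medial step amplitude
(1.97 μm, vs 1.9 generated plus 0.2 μm position noise) and the period
(1.50 min: the ratchet generator quantises the 1.7 min nominal period to
the 15 s frame grid) are recovered, and the net drift implied by the steps
appears as the speed. Group comparison of per-embryo rate constants:

```r
mann_whitney_u(c(1.38, 1.45, 1.42, 1.51, 1.33, 1.40, 1.44),   # 7 females
               c(1.19, 1.25, 1.16, 1.21, 1.08, 1.24, 1.31, 1.18)) # 8 males
#> # A tibble: 1 x 3
#>       U  p_value method
#>   <dbl>    <dbl> <chr>
#> 1    56 0.000311 exact
```

The full pipeline is also available as three composable stages —
`cmd_simulate()`, `cmd_quantify()`, `cmd_compare()` (plus
`cmd_kymograph()`), each writing delimited tables and a JSON manifest —
and as a thin command-line wrapper in `inst/cli/cardiomorph.R`. Each result
type has an `autoplot()` method; `tidy()`/`glance()` work on fits. See the
vignette `vignettes/heart-tube-closure-quantification.Rmd` for the methods
and their assumptions.

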