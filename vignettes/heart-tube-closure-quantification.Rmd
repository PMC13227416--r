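---
title: "Quantifying heart tube closure and cardioblast migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heart tube closure and cardioblast migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomorph)
```

## The biological measurement

During *Drosophila* embryogenesis the heart forms as two contralateral rows
of 52 cardiac progenitors (cardioblasts) migrate toward the dorsal midline,
where they meet and enclose a tube. Two complementary views of this process
can be quantified from time-lapse microscopy sampled every 15 s:

* **Tissue level** — the luminal region between the converging primordia,
  annotated as a closed polygon per frame. Its area shrinks approximately
  exponentially, and its shape (circularity, anterior-posterior and
  medial-lateral extents) characterises tube morphology.
* **Cell level** — the centroid trajectory of each cardioblast nucleus.
  Cardioblasts do not advance monotonically: they take cyclic medial
  (forward) and lateral (backward) steps that are rectified into net medial
  motion, so a trajectory decomposes into a drift, an oscillation period,
  and step amplitudes.

`cardiomorph` implements these quantifications, a female-versus-male group
comparison at the embryo level, and a synthetic-data generator with known
ground truth that the whole pipeline is validated against. Coordinates are
micrometres with x along the medial-lateral (ML) axis and y along the
anterior-posterior (AP) axis; only coordinate differences are ever used, so
the per-embryo origin is arbitrary.

## Time registration

Embryos are aligned in time by a threshold rule rather than by an external
clock: the origin `t0` is the **last** frame at which

* the ML extent of the luminal outline exceeds **80 um** (tissue analyses), or
* the mean distance between contralateral nuclei exceeds **65 um** (cell
  analyses).

"Last" makes the rule robust to early fluctuations around the threshold: in
noisy series the extent may dip below and re-exceed the threshold, and the
literal last exceedance is taken. If no frame exceeds the threshold, the
first frame is used and a warning with class
`cardiomorph_fallback_warning` is raised — the series is then analysed in
full rather than silently dropped. The ML cable-to-cable distance is
operationalised as the ML extent of the luminal outline, which the
contralateral actin cables bound; the package documents this proxy rather
than measuring the cables themselves.

## Closure kinetics

Registered luminal areas are fitted with the decaying exponential

$$a(t) = A\,e^{-kt},$$

with `A` (um^2) a free amplitude and the closure rate constant `k` reported
in hr^-1. The fit uses only frames with registered `t >= 0`: pre-origin
frames belong to the plateau, not the decay. `A` is deliberately not pinned
to the first registered area — freeing it absorbs registration jitter, and
because an exponential restarted from any origin is still an exponential
with the same rate, `k` is insensitive to where registration lands within
the decay.

Numerically the fit is Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) initialised from the log-linear regression of
`log(a)` on `t`, with `k` bounded below by 0 (closure is a decay by
definition; a constant series yields `k = 0`). Optimiser failure returns
the log-linear initial estimates flagged `converged = FALSE` instead of
raising, so one pathological embryo cannot abort a cohort run.

## Lumen morphometrics

Per frame the package reports area (absolute shoelace value, orientation
independent), closed-contour perimeter, circularity
$c = 4\pi a / p^2 \in (0, 1]$, and the maximum AP/ML lengths. The "longest
axis" is defined geometrically as the maximum caliper diameter — the
farthest pair of convex-hull vertices — and the outline is rotated about
its centroid so this axis is vertical before reading off the y-extent (AP
length, equal to the diameter) and x-extent (ML length). This matches a
brute-force search over rotation angles at 0.01 degree resolution to within
0.1% in the test suite, and is invariant to rigid rotation of the input. A
repeated closing vertex is deduplicated on load; perimeter always includes
the closing edge.

## Cardioblast dynamics

**Pairing.** Left and right rows are each ranked by mean AP position and
paired by rank; rows are ordered collectives with preserved neighbour
relations, so rank pairing is used instead of optimal assignment. Surplus
tracks on the longer row are reported and left unpaired.

**Speed** is the ordinary least-squares slope of the displacement from the
track's first position against time (um/hr). Displacement, not cumulative
path length, is used: the path length of an oscillating nucleus grows with
the oscillation amplitude and would conflate stepping with migration,
whereas the displacement slope recovers the drift of a drift-plus-sinusoid
track to within a few percent.

**Period.** The medial velocity (finite difference of the signed medial
position, positive toward the midline for either row) is autocorrelated
with the biased estimator, which guarantees decay with lag. The period is
the lag of the first local maximum at lag >= 2, refined by three-point
parabolic interpolation so that off-grid periods (e.g. 1.7 min sampled at
0.25 min) are resolved below the lag grid. The first peak must additionally
exceed the 95% white-noise confidence bound $1.96/\sqrt{n}$; a merely
positive peak is not evidence of periodicity, and without this gate
noise-only traces would be assigned a period most of the time. Tracks with
no qualifying peak get a missing period, which propagates as `NA` (never
zero) and is excluded from embryo-level period means only.

**Step decomposition.** The signed medial position is smoothed with a
centred moving average (default window 3 frames = 45 s) for extremum
*detection*; each detected extremum is then snapped back to the raw trace
within the smoothing half-window, and both the prominence pruning (default
0.3 um) and the amplitudes use raw values. Measuring on the smoothed trace
would bias triangle-like waveforms down by roughly the per-frame slope and
was rejected. A medial step is the excursion from a local minimum to the
next local maximum; a lateral step the reverse; by construction
`net_medial_step = medial_amp - lateral_amp` exactly. Excursions truncated
by the start or end of the recording are discarded whenever at least one
complete interior excursion exists — a partial boundary excursion is not a
complete step — but a strictly monotone track still yields its single
boundary-to-boundary step. The smoothing window and prominence defaults are
package choices (the underlying step-extraction protocol is not fully
specified in the source literature) and are exposed in `run_config()`.

## Group statistics

Embryonic means are compared between females and males with two-sided
Mann–Whitney tests: exact p-values (via `wilcox.test`) when both groups
have at most 10 embryos and the data are tie-free, otherwise the normal
approximation with tie and continuity corrections, with the method switch
recorded per metric. The exact branch is verified in the tests against an
independent full enumeration of all `choose(n1 + n2, n1)` group
assignments. Group summaries report mean, sample SD and SEM = SD/sqrt(n),
the three quantities of the standard box summary. No multiple-testing
correction is applied across metrics, matching per-metric reporting, and
embryos of unknown sex are excluded (with a note) rather than guessed —
mirroring workflows where sex is assigned post hoc from later development.

## The synthetic-data generator

The generator is the package's ground truth and defines the conditions the
validation runs under; its defaults are the study design: 7 female and 8
male lumen embryos, 6 and 6 track embryos, 52 cardioblasts per row, 15 s
frames, and group parameters at the reported values (closure rate 1.4 vs
1.2 hr^-1 with SD 0.1; period 1.7 vs 1.4 min with SD 0.8; medial steps 1.9
vs 2.0 um; lateral steps 0.8 vs 0.7 um; speeds near 23 um/hr).

**Lumens.** Each frame is an elliptical polygon whose vertex count, area
and ML extent are set exactly (the discretisation factor of the n-gon is
corrected analytically). The AP extent stays fixed while the ML width
carries the whole decay — the slit-like geometry of two rows closing a gap
— so that area and ML extent both decay as `exp(-kt)`. The decay-onset ML
width defaults to 80.3 um, just above the 80 um threshold: the plateau
frames (which hold the onset shape) all exceed the threshold and the first
decay frame falls below it for rates near the observed ones, making the
last plateau frame the exact registration origin with no discontinuity in
the area series. Noise enters as a multiplicative area factor (isotropic
rescaling, default 5%) and per-vertex Gaussian jitter (default 0.1 um).

**Tracks.** Rows start at ±37.5 um (75 um separation, above the 65 um
registration threshold) with 5 um AP spacing. Two medial waveforms are
available: `drift_sinusoid` (`m(t) = vt + B sin(2πt/T)`) for speed/period
recovery, and `ratchet` (linear advance of `medial_step`, linear retreat of
`lateral_step`, equal phase durations) for step recovery. Ratchet phases
are quantised to an integer number of frames so that the waveform extrema
lie on the sampling grid and the amplitudes are exactly recoverable; the
realised period is therefore the nominal period rounded to the frame grid
(1.7 min becomes 1.5 min at 15 s sampling). Position noise (default 0.2 um
per coordinate) is added independently per sample.

Every generator is a pure function of its parameter object including the
seed. What the generator does **not** emulate: segmentation error
structure, uneven sampling, cell divisions or track loss, myosin dynamics,
photon noise. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated motion and noise models, not robustness to
every artefact of real microscopy.

**Cohorts** draw per-embryo parameters from the group means with the
between-embryo SDs (mildly truncated to stay physical: rates >= 0.2 hr^-1,
periods >= 0.6 min, lateral steps positive and below 0.9 of the medial
step). Cohort track embryos use the ratchet mode, so their speed ground
truth is implied by the drawn step amplitudes and period. With identical
group parameter lists the cohort is a null cohort; the Mann–Whitney
calibration runs 1000 such null draws at n = 6 + 6 at the embryo level —
under the null the embryo values are exchangeable, which is exactly what
calibrates the test — and observes a rejection rate in [0.02, 0.09] at
alpha = 0.05, the mild conservatism expected of an exact test at small n.

## Problem sizes and determinism

The validation suite uses 20 lumen series per rate (250 frames, 100
vertices), 50 tracks for speed and period recovery (241 and 161 samples),
one 121-frame ratchet track for exact step recovery, 1000 null cohorts for
calibration, and 100 random convex polygons against the 0.01 degree
rotation oracle. Pipeline runs (`cmd_simulate`/`cmd_quantify`/
`cmd_compare`) are byte-deterministic for a fixed seed; every warning
raised during a stage is collected into that stage's JSON manifest along
with the config snapshot, input checksums and timings.

## Known limitations

* The lumen-extent proxy for the cable-to-cable distance assumes the
  luminal outline is bounded by the cables at every frame.
* Period estimation assumes near-uniform sampling; gaps in a track shift
  the effective lag grid.
* Step decomposition with fewer than ~2 cycles of data cannot separate
  drift from stepping; such tracks report their single net excursion.
* Only a single exponential closure model is offered — no logistic or
  bi-exponential alternatives, and no model selection.
* The comparison machinery tests differences; it does not quantify
  evidence *for* equivalence (no TOST or Bayesian analysis).
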