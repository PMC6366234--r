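---
title: "Methods: from stork movement to a static uplift and energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stork movement to a static uplift and energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Soaring birds subsidize flight with rising air. Where uplift is available
they circle upward and glide on; where it is absent they must flap, which
for a large bird is by far the most expensive thing it does with its time.
This package implements a complete analysis chain that treats the birds
themselves as uplift sensors: soaring tells us an uplift was present,
high-altitude flapping tells us one was absent, and the climb rate while
soaring tells us how strong the uplift was. Static landscape descriptors —
topography, greenness, land use — are then used to predict where uplift
occurs, how strong it tends to be, and what that structure costs the birds
energetically.

Every stage is validated against a synthetic-data generator that plants a
known uplift field in a simulated landscape, so the whole chain can be
tested for parameter recovery rather than merely for plausibility.

# The synthetic study system

`generate_landscape()` builds co-registered 100 m rasters from smoothed
Gaussian random fields: a DEM (broad relief of s.d. 250 m with fine-scale
relief of s.d. 40 m), NDVI in [-1, 1], a categorical land-use layer
(bare soil, water, urban, wetland, dump, pasture, forest), an urban
footprint and a latitude band anchored at 44 degrees N. The true uplift
probability is logistic in standardized roughness (+2.8), elevation (+2.0)
and NDVI (-1.3) with land-use offsets (urban -2, wetland -1.5, dump -1) and
intercept +2.4; water cells are forced to zero (water produces no thermals).
The true uplift intensity rises with uplift probability
(0.4 + 1.6 p, in m/s) and falls with latitude. The latitude slope
(-3 m/s per degree) is deliberately steep: it compresses a continental-scale
gradient into the ~0.14 degree band of a 15 km landscape so that the
latitude effect remains estimable at the fixture's extent.

The two dynamic predictors — thermal and orographic uplift potential — are
emitted as coarse, noisy views of the true intensity field and of a
roughness-derived proxy (block-averaged over 15 cells, noise s.d. 0.25).
The coarseness is what makes them weaker predictors than the static layers,
which mirrors how reanalysis-derived uplift estimators behave against
100 m landscape data.

`simulate_tracks()` then flies birds across this landscape on a 15 s
behavioural tick (the duration of one soaring circle). At each decision
point the bird draws Bernoulli(p_uplift) at its current cell. On success it
soars for 90 s — circling with 20-40 m radius, or climbing straight for the
22% of soars that are linear — at a climb rate drawn around the cell's true
intensity, then glides straight for 60 s at a 1.95 m/s sink. On failure it
flaps for 6 s and glides out the rest of the tick. Circle entry and exit
are tangential to the current heading, and bouts are aligned to the tick,
so 15 s track segments are behaviourally pure; this is what makes the
segmentation's noise-free accuracy a meaningful ceiling rather than an
artifact of boundary segments. Two structural choices matter downstream:

* The glide after a soar lasts 60 s, which equals the event-separation
  rule (below). Each successful uplift exploitation therefore becomes its
  own soaring event, so presences sample the landscape in proportion to
  p_uplift — without this, consecutive successes merge and presences would
  sample p(1-p), biasing the suitability threshold.
* The bout durations were chosen so the realized behavioural budget
  reproduces the study conditions: about 0.51 of classified flight time
  soaring and about 0.05 of classified ACC flight time flapping, at the
  attempt-weighted success rate (~0.5) the landscape defaults produce.

Devices follow the real duty cycle: a plain GPS fix every 5 min, 1 Hz GPS
bursts of 300 s every 15 min, and a 3.8 s tri-axial ACC burst (40 samples
per axis at 10.54 Hz) every 10 min with a per-bird phase offset —
without the offset, burst starts would align with the behavioural tick and
over-sample flapping. Flapping puts a ~1.2 g wingbeat oscillation at 3.5 Hz
on the heave axis; soaring and gliding carry only small dynamic noise
(0.03 g and 0.08 g). GPS error is an AR(1) process (marginal s.d. 3 m
horizontal, 5 m vertical, lag-1 correlation 0.95 at 1 Hz): GPS error is
strongly autocorrelated in reality, and modelling it white would wreck
track geometry at 1 Hz — a straight glide would accumulate hundreds of
degrees of spurious turning.

What the generator does *not* emulate: weather and wind (uplift is a static
field plus Bernoulli noise), social behaviour, route choice, device
dropouts, and terrain-following flight. Passing tests therefore show that
the chain recovers what it assumes — not that real storks obey those
assumptions.

# Behavioural segmentation (GPS)

Bursts of at least 120 s are cut into consecutive 15 s segments carrying
the mean vertical speed (forward height differences) and the absolute
cumulative turning angle (planar bearings; burst extents are far below the
scale where projection error matters). The turning angle at a window's
first fix describes the corner *into* that window — its geometry lives in
the previous step — so it is attributed to the previous window. A full
circle then sums to ~360 degrees and a straight glide entered from a circle
stays near zero.

Classification is an expectation-maximization binary clustering: a
four-component Gaussian mixture (diagonal covariances) on the two metrics,
constrained so components occupy the four quadrants of two per-variable
low/high delimiters; the delimiters are recomputed each EM step as the
midpoint between the low- and high-group component means, and component
means are clamped to their side. Labels follow the fitted delimiters, not
component membership: a component can lodge in the upper turning tail of
the glide cloud, and labelling by membership would hand a quarter of glides
to circular soaring. Segments above the turning delimiter are circular
soaring; the rest are linear flight, split by the sign of their own mean
vertical speed into linear soaring and gliding. Numerical safeguards: EM is
initialized from the per-variable median split, variances are floored at
1e-3 of the data s.d., convergence is a 1e-6 relative log-likelihood change
within 200 iterations (failure is an error, not a silent result), and if
the low/high turning group means sit closer than 45 degrees the data are
treated as a single turning regime (all linear below a pooled mean of
180 degrees, all circular above).

A single smoothing pass relabels any segment that differs from both
immediate neighbours to the modal label of the two segments before and
after (self excluded, tie keeps the original, edge segments with one
neighbour are never touched). Soaring segments (circular + linear pooled)
then become events: runs separated by less than 60 s merge, events with
more than 30 s of soaring survive, and the event centroid is the
fix-weighted mean position.

# Accelerometry

ODBA uses the whole-burst mean per axis as the static component — the
bursts last 3.8 s, well below the window lengths where a running mean would
differ — and sums absolute dynamic components across axes per sample. Mean,
sum and s.d. of per-sample ODBA and of the absolute dynamic heave component
give six statistics per burst; all six feed a standardized k-means (k = 3,
25 restarts, seeded), and clusters are ranked by centroid mean ODBA into
least / intermediate / most active. Bursts are geolocated by time-linear
interpolation between bracketing GPS fixes; height above ground (ellipsoid
height of the nearest fix minus the DEM at the burst location, nearest-cell
lookup) is only assigned when that fix is under 30 s away. Most-active
bursts above 100 m become uplift absences — the height filter removes
take-off flapping.

# Uplift suitability

Presences (event centroids) and absences (flapping bursts) are annotated
with predictors under three frameworks: static (DEM, slope, aspect,
roughness, TPI, slope and aspect unevenness, NDVI, land use, urban
footprint), dynamic (the two uplift potentials), and combined. Land use is
one-hot encoded so the forest attributes importance per class. Terrain
derivatives use Horn's 3x3 method for slope and aspect (the de-facto GIS
standard; flat cells get missing aspect rather than an arbitrary number),
max-minus-min roughness, centre-minus-neighbour-mean TPI, and 3x3 standard
deviations (circular for aspect) for the unevenness layers; edge cells and
cells touching missing values are missing.

Each framework is fitted ten times as a 500-tree regression forest
(mtry = floor(sqrt(p))) on a fresh 90/10 split; regression on the 0/1
response makes predictions probabilities. Held-out metrics are ROC AUC
(trapezoidal; the rank-statistic identity is enforced in the tests),
and sensitivity/specificity/TSS at the run's max-TSS threshold
(TSS = sensitivity + specificity - 1; the threshold scan runs over observed
scores with ties broken upward). The map averages the ten forests per cell,
leaves any cell with a predictor outside its training range unclassified —
forests do not extrapolate — and binarizes at the mean of the per-run
thresholds. With presences outnumbering absences ~30:1, forest
probabilities crowd toward 1 and the max-TSS threshold lands around 0.9;
that high threshold is a property of prevalence, not of model quality,
which is why TSS (prevalence-robust) drives the binarization.

# Uplift intensity

Positive fix-level vertical speeds from the 1 Hz bursts are pooled across
individuals and averaged per 100 m cell; cells above the 99.97th percentile
are removed. The Gaussian GAM models the square-root of the cell mean:
aspect as a cyclic cubic spline (8 knots, period 0-360), NDVI, elevation,
roughness and latitude as thin-plate splines (10 knots), land use
parametric against the bare-soil reference, and the dynamic potentials
parametric where the framework includes them; smoothing parameters by REML
(GCV available). Frameworks are ranked by AIC on the identical response.
The intensity map squares the fitted square-root scale mean (no
retransformation bias correction; the option is noted in the configuration)
and predicts only on suitable, in-range cells within the training latitude
band.

# The energy landscape

Flying ACC bursts (height above ground over 100 m, which also guarantees a
time-matched fix) are averaged per individual and UTC calendar day — mean
burst ODBA on one side, mean predicted uplift probability at the burst
locations on the other; days with fewer than five qualifying bursts are
dropped, and bursts on unclassified map cells are excluded from the
suitability mean. The linear mixed model sqrt(daily ODBA) ~ daily
suitability + (1 | individual) is fitted by maximum likelihood (not REML)
so its AIC is comparable with the slope-free null; random slopes are
available behind a configuration flag but off by default, since individual
differences enter the paper's argument only as intercept shifts. A negative
fixed slope with a large AIC advantage over the null is the chain's
headline: the static map carries real energetic information.

# Problem sizes and test design

The standard validation fixture is a 150 x 150 landscape (seed 42) with 20
birds tracked for 4 days of 8 flight hours — about 770k burst fixes, 51k
segments, 4.3k soaring events, 3.8k ACC bursts and ~150 absences. These
sizes were chosen so the full chain, repeated forest fits included, runs
comfortably on a single core while keeping enough absences for stable
threshold estimates. Oracle tests (ODBA, TSS threshold, AUC, terrain
operators) compare against independently coded brute-force implementations
at 1e-9; recovery tests assert segment-level accuracy (>= 0.95 noise-free,
>= 0.90 at default noise), held-out AUC >= 0.85 with planted drivers in the
top importances, suitable-area agreement with the planted field within
0.1, cyclic-smooth recovery with correlation >= 0.9 and exact periodicity,
AIC selection of the generating framework in >= 9/10 replicates, and a
negative energy slope in >= 9/10 replicate track simulations over the
fitted map. The binomial honesty of the planted field is checked by a
pooled chi-square over planted-probability deciles, since no single 100 m
cell accumulates enough attempts under the real duty cycle.

# Known limitations

* The simulator's behavioural rhythm is a renewal process on a 15 s tick;
  real flight mixes bout lengths continuously, so segment-pure windows
  overstate what segmentation can achieve on real data by a few points.
* Absences are scarce by construction (flapping is rare and heights are
  only assigned near fixes); max-TSS thresholds estimated on ~15 held-out
  absences are noisy, and the ensemble threshold inherits that noise.
* The GAM's adjusted R-squared is low on simulator output, as the response
  carries Bernoulli and climb-rate noise far exceeding the planted smooth
  structure; AIC ordering, not variance explained, is the meaningful
  comparison.
* ESRI ASCII grids carry no CRS; the georeference is the package's local
  metric convention (row 1 = north, cell centres, equirectangular
  longitude/latitude anchor).
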