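---
title: "Methods: quantitative analysis of droplet-based functional screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of droplet-based functional screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
library(dplyr)
```

`dropscreen` implements the quantitative backbone of an ultrahigh-throughput
microbial screen run in water-in-oil droplets (WODLs): single cells are
encapsulated with a quenched fluorogenic protease substrate, cultivated, and
droplets are sorted by the fluorescence their secreted endopeptidases
develop. Five analysis stages are covered — occupancy imaging, OD600
calibration and growth-curve fitting, Poisson encapsulation statistics,
sorting-gate arithmetic, and OTU enrichment/activity scoring — together with
synthetic-data generators that provide ground truth for every stage.

## Occupancy imaging

Culture turbidity cannot be read out directly inside a ~120 µm droplet, so
growth is quantified as *occupancy*: the fraction of the droplet's projected
area covered by cells,

$$A_{occup}(\%) = \frac{A_{droplet} - A_{ex}}{A_{droplet}} \times 100,$$

where $A_{ex}$ is the cell-free area inside the droplet boundary.
`measure_image()` composes three steps:

* **Droplet detection.** The oil background is estimated from the frame
  border; pixels deviating from it by more than 5 border-noise MADs (and 2%
  of the image's dynamic range) form the foreground, whose largest connected
  component — after a small morphological opening, hole filling, an
  edge-contact check and a circularity check — is fitted as a circle through
  its centroid and equivalent radius. A single dominant droplet per frame is
  assumed, so this component fit meets the same accuracy a circular Hough
  transform would provide at a fraction of the cost; a user-supplied
  geometry can replace it to mimic manual delineation. Both threshold terms
  scale under affine intensity changes, which makes the whole measurement
  invariant to contrast/brightness rescaling.
* **Interior segmentation.** An Otsu threshold is computed on a 256-bin
  histogram of the droplet-interior pixels only (the standard parameter-free
  binarisation choice), cells are taken as the darker class by default, and
  a 1 px opening suppresses salt noise before areas are counted. A
  near-uniform interior is classified as empty or confluent by its darkness
  relative to the surrounding oil. Only pixels classified as cells are
  excluded from $A_{ex}$; the droplet rim is not treated specially.
* **The occupancy formula**, applied exactly. Coordinates are 0-based with
  a pixel-centre convention; areas are pixel counts, convertible to µm² via
  `um_per_px^2`.

## The synthetic image generator

`generate_droplet_image()` renders a circular droplet (default 120 µm) as a
medium disk (intensity 0.80) on an oil background (0.95) with dark cell
blobs (0.25) and additive Gaussian noise (default sd 0.01). The microscope
modality's contrast transfer is not published for this assay, so these
levels are free parameters of the generator chosen to resemble bright-field
insets: cells darker than medium, medium slightly darker than oil.

Blob seed positions are placed without overlap by rejection sampling (with
an attempt cap, relaxing spacing when packing is tight); a shared blob
radius is then tuned by bisection on the rendered union area until the
pixel-counted occupancy is within 0.25 percentage points of the target.
Letting dilated blobs merge is what makes high targets (above random
close-packing density, up to 100%) reachable, and resembles a culture
growing confluent. The rendered mask is the ground truth, so estimator
accuracy can be asserted against exact pixel counts.

The generator does **not** emulate realistic optics (point-spread function,
shading), droplet polydispersity or coalescence, or the cell-aggregation
behaviour some organisms show at late time points (occupancy here is
monotone in rendered area). Tests passing on these images therefore
establish correctness of the measurement arithmetic and its invariances,
not robustness to every real-world artefact.

## OD600 calibration

Sealing droplets with media of known OD600 gives (occupancy, OD600) pairs;
`fit_calibration()` fits ordinary least squares of **OD600 on occupancy**.
The direction was an open choice — the screen's use case is converting a
measured occupancy into an OD estimate, so OD600 is the response. One curve
should be fitted per species, since cell size and contrast differ.

The package's standard calibration scenario
(`run_calibration_experiment()`) images six OD600 levels, 0.1–1.6, at 50
occupancy points per OD unit (occupancies 5–80%) in a 160 px frame at
1 µm/px with the default noise, and summarises ten independently seeded
series by their median R². These sizes keep one experiment around a second
while spanning the linear range; the measured R² routinely exceeds 0.999,
comfortably above the 0.99 quality bar expected of such calibrations.

## Growth-curve fitting

Lag time and maximum growth rate are extracted with the Baranyi–Roberts
model, fitted in-package (the original workflow delegated this to the
ComBase service, whose internals are not described). On $y = \ln OD$:

$$y(t) = y_0 + \mu_{max} A(t) - \ln\!\left(1 +
  \frac{e^{\mu_{max}A(t)} - 1}{e^{y_{max}-y_0}}\right),
\qquad
A(t) = t + \frac{1}{\mu_{max}}\ln\!\left(e^{-\mu_{max}t} + e^{-h_0}
  - e^{-\mu_{max}t-h_0}\right),$$

with lag reported through the standard identity $\lambda = h_0/\mu_{max}$.
The late-time log term is evaluated in log-sum-exp form so long horizons do
not overflow. `fit_growth()` runs Levenberg–Marquardt least squares
(`minpack.lm`) from a 3×3 grid of starting values derived from a log-linear
segment scan, keeps the lowest-RSS solution, and flags a constant series as
"no growth" ($\mu_{max}=0$, lag reported as 0). Noise-free recovery is
exact to well under 1% across a grid of ($\mu_{max}$, lag) including the
8.9 h and 14.3 h lag regimes typical of the screen's model organisms; with
5% relative OD noise the median recovery error over 20 seeds stays under
10%. The test suite verifies the closed form against a numerically
integrated Baranyi ODE to 1e-6.

`generate_growth_series()` offers additive or relative Gaussian OD noise;
relative noise is the realistic reading-error model for plate readers and
is what the recovery benchmarks use.

## Encapsulation statistics

Cell loading is Poisson: `occupied_fraction()` ($1-e^{-\lambda}$),
`estimate_lambda()` (its inverse), `lambda_from_density()`
($\lambda = \text{density}\times\frac{\pi}{6}d^3$; a 120 µm droplet holds
0.905 nL), `mixture_fractions()` (independent products for two premixed
strains — no interaction term, matching how mixed cultures are prepared)
and `expected_cells_analyzed()`. Headline values are reported at 2
significant figures — the convention behind "approximately 630,000
microorganisms analysed" from 1,002,443 droplets at $\lambda = 1$ — with
the exact expectation always retained.

## Sorting-gate arithmetic

`top_fraction_gate()` implements "top q" as the empirical $1-q$ quantile
(linear interpolation between order statistics) with **strict** exceedance:
ties at the threshold are excluded, so the gate never sorts more than
requested. An instrument's realised fraction can differ slightly (the
reference run sorted 10,356 of 1,002,443 ≈ 1.03% at a nominal 1%); that
slack is gate calibration on the hardware and is not reproduced. Whether
the instrument used ≥ or > at the boundary is unstated; strict exceedance
is the conservative choice. Gate membership is invariant under strictly
monotone intensity transforms, which the suite checks.

`intensity_histogram()` defaults to logarithmically spaced bins, mirroring
the sorter display on which empty droplets form a peak at intensities
10–20. The synthetic population models that baseline as lognormal with
median 14 and log-sd 0.35 — a right-skewed shape whose mode falls inside
the 10–20 band; only the peak location constrains the distribution's shape,
so lognormal is a modelling choice. Strain fluorescence accumulates
proportionally to the time-integral of the Baranyi OD trajectory
(`fluor_rate` × OD·h), with small lognormal droplet-to-droplet jitter: a
strong producer separates from empties by orders of magnitude, a weak one
only modestly, which is what makes low-gate isolation of the weak strain
testable.

## Enrichment scoring

The enrichment ratio of an OTU is its **relative abundance** post-sorting
divided by its relative abundance post-cultivation. Fractions, not raw
reads, are compared: library depths differ between the two samples, and
raw-count ratios would be depth-confounded. OTUs absent from the pre-sort
library get an *undefined* ratio and are reported as their own class rather
than pseudocounted (an optional pseudo-fraction, e.g. `0.5/depth`, is
available). Ratios exactly 1 are kept as a separate "unchanged" class.

One subtlety matters when constructing scenarios: because post fractions
renormalise, the expected ratio of OTU $i$ is
$f_i / \sum_j p_j f_j$ for configured factors $f$ and pre-abundances $p$.
Factors equal the realised ratios only when their abundance-weighted mean
is 1; the bundled 80-OTU scenario (45 enriched, 35 depleted) is built that
way, and deep multinomial sampling (depth $10^6$) recovers the 45/35 split
exactly.

## Activity normalisation

Kinetic slopes are OLS over the full read (a 20-min window by default, with
an optional trim to the initial linear region at R² ≥ 0.999). Two standard
curves are supported: Nma fluorescence (standards 16 pmol–1 nmol Nma
equivalents) and Bradford protein (0–0.25 mg/mL bovine gamma globulin);
both keep their fitted intercept — no convention forces the Nma curve
through the origin, so the fitted intercept is retained. Specific activity
is fluorescence increase per minute per mg of supernatant protein, with the
protein mass taken as mass in the assayed aliquot (Bradford mg/mL × aliquot
volume). Volumetric activity converts the slope to µmol product/min through
the Nma curve slope and refers it to the supernatant volume in the reaction
(50 µL in the standard 50 + 50 µL mix). Relative activities set a reference
strain — or, for the 19-substrate P1-specificity profile (all proteinogenic
residues except cysteine), the most-cleaved substrate — to exactly 100%.

## Numerical and degenerate-input conventions

* Identical seeds give bit-identical generator output; a single seed fans
  out to per-stage substreams so stages can be regenerated independently.
* Occupancy inputs are validated ($A_{droplet}>0$,
  $0 \le A_{ex} \le A_{droplet}$); blank frames, edge-touching droplets and
  non-circular dominant objects raise errors with diagnostics.
* All-tied intensity tables produce a degenerate, flagged gate selecting
  nothing.
* Multinomial OTU sampling conserves requested depths exactly.
* Growth fitting tolerances: `ftol = 1e-10`, 200 iterations, 9 starts.

## Known limitations

Image analysis assumes one dominant, fully visible droplet per frame; there
is no multi-droplet tracking, 3-D volume estimation, or fluorescence
quantification from images. Poisson loading ignores cell clumping and inlet
settling. Enrichment scoring has no replication-aware differential
statistics — it is a descriptive ratio, as in the screen it supports.
Sequence-level steps (OTU picking, taxonomy, trees) are out of scope; OTU
tables enter as counts.
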