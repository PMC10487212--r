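---
title: "Methods: from hyperspectral cubes to composition maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hyperspectral cubes to composition maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemmap)
```

This vignette explains the models and procedures `chemmap` implements,
the assumptions behind them, the tunable parameters, and the design
decisions made where the methodology left genuine freedom. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. The measurement model

A push-broom hyperspectral rig images a fresh-cut fruit slice twice: a
visible/short-wave unit (380–1000 nm) and an NIR unit (860–1690 nm).
Raw counts `I` are converted to relative reflectance with white (`W`,
Teflon) and dark (`B`, capped lens) reference frames,

$$R = \frac{I - B}{W - B},$$

band by band. The calibration is scale-invariant (any common gain of
`I`, `W`, `B` cancels), negatives are clipped to zero, and values above
one — possible with an imperfect white standard — are kept and counted.
Band edges below 420 nm and above 1600 nm are discarded because sensor
photon sensitivity collapses there; both sensors are then fused onto one
5 nm grid of 237 bands, the visible unit supplying everything below
1000 nm and the NIR unit everything at and above it. No multiplicative
scale matching is applied at the seam: the two units are independently
reflectance-calibrated, so their overlap should already agree, and a
hard switch keeps each band traceable to one physical sensor (the fused
table records which). Savitzky–Golay smoothing (window 11 points =
55 nm, order 2, configurable) removes channel noise; the window was
chosen to stay well below the 30–50 nm width of the absorption features
the calibration relies on, and mirror padding keeps the spectrum length
unchanged. Wavelengths in the 860–1000 nm overlap are taken from the
visible unit; this is a recorded package choice, not a claim about the
original instrumentation.

## 2. Registration and ROI extraction

The wet-chemistry reference values belong to ten 18 mm discs whose
positions are only visible in a photograph taken *after* sample
extraction, so that photograph must be registered onto the hypercube.
Three screw fiducials provide six control points (two slit ends each);
three transform families are fitted by least squares — non-reflective
similarity (4 dof), affine (6 dof), projective (8 dof, normalized DLT
followed by Gauss–Newton refinement of the geometric error, started from
both the DLT solution and the affine fit so the nested-family residual
ordering is preserved). Errors are reported as RMSE over per-point
Euclidean distances (pixels) and MAPE pooled over both coordinates of
all points; both pooling conventions are the package's own and are
declared here because scalar error formulas leave them open for 2-D
points.

The family is chosen by the lowest *check-point* RMSE (ties: check
MAPE, then fewer required control points). The three check points are
placed at three borehole centers spread across the slice (regions 1, 6,
10) rather than at the slit middles of the screws. This is a deliberate
design choice: check points co-located with the control clusters cannot
discriminate an affine fit from a projective fit (the two agree at
interpolation points to hundredths of a pixel), whereas held-out points
away from the controls expose the projective family's noise-amplified
perspective terms. With this geometry, simulated scenes whose true
distortion is affine select the affine family in well over 90% of
trials, and the projective family shows the worst check-point errors
despite the best control-point fit, as expected for the family with the
most freedom to chase landmark noise.

ROI discs are found by a gradient-vote circular Hough transform (radius
resolution 1 px, votes cast both along and against the local gradient,
3×3 box aggregation of the accumulator to absorb direction quantisation,
non-maximum suppression at the minimum search radius, ties by higher
score then smaller radius). Detected circles are renumbered into the
standard two-columns-of-five layout and their centers mapped through the
fitted transform to label the hypercube-frame mask.

## 3. Wavelength selection under availability constraints

Only wavelengths at which optical hardware can be bought are candidates:
a 5 nm availability grid over 420–1600 nm carries flags for bandpass
filters and for light sources (LED or laser; the light-source modality
is their union).

**Ranking and uncorrelatedness.** Candidates are ranked by RReliefF,
the regression form of the Relief family: for each instance, its 10
nearest neighbours (Manhattan distance on range-normalised features)
contribute rank-weighted (exp(−(rank/20)²), normalised) estimates of
the probabilities of a changed prediction given a changed feature, and
the weight of each feature is the difference of the two conditional
attributions. Iterating over all instances makes the ranking
deterministic and sample-order invariant. The top 20 wavelengths then
pass the uncorrelatedness loop: keep the best-ranked, drop later ones
correlated with it at |r| > 0.8, advance to the next survivor, repeat;
at most six survivors are returned. Pruning uses the absolute Pearson
correlation: two perfectly anti-correlated bands are just as redundant
as two correlated ones, so the 0.8 threshold is applied to |r|.

**Subset selection.** The CFS merit
$$\mathrm{merit}(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}}$$
scores a subset by mean absolute feature–target correlation against mean
absolute inter-feature correlation. Best-first search explores the
subset lattice from the empty set, expanding the best open node by
single additions/removals and stopping after five consecutive
non-improving expansions (the common default of the framework this
procedure originates from). If the winning subset exceeds six members,
all six-member sub-subsets are enumerated and the best merit wins, ties
going to the lexicographically smallest wavelength list. The "highest
correlation with composition change" used to compare six-member
sub-subsets is operationalised as the same CFS merit — the selection
hypothesis (relevant yet mutually uncorrelated) is exactly what that
score expresses.

## 4. Calibration models

Each trait gets a multilayer perceptron with one hidden layer of four
tangent-sigmoid units and a linear output, trained by full-batch
Levenberg–Marquardt (analytic Jacobian; damping ×10 on rejection, ×0.1
on acceptance) on inputs and targets z-scored on the calibration split
only. The data partition holds out two whole fruit per origin (20% of
rows) for validation; the rest is shuffled into 65% calibration and 15%
cross-validation *of the total row count* — at the standard 600-row
scale, 390/90/120, which is self-consistent (390 + 90 = 480 = 600 − 120).
Designs whose row count cannot reproduce these proportions exactly are
rejected rather than silently re-proportioned.

Training stops at the first of: calibration MSE ≤ 1e-4 (standardized),
500 epochs, 15 consecutive epochs without a new cross-validation
minimum, or damping overflow; the best-cross-validation weights are
restored. The early-stopping monitor is the cross-validation split — the
held-out fruit must stay untouched, so cross-validation is the only
leak-free choice for the failure counter. The nominal learning rate of 0.3 is
stored for configuration fidelity although LM steps are driven by the
damping parameter, mirroring the convention of the toolbox the
hyperparameters come from. Twenty replicate initialisations are trained
per candidate wavelength set; sets are compared on mean ± SD of stage
metrics (R, RMSE, MAPE), the winner having the highest mean
cross-validation R (ties: lower RMSE, then MAPE).

Because best-epoch restoration optimises against the cross-validation
split, cross-validation R is slightly optimistic; the package's
no-information test therefore scores an untouched holdout.

## 5. Maps and spatial reliability

Calibrated cubes are flattened to a pixels × bands matrix (row-major
pixel order, invertible), the slice foreground is separated from
background by thresholding (fixed threshold, or Otsu's method with an
optional second Otsu split that removes the specularly bright fiducial
class; the Otsu threshold takes the midpoint of the between-class
variance plateau so it sits centrally in an empty histogram gap), and
the model predicts every foreground pixel. Background carries an NA
sentinel plus an explicit mask — multiplying by a 0/1 mask, the obvious
alternative, cannot distinguish a genuine zero prediction from
background. Region-wise reliability is the absolute percentage
difference between each disc's mean predicted value and its reference
value, summarised over validation fruit and compared across the ten
regions by one-way ANOVA with Tukey's HSD (Tukey–Kramer when
unbalanced) and an insertion-based compact letter display. Histogram
shape is reported as mean, skewness and kurtosis over foreground pixels;
kurtosis uses the non-excess convention (normal = 3), recorded in the
output. No accept/reject quality rule is built on these statistics —
the underlying criterion is qualitative, so the package exposes the raw
numbers only.

## 6. The synthetic data generator

No public fruit dataset accompanies this kind of campaign, so the
generator emulates the sampling design and every test runs against it:

* **Reference table.** Six origins × 10 fruit × 10 regions (600 rows)
  with origin-level means/SDs of MC, SSC, TA, CC from the package's
  default design (`origin_chemistry_defaults()`). A Gaussian copula
  imposes the inter-trait correlation; because the target correlations
  are defined on the pooled table, the generator analytically calibrates the
  within-origin latent correlation so that the *pooled* correlations
  converge to the configured targets (CC with MC/SSC/TA: −0.56, 0.52,
  −0.14). The three remaining pairs default to MC–SSC −0.45, MC–TA
  0.10, SSC–TA −0.05 — weak-to-moderate couplings consistent with
  dilution physiology — and the implied matrix is checked positive
  semi-definite. Marginals are truncated normals (MC in (0,100), the
  rest non-negative). The within-origin variance is split 50/50 between
  a between-fruit and a within-fruit (between-ROI) level; no empirical
  estimate of this partition is available, so both shares are exposed
  as configuration.
* **Chemistry fields.** Per fruit, each trait's 2-D field is a linear
  combination of wide Gaussian bumps at the ten ROI centers plus an
  optional axial trend, with bump coefficients solved from the 10×10
  disc-average constraint system — so disc means reproduce the table
  exactly and the maturity gradient along the stem axis appears whenever
  the ROI values carry it. Default raster 256×256 at 0.5 mm/px (18 mm
  discs = 36 px); tests use 160×160 at 1 mm/px to keep runtimes small,
  and the geometry is stated in physical units so the scale is a free
  parameter.
* **Optics.** Reflectance is a smooth baseline plus per-trait Gaussian
  bands scaled by the trait's standardized deviation: carotenoids
  negative near 505 nm, moisture positive near 490 nm and negative at
  the 960/1425 nm water overtones, sugars negative near 489 and
  1215 nm, acidity near 512/1240 nm. Band centers and signs reproduce
  the qualitative correlation structure of ripening flesh; amplitudes
  and widths are not optical constants and make no radiometric claim.
  Raw frames receive additive Gaussian noise (default 1% of the white
  level, ×5 outside 420–1600 nm so the trimming step has something to
  remove). With zero noise the whole preprocessing chain inverts the
  forward model exactly, which the tests exploit as a closed loop.
* **Controlled scenes for parameter recovery** narrow each trait's
  coupling to the specific bands under test (e.g. moisture only at
  495/500 nm, σ = 5 nm). The narrow width is part of the construction:
  with wide bands and correlated traits, a band *tail* can carry a purer
  univariate signal than the center, and "recovering the stated band"
  stops being well defined.

What passing these tests does **not** show: real fruit spectra have
scattering baselines, pathlength effects and instrument drift that the
linear Gaussian-band model omits, and real inter-trait correlations are
not exactly Gaussian-copula. The generator validates the *pipeline
mechanics and statistics*, not field performance.

## 7. Numerical choices and degenerate inputs

* Positive-semi-definiteness of the correlation matrix is enforced with
  an 1e-8 eigenvalue tolerance; near-constant columns (SD < 1e-6) warn
  and clamp rather than abort, since the correlation target is then
  unreachable by construction.
* The Savitzky–Golay window must be odd, larger than the polynomial
  order and no longer than the spectrum.
* Transform fitting rejects coincident/collinear configurations by rank
  tests (SVD gap 1e-8); `white ≤ black` at any band aborts calibration
  naming the bands.
* Best-first search treats merit improvements below 1e-10 as ties;
  six-member enumeration breaks exact ties lexicographically.
* Zero-variance features are excluded from CFS correlations with a
  warning; a constant regression target is an error everywhere.
* MAPE is undefined at zero targets and errors out rather than
  returning infinity; the registration variant advises offsetting the
  point frame.
* All generators and trainers are pure functions of (configuration,
  seed); pipeline stages derive their seeds from one root seed and a
  stage-name hash, so any stage can be replayed alone.

## 8. Problem sizes used by the tests and the acceptance script

The suite runs the full 600-row design everywhere the partition
structure matters, 6 000-row tables for correlation convergence, 200
jittered scenes for transform selection, 50 controlled-optics datasets
for wavelength recovery, 100 random candidate sets (≤ 12 wavelengths)
for the exhaustive-search cross-check, and 500 simulations for the
Tukey type-I rate — sizes at which the binomial/Monte-Carlo margins of
the asserted thresholds are comfortable. Cube-based closed-loop tests
use reduced rasters (64–160 px) because the identities they check are
pixel-wise and do not depend on raster size.
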