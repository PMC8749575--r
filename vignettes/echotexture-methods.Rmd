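---
title: "Echotexture analysis of muscle ultrasonograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echotexture analysis of muscle ultrasonograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotex)
```

## Scope

`echotex` quantifies the first-order echotexture of B-mode muscle
ultrasonograms — mean pixel intensity (MPI) and pixel heterogeneity (MPH)
over circular spot meters — and runs the statistical pipeline that relates
those variables to meat-quality traits: group ANOVAs with post-hoc letters
and a Pearson correlation screen with regression equations. Because raw
scanner data for this kind of study are rarely shareable, the package also
ships a speckle-image and trait-table simulator whose defaults reproduce
the group means and standard errors of a published reference study of
organic turkeys (three diet groups, 15 birds each, four scanning planes).
Everything upstream of the image (husbandry, laboratory assays, sensory
panels, histology) is out of scope and enters only as columns of the input
trait table.

## The measurement model

### Greyscale conversion and byte-scale normalization

RGB ultrasonograms are reduced to 8-bit grey with the ITU-R BT.601 luma
weights (0.299, 0.587, 0.114) — the long-standing default of mainstream
imaging libraries — and rounded **half-up**, so conversions are bit-exact
and platform-independent (base R's `round()` rounds half-even, which would
make results grid-dependent). Images are then normalized by grey-level
stretching:

$$G_i = T\,\frac{f_i - f_\min}{f_\max - f_\min},\qquad T = 255,$$

with $f_\min, f_\max$ the per-image extremes computed over the **whole
image**, not the region of interest: the stretch is a display
normalization applied before any ROI is placed. Consequences worth
knowing:

* a non-constant image attains exactly 0 and 255 after normalization, and
  the map is idempotent (a normalized image is its own fixed point);
* the stretch is invariant to affine rescaling of the input,
  $a f + b \mapsto$ the same output ($a>0$), up to one grey level of
  rounding;
* a constant image has an undefined stretch; it is defined to map to all
  zeros with a warning rather than an error, so batch runs survive
  degenerate frames;
* 16-bit input is rescaled onto the byte scale with the same formula at
  read time.

### Spot meters and MPI/MPH

Four identical circular spot meters (default diameter 33 px, the
conventional size for muscle echotexture work, stored exactly rather than
as "approximately 33") are placed in the muscle parenchyma. Placement is a
choice of the analyst; the package accepts manual placements from a CSV
and offers `defaultSpotLayout()`, a reproducible 2 x 2 grid at the image
center. Validity rules are strict: identical diameters, every circle fully
inside the image, and pairwise center distances strictly greater than the
diameter (tangent circles are rejected).

A pixel belongs to a spot when its center lies strictly within
`diameter/2` of the spot center in Euclidean distance — a deterministic,
grid-independent membership rule. Pixels are returned in row-major order.
Note a small consequence: at diameter 3 around an integer center the disk
contains 9 pixels, because the diagonal neighbours at distance
$\sqrt 2 \approx 1.414$ fall strictly inside radius 1.5.

Per spot, the mean and the sample (n−1) standard deviation of the pixel
values are computed; then

* **MPI** = arithmetic mean of the four spot means;
* **MPH** = arithmetic mean of the four within-spot SDs (default).

The phrase "standard deviation of the mean pixel values" is genuinely
ambiguous in the field's reports; the default treats MPH as within-ROI
grey-level dispersion, matching first-order texture methodology. The
alternative reading — the SD **across** the four spot means — is
implemented behind `mphMode = "across-spots"`. Sample rather than
population SD follows the convention of the statistical software the field
uses.

### Normalization versus MPI calibration

The speckle simulator is calibrated on **raw envelope intensities**: for a
Rayleigh scale $\sigma$ the expected amplitude is $\sigma\sqrt{\pi/2}$, so
`calibrateSigma(target)` returns $\mathrm{target}/\sqrt{\pi/2}$. Byte-scale
normalization subsequently multiplies all intensities by
$255/f_\max$ (about 1.2–1.3 for a typical simulated frame), so the
*normalized* MPI of a calibrated image sits above its raw target. This is
inherent to display normalization, not a calibration error; recovery
checks therefore run `analyzeBatch(..., normalize = FALSE)`, while the
study pipeline keeps `normalize = TRUE` as its procedure. MPH targets are
not calibrated from images at all: under Rayleigh speckle the pixel SD is
tied to the mean ($\mathrm{SD} = \mathrm{mean}\cdot\sqrt{4/\pi - 1}$), so
printed MPH levels cannot be matched independently by this image model.
The statistically calibrated echotexture table produced by
`simulateTraitTable()` is the route that matches both MPI and MPH group
means.

## The synthetic-data model

### Speckle images

Fully developed speckle is the envelope $\sqrt{Z_1^2 + Z_2^2}$ of two
independent zero-mean Gaussian fields of scale $\sigma$ (grey levels), i.e.
Rayleigh amplitudes with mean $\sigma\sqrt{\pi/2}$ and SD
$\sigma\sqrt{2-\pi/2}$ — closed forms that give the test suite analytic
oracles. Log-compression is deliberately omitted from the default model
for the same reason. Optional anisotropic smoothing (Gaussian kernel with
SDs of 1 px across rows and `anisotropy` px across columns, applied to the
Gaussian fields and renormalized so the marginal distribution is exactly
preserved) emulates the elongated, more "linear" speckle grain seen when
the probe is parallel to the muscle fibers. The shipped per-plane aspect
ratios (L = 3, T = 1, O1 = 1.5, O2 = 2.5) encode that the fibers run
largely perpendicular to the probe in L/O2 and parallel in T/O1; they are
a modelling choice, fixed once, not fitted quantities. Values are rounded
half-up and clamped to [0, 255], with a warning when more than 1% of
pixels clamp. No beamforming, time-gain compensation or tissue layering is
modelled: these images are statistical stand-ins, and passing tests on
them demonstrates correctness of the measurement chain, not realism of
any scanner.

### Trait tables

Per bird, a latent multivariate-normal vector covers the 8 echotexture
variables and all traits: unit variances, identity correlations except for
explicitly planted echotexture-trait pairs (the reference study publishes
no within-group covariances, so traits are otherwise independent — a
deliberate, documented simplification). Requests that make the matrix
non-positive-semi-definite are rejected naming the offending triples. Each
variable is then mapped to its group scale as
$\mu_{g} + \mathrm{SEM}_{g}\sqrt{15}\, z$: only mean ± SEM are printed in
the reference tables, so the within-group SD is reconstructed under the
study's n = 15 (and stays fixed when a different number of birds is
simulated). Marginals are Gaussian; heavier tails are out of scope.

Sensory traits are snapped to the 1–5 scoring grid in 0.5 steps **after**
correlation planting; the attenuation this causes is part of the simulated
measurement process and is measured rather than corrected. One visible
consequence of taking the printed SEMs at face value: a sensory SEM of
0.003 (cohesiveness, group Exp1) implies a within-group SD of about 0.01,
which collapses to a constant column after grid snapping; the screen
skips zero-variance columns with a notice, exactly as it would on real
degenerate data.

Reproducibility contract: one master seed; `simulateTraitTable()` draws
groups in the fixed order C, Exp1, Exp2; `simulateStudy()` uses the master
seed for the tables and `seed + 1000 + i` for the i-th image in manifest
order. Fixed seeds give bit-identical outputs.

## The statistical pipeline

### Correlation screen

For each stratum (each group, or all birds pooled — pooling simply ignores
the group structure), every (echotexture variable, trait) pair yields a
Pearson r, a two-tailed p from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$
degrees of freedom (the standard product-moment test; `p = 1` exactly when
`r = 0`), and the least-squares line, which provably passes through the
sample means — a property the tests verify on every emitted row.
Zero-variance columns within a stratum are skipped with a notice, not an
error. Equation strings are formatted with two decimals and an ASCII
hyphen so text output is reproducible.

No multiple-testing correction is applied anywhere: the screening
convention reports raw p < 0.05 over the full candidate set, and the
candidate bookkeeping (planes x variables x traits x groups) is reported
alongside. An optional Benjamini–Hochberg column (`bhAnnotation = TRUE`)
is clearly an annotation, never the selection rule.

Two bookkeeping conventions deserve notice. First, the reference study
counts 26 physicochemical/sensory characteristics, but its trait tables
print 29 rows; the enumeration that yields 26 is not given. The shipped
trait model therefore has all 29 columns while the nominal candidate count
defaults to 26 (`nTraitsNominal`), reproducing the published totals of 624
and 208; the count is a configuration value, and `performed` reports the
pairs actually tested. Second, the reference within-group table contains
one row printed with p = 0.07 inside a table of significant correlations;
a strict p < 0.05 screen does not reproduce such a row, and the package
makes no attempt to.

Correlation strength uses the Guilford verbal bands on |r| (< 0.2 slight,
0.2–0.4 low, 0.4–0.7 moderate, 0.7–0.9 high, ≥ 0.9 very high), closed on
the left. Reports in this literature sometimes call pooled correlations of
about 0.3 "moderate", which those bands label "low"; the band edges are
configurable rather than guessing intent.

### ANOVA and letters

One-way ANOVA uses `stats::aov` with Tukey HSD pairwise comparisons; the
compact letter display is assigned by the standard insert-and-absorb
algorithm with levels ordered by decreasing mean, so "a" attaches to the
largest mean as in group-mean tables, and levels sharing a letter are
pairwise non-significant at `alpha`. Degenerate inputs are defined, not
crashed on: all observations identical gives F = 0, p = 1, one shared
letter; zero residual variance with distinct means gives F = ∞, p = 0.

Two-way ANOVA (group x plane) is fitted **without interaction** by
default, matching designs where only main effects are reported, on
balanced-design sums of squares. LSD post-hoc tests are the textbook
definition: unadjusted pairwise t tests using the ANOVA residual mean
square and residual degrees of freedom. A factor left with one level is
dropped with a message (the model degenerates to one-way); empty cells are
an error naming the cell.

### Calibration facts worth recording

Because the echotexture variables are Gaussian in the simulator, the null
distribution of each screen p-value is exactly uniform for any fixed
non-constant trait column, so the type-I error of the α = 0.05 screen is
0.05 by construction; the acceptance script measures it empirically over
1000 replicate null studies. Planted correlations are recovered with the
usual small-sample attenuation of the sample correlation
($\mathbb{E}[\hat r] \approx r - r(1-r^2)/2n$, under 0.013 at n = 15).

One result of simulating faithfully from the printed summary statistics:
with moisture group means 73.1/72.1/74.2 and SDs reconstructed as
SEM·√15 (0.39/0.77/1.16), the probability that Tukey HSD separates all
three groups into distinct letters at n = 15 is only about 0.75 (the
acceptance script computes this rate). The weakest pair differs by 1.0
with an honest significant difference of about 0.74, giving per-pair
power near 0.87. In other words, the fully distinct a/b/c pattern printed
in the reference table is a feature of that particular realized sample,
not a near-certain outcome at those effect sizes — a useful caution when
treating printed superscripts as replicable effects.

## Numerical and interface conventions

* Pixel coordinates are 1-based `(row, col)`, the natural R convention;
  CSV interfaces (`center_row`, `center_col`) use the same convention.
* Rounding is half-up everywhere an intensity is discretized.
* CSV dialect: UTF-8, comma-separated, "." decimal, mandatory header.
* PNG and TIFF I/O use the `png` and `tiff` packages; single-frame
  uncompressed DICOM (8/16-bit grey or RGB, MONOCHROME1 inverted to the
  larger-is-brighter convention) and 24-bit BMP are parsed by compact
  built-in readers. Multi-frame DICOM is rejected with instructions to
  extract a frame.
* The batch analyzer collects per-row failures into a run report and
  continues; the pipeline writes partial outputs and a nonzero status
  rather than aborting.

## Problem sizes used by the tests

The test suite exercises oracle equivalence on 600 random instances
(48 x 48 images with random spot sets; random correlation vectors),
normalization invariants on 100 random images, speckle moments at
256 x 256, screen calibration over 1000 replicate null studies at
n = 15/group, planted-correlation recovery over 1000 replicates (three
independent groups each, targets r ∈ {0.3, 0.5, 0.67}) and at a single
n = 2000 draw, and letter separation over 400 replicate ANOVAs. End-to-end
pipeline tests run a reduced study (4 birds/group, 96 x 128 images) for
speed; the shipped demo configuration keeps the reference scale
(15 birds/group, 480 x 640).

## Limitations

* First-order texture only: no grey-level co-occurrence or run-length
  features, no segmentation of muscle boundaries, no shadow or artifact
  rejection.
* The speckle model is statistical, not physical; it cannot match MPI and
  MPH targets simultaneously, and image-derived echotexture is independent
  of the simulated traits by construction (planted correlations live in
  the table route).
* Trait marginals are Gaussian around printed means with independence
  except for planted pairs; real trait covariance structures are unknown
  from summary tables.
* The pooled screen ignores group structure entirely, as in the reference
  analysis; it is not a meta-analytic pooling.
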