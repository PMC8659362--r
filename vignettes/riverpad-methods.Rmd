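---
title: "riverpad: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riverpad: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverpad)
```

`riverpad` turns photographs of paper analytical devices (PADs) used for
citizen phosphate monitoring into calibrated concentrations, map brackets
and seasonal summaries. This vignette is the package's account of the
models it implements, the parameters that matter, and the places where the
design was genuinely open.

## The device and its geometry

The field device is a laminated strip of wax-patterned filter paper:
eight 10 mm circular zones on a 4 × 2 grid inside a rectangular wax box,
six loaded with the phosphomolybdenum-blue (PMB) reagents and two left
unloaded as negative controls, plus a printed blue internal-standard
square and a four-digit device code. Published images of the device show
the arrangement but not its dimensions (only the 10 mm zone diameter is
stated), so the layout module fixes a concrete, configurable geometry:
14 mm centre-to-centre pitch, a 62 × 34 mm wax box on an 80 × 50 mm
laminate, an 8 × 8 mm reference square right of the box, blanks as the two
rightmost zones of the bottom row. The exact pitch is immaterial to the
analysis — what matters is that generator and quantifier share one layout,
carried as a versioned YAML document.

Coordinates are millimetres in the device frame, origin at the laminate's
top-left corner, y downward; pixel frames use the same convention with
pixel (i, j) centred at (j − 0.5, i − 0.5). Stating this once avoids the
usual half-pixel and sign errors when mapping between frames.

## The readout statistic

Each detection zone is sampled over the central 70% of its radius
(`sampling_fraction = 0.7`, excluding pixels near the printed wax ring
where wax bleeds into the paper) and summarised as an average intensity
`AI = mean(255 − gray)`, with gray the Rec.601 luma — the same quantity an
ImageJ mean-gray measurement of an inverted image gives. A red-channel
option exists but grayscale is the default. The zone readout is the
average relative intensity

$$\mathrm{ARI} = \frac{AI_\mathrm{reaction} - AI_\mathrm{blank}}{AI_\mathrm{ref}}$$

with $AI_\mathrm{blank}$ the arithmetic mean of the two blank zones and
$AI_\mathrm{ref}$ the intensity of the internal-standard square. Devices
report the mean ± sd over the six detection zones.

One deliberate asymmetry: $AI_\mathrm{ref}$ is measured as the *direct*
luminance of the blue square, not inverted against the fixed 255 white
point. The algebraic purpose of the internal standard is that a
multiplicative change of illumination or camera gain, $v \mapsto g\,v$,
cancels from the ratio. The blank-subtracted numerator scales with $g$
whatever convention is used (the constant inversion offset cancels in the
difference), but an inverted reference, $255 - g\cdot\mathrm{gray}$, does
not scale with $g$ and would leave a residual gain dependence of tens of
percent across realistic exposures. Measuring the reference as luminance
makes numerator and denominator both linear in $g$, so ARI is invariant to
machine precision — the property the tests assert at $10^{-6}$. The same
algebra shows what the statistic cannot do: an additive colour cast over
the porous zones cancels exactly in the numerator, but additive offsets
that also shift the reference square, and illumination *gradients* across
the device, are only attenuated, not removed. Both are exercised by the
generator and discussed under limitations.

Zone location fits the known layout to the image rather than detecting
circles freely: dark pixels (grayscale below 130) are labelled into
connected components; ring-like components are kept by size, squareness of
bounding box and non-blueness (the blue reference square is rejected by
its colour, the wax box outline by its size); and a similarity transform
(scale, rotation, translation; Kabsch/SVD with nearest-neighbour
correspondence, refined once) maps layout centres onto the detected ring
centroids. Role assignment (detection vs blank) is therefore inherited
from the layout and never inferred from colour — a blank zone darkened by
pigmented water cannot be mistaken for a detection zone. The mean fitted
vs detected centre distance is reported as a residual; above 3 px the
reading is refused as misaligned. Zones with more than 1% of sampled
pixels on the 0/255 rails are flagged `saturated` but retained.

## The synthetic-data generator

No raw field imagery is published, so the generator is a first-class
module: it renders device photographs with known ground truth carrying the
statistical structure the analysis assumes, and every downstream claim is
tested against that truth.

**Colour development.** The assay's time course — rapid development in the
first minute, plateau from about two minutes — is emulated by a saturating
dose response crossed with first-order kinetics:

$$S(c, t) = b + a_\mathrm{max}\,\frac{c}{c + K}\,(1 - e^{-k t})$$

with defaults $a_\mathrm{max} = 0.55$, $K = 40$ mg/L, $k = 1.5$ min⁻¹ and
reagent background $b = 0.02$. Only the empirical shape of the published
curves constrains this choice; any smooth monotone form that plateaus by
2–3 min and is near-linear below ~10 mg/L would be equally faithful. With
these defaults $1 - e^{-1.5 \cdot 3} = 0.989$, so the 3-minute field
incubation sits safely on the plateau — the package's `plateau_time()`
operation confirms this on the generated time course. Silicate, the
classical PMB interferent, develops the same complex over far longer
timescales; it is modelled with the same form and the rate scaled by
0.008, chosen so that 1000 mg/L silicate at 3 min sits within 0.02 of a
blank, matching the assay's observed blank-equivalence. Reagent ageing is
exposed only as a multiplier on $a_\mathrm{max}$.

**Rendering.** The blue complex attenuates the paper's red and green
channels by $(1-S)$ and blue by $(1-0.15S)$; blank zones receive only the
water tint (a signed per-channel additive cast over every porous zone);
the reference square is painted a saturated printed blue, RGB (45, 70,
200). The frame is multiplied by a gain field (overall gain times a linear
left-to-right gradient), offset, perturbed with i.i.d. Gaussian pixel
noise, rotated in-plane (≤10°; the workflow photographs the device flat,
so no perspective warp) and quantised to 8 bits.

**Noise model.** Two sources: per-pixel Gaussian noise (default sd 6
counts) and a per-zone reagent-deposition variability (`zone_cv = 0.12`, a
multiplicative factor on each zone's signal). The deposition term is what
real replicate zones show — pipetted reagent volumes vary by a few
percent — and it dominates the per-zone ARI scatter, giving a blank
per-zone ARI dispersion of about 0.007 under default conditions, the
dispersion the calibration-facing defaults were designed to. Pixel noise
alone cannot realistically produce that scatter at plausible levels, and
it also dithers the 8-bit quantisation, which on noiseless constant zones
would otherwise round coherently by up to half a count.

**Campaign conditions.** Synthetic campaigns scatter points uniformly in a
Humber-catchment bounding box, draw timestamps over a sampling year, and
take true concentrations lognormal (median 3 mg/L, σ_log 0.6 — matching
the mg/L-range levels that motivate the brackets) modulated by a
sinusoidal seasonal term on the log scale (default amplitude 0.5, peak in
late July). Capture varies per record: gain uniform on 0.80–1.02 (wide,
but bounded above because autoexposure keeps the white laminate off the
255 rail — once pixels clip, no normalization can recover them), gain
gradient ±2%, offset ±2 counts, rotation ±5°. These gradient and offset
ranges reflect diffuse outdoor lighting on a flat 8 × 5 cm device; they
matter because they are exactly the disturbances the ARI statistic does
*not* cancel, and they contribute a concentration error of a few tenths of
a mg/L alongside the deposition scatter.

**What the generator does not emulate.** Perspective distortion, flash
glare, JPEG artefacts, shadows with sharp edges, OCR-able device codes,
chemical matrix effects beyond the single slow interferent, and any
spatial correlation in water chemistry. Passing tests therefore show that
the *analysis* is correct and well-conditioned under the stated noise
structure, not that the physical assay achieves these error rates in the
field; the synthetic pipeline's detection limits come out well below the
field assay's printed 3 mg/L because paper chemistry, handling and
lighting in the wild are harsher than this model.

## Calibration, limits, brackets

Calibration is ordinary least squares of ARI on concentration over the
0–10 mg/L regulatory range (a log-linear option serves wide-range
demonstration sets). The response is mildly concave (Michaelis curvature:
$c/(c+40)$ drops ~4% below linearity at 10 mg/L), which the linear fit
absorbs into its residuals; σ_blank comes from the zero-concentration
replicates when present, else from the residual dispersion. A fitted slope
that is not positive marks the model unaccepted and all inversion is
refused.

Detection limits use the ICH-style convention LOD = 3.3 σ_blank/β₁ and
LOQ = 10 σ_blank/β₁, stated explicitly because printed LOD/LOQ pairs for
colorimetric assays rarely pin down the convention (the assay's published
pair has ratio 2.67, consistent with neither 3.3/10 nor 3/10); the
published values are treated as upper bounds the pipeline must beat, not
as targets to reproduce. Inverse prediction is first-order:
$\hat c = (\mathrm{ARI} - \beta_0)/\beta_1$ with variance
$(\sigma_\mathrm{resid}^2 + s^2/n)/\beta_1^2$; estimates below LOD keep
their numeric value (the map needs it) but are labelled `<LOD`; readings
above the calibrated response range are refused rather than extrapolated.

The public map brackets are integer-valued — none <1, low 1–3, medium
4–6, high ≥7 mg/L — leaving (3, 4) and (6, 7) formally unassigned.
Concentrations are rounded half-up to the nearest integer before
bracketing, which makes the brackets exhaustive, mutually exclusive and
monotone; 3.4 maps to low, 3.6 to medium. Blank-equivalence testing uses
the Welch two-sample two-tailed t-test (configurable to pooled), with the
verdict at α = 0.05; method comparison against a laboratory reference
rounds both estimates to one significant figure, the resolution at which
the semi-quantitative field device is meant to agree.

## Campaign QC and products

Record parsing is conservative and lossless: malformed rows (coordinates
out of bounds, bad device codes, unparseable timestamps) are returned with
reasons, never dropped; offset-less timestamps are assumed UTC and
flagged. QC flags annotate and never block: `incubation_short` below the
180 s protocol, `saturated` from the reading, `missing_image`, and
`blank_anomaly` when the blank zones read darker than the surrounding dry
paper by more than 0.10 in internal-standard units — the signature of
pigmented or turbid water, measured as a contrast so it is gain-stable.
Map features carry the inverted concentration, its bracket (the stored
category always equals `classify_level` of the stored concentration), and
QC flags into an RFC 7946 GeoJSON FeatureCollection with (lon, lat)
coordinate order and a conventional `marker-color`. Seasonal summaries
aggregate by month-of-year or quarter across years, reporting empty
periods with n = 0. The volunteer's own slider reading is carried as
metadata and compared to the computed bracket, never used in calibration.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty masks, reference squares
that cannot be sampled, non-positive AI_ref (washed-out reference),
constant groups in the t-test (t = 0 for identical groups), perfect fits
(suppressed `summary.lm` warning), and negative concentration estimates
(clamped to zero before bracketing). All stochastic outputs derive from a
single integer seed through a Lehmer-style stream kept inside 32-bit
range, and rendering is bit-identical for a fixed seed.

The test suite and acceptance script size their simulations to run on one
CPU in a few minutes as a deliberate design point: renders at 5 px/mm
(460 × 310 px frames), a full calibration of 11 standards × 6 replicates,
reduced 6 × 3 sets for repeated-seed recovery checks (20 seeds), and
50-record campaigns. At these sizes the Monte-Carlo error of the checks is
comfortably below the tolerances they assert.

## Known limitations

- Illumination gradients and additive offsets are attenuated but not
  cancelled by the ARI statistic; strong directional light will bias
  readings by design of the method itself.
- Clipped (overexposed) captures are flagged, not corrected; information
  on the 255 rail is gone.
- The linear calibration inherits a small concavity bias near the top of
  the 0–10 mg/L range.
- The bracket rounding rule is a convention; assays reporting continuous
  concentrations near 3.5 or 6.5 mg/L sit on a knife edge between map
  colours.
- Synthetic LOD/LOQ reflect the generator's noise model, not field
  chemistry; they should be read as "the analysis adds little error", not
  as a claim about the paper device's chemistry.
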