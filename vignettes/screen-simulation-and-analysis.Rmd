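---
title: "Simulating and analyzing SCPN-refinement screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing SCPN-refinement screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpnscreen)
```

## The measurement model

The screen quantifies refinement of subcerebral projection neuron (SCPN)
identity in cultured cortical neurons from multichannel immunofluorescence.
Each well contributes several imaging fields with a Hoechst nuclear channel
and up to three marker channels (CTIP2 on 488, SATB2 on 546, CTIP1 on 647).
Per nucleus, the analysis needs only two things: its morphology (area,
width, Hoechst intensity — for viability) and its mean intensity in each
marker channel (for expression calls). Everything downstream is counting:

* a nucleus is **CTIP2-positive** when its CTIP2 call is `low` or `high`,
  and likewise for SATB2/CTIP1;
* the **refinement ratio** of a well is
  $R = n_{\mathrm{CTIP2^+SATB2^-}} / n_{\mathrm{CTIP2^+SATB2^+}}$,
  matured SCPN-like cells over immature dual expressors;
* treatment effects are read off three normalized metrics: $R$ relative to
  untreated wells, total CTIP2+ counts relative to Fezf2-modRNA wells, and
  total SATB2+ counts relative to GFP-modRNA wells.

A refining compound converts dual expressors into CTIP2-only cells. The
generator encodes this as a single parameter $\delta \in [0,1]$, the
fraction of dual-positive cells converted:
$f'_{\mathrm{co}} = f_{\mathrm{co}} + \delta f_{\mathrm{dual}}$ and
$f'_{\mathrm{dual}} = (1-\delta) f_{\mathrm{dual}}$. Conversion conserves
$f_{\mathrm{co}} + f_{\mathrm{dual}}$ exactly — refinement changes identity,
not CTIP2 positivity — and the pooled-count ratio converges to
$(f_{\mathrm{co}} + \delta f_{\mathrm{dual}}) / ((1-\delta) f_{\mathrm{dual}})$,
which the test suite verifies against delta-method standard errors.

## What the synthetic plates emulate

Because the original screen images are not deposited, the package ships a
seeded generator whose defaults *are* the study's stated conditions:

* **~60% viable nuclei** among candidates per field; the non-viable
  remainder is a fixed mixture of small dim fragments (45%), oversized
  doublets (30%), pyknotic nuclei — small, condensed, Hoechst-bright —
  (12.5%) and normally sized but abnormally bright nuclei (12.5%).
* **Primary-neuron-like wells** (`primary_population_model()`): subtype
  fractions (CTIP2-only, SATB2-only, dual, unlabeled) = (0.05, 0.15, 0.20,
  0.60), i.e. 25% CTIP2+ and 35% SATB2+, inside the reported 20–30% and
  30–40% baselines, with the majority of each immunostained population dual
  positive; marker intensities are **trimodal** (distinct negative/low/high
  components).
* **mES-derived-like wells** (`mes_population_model()`): (0.03, 0.13, 0.07,
  0.77), i.e. ~10% CTIP2+ and ~20% SATB2+, with positive nuclei drawing
  from a single broad right-skewed **continuum** of intensities.
* **Compound effects**: the refinement shift $\delta$ (optionally
  dose-dependent through a saturating Hill curve,
  `dose_response_shift()`), and toxicity as a removed `kill_fraction`
  plus a `pyknotic_fraction` of survivors re-rendered small and bright.
  Presets: moderate = (0.45, 0.20), severe = (0.70, 0.35).
* **Plate layout**: control wells (untreated, DMSO vehicle, GFP modRNA,
  Fezf2 modRNA) plus compound wells in replicate at each designed dose
  (`screen_plate_map()`; the library design used duplicate wells at 10, 1
  and 0.1 uM, and the analyzed screen a single 1 uM dose).

It deliberately does **not** simulate optics (no PSF convolution or
chromatic shift), rosette-like spatial organization, uneven illumination, or
time-lapse. Passing tests therefore demonstrate correctness of the
*analysis* under realistic counting statistics and nucleus-level image
structure, not robustness to every artifact of real microscopy.

### Intensity scale and component locations

Intensities live on a 12-bit scale (0–4095) stored in 16-bit TIFF
containers; the printed analysis constants (Hoechst < 900, SATB2-high
500–1500) are only plausible on such a scale. The trimodal component
locations/spreads are, per marker (negative, low, high; `p_high` = share of
positives in the high component):

| marker | negative | low | high | p_high | low band | high band |
|---|---|---|---|---|---|---|
| CTIP2 | 15 ± 8 | 120 ± 12 | 360 ± 45 | 0.7 | [50, 150) | [150, 700) |
| SATB2 | 20 ± 10 | 300 ± 50 | 800 ± 120 | 0.6 | [150, 500) | [500, 1500) |
| CTIP1 | 12 ± 6 | 70 ± 8 | 180 ± 40 | 0.6 | [50, 90) | [90, 400) |

These were fixed once, before any test was run, to satisfy two
self-consistency constraints simultaneously: (i) the fixed-band classifier
must recover the generated component of ≥ 95% of nuclei, which requires
each component to sit 2.5+ spreads inside its band; and (ii) the
20%-of-maximum calibration rule must separate the negative component from
low+high with ≤ 5% error. Constraint (ii) rules out placing the CTIP2 low
component at the low band's center (100): with a high component near 400,
the observed per-well maximum mean is ~500–600, so the calibrated threshold
(~110) would land on top of such a low component. Shifting low up to 120 and
high down to 360 keeps both constraints comfortably satisfied while staying
inside the printed bands.

### Rendering and placement

Nuclei render as smooth-edged ellipses with ~1 px anti-aliased borders;
pixel coverage is 0.5 exactly on the ellipse outline, so counting pixels
above the half-maximum recovers the true area (tested to within 10%).
Placement is Poisson in count (`density`, default 150 candidates per field)
with a hard-core minimum spacing (9 um) except for a configurable fraction
of nuclei (default 10%) planted as clumped pairs at 6.5–8.5 um
center-to-center, specifically to exercise clump splitting. The default
field is 675 x 512 px at 0.65 um/px — a typical 20x camera field; none of
field size, bit depth or magnification optics are stated facts about the
original rig, so all are configurable. Every draw of a plate flows from one
top-level seed through deterministic per-well child seeds; identical seeds
give bit-identical TIFFs.

## Fixed semantics for the five detection parameters

The original analysis ran in a proprietary imaging package whose nucleus
detection exposes five printed parameters. This package's interpretation is
fixed and published here, so results are reproducible parameter for
parameter:

1. **Common threshold (0.1)** — global foreground: Hoechst ≥ 0.1 x the
   *robust maximum*, defined as the 99.9th percentile of the channel
   (hot-pixel resistant; the absolute maximum is available via
   `robust_max_quantile = 1`).
2. **Split factor (5.0 um)** — candidate seeds are local maxima of the
   (lightly smoothed, sigma 1 px) Euclidean distance transform; maxima
   closer than 5 um are merged (single linkage, keeping the deepest maximum,
   ties broken in raster order), and the mask is divided by seeded region
   growing.
3. **Individual threshold (0.5)** — each region's boundary is re-thresholded
   at 0.5 x that region's own peak Hoechst value, keeping the connected
   component containing the peak.
4. **Area > 10 um^2** — smaller regions are discarded and counted as debris.
5. **Contrast (0.05)** — regions whose (mean − local background) / robust
   maximum falls below 0.05 are discarded; local background is the median
   Hoechst intensity in a 2 um annulus around the region, excluding all
   foreground. The annulus choice is this package's fixed convention — some
   deterministic definition is required and none is published.

"Object width" is interpreted as the minor-axis length of the
intensity-weighted best-fit ellipse. Coordinates are pixel-centered and
0-based (x = column, y = row); areas are always reported in um^2. Labels are
assigned in raster order of each region's first pixel, making the whole
stage deterministic and platform-independent. On masks with no touching
nuclei the splitting provably degenerates to plain connected-component
labelling, which the acceptance suite checks exactly. No flat-field
correction is applied; whether the original pipeline thresholded corrected
intensities is unstated.

## Viability and toxicity

Viable nuclei satisfy, with *strict* inequalities matching the printed
signs: 33 < area < 100 um^2, width > 3.7 um, mean Hoechst < 900. Boundary
values are excluded. Excluded nuclei carry the first failing criterion in
the fixed order area, width, intensity.

The original toxicity exclusion was a blinded visual screen; it is
operationalized here quantitatively: a well is `severe` when its viable
count falls below 0.4 x the control-well median or its pyknotic fraction
(sub-minimum-area, Hoechst ≥ 900 candidates) exceeds 0.30; `moderate` below
0.7 x the median or above 0.15; otherwise `none`. All four cutoffs are
configurable (`toxicity_cutoffs()`). Disruption of rosette-like clustering
is *not* operationalized — the generator does not simulate rosettes, and a
reproducible quantitative proxy would be speculative.

## Classification policies

Two policies are implemented because the source describes both without
reconciling them: fixed per-marker intensity bands, and a threshold
calibrated to 20% of the maximum mean intensity observed among a well's
nuclei. The default is `fixed_bands`, which reproduces the tiered screen
analysis; `fraction_of_max` calibrates per well and per marker ("other
nuclei" most plausibly means the same imaging well) and reports positives
as `low` (it defines no high tier). Bands are half-open $[lo, hi)$; the
shared boundary between low and high belongs to high, and values above the
high band clamp to high rather than being discarded — silently dropping the
brightest expressors would bias every count. "Positive" means low ∪ high
throughout the subtype logic, preserving both the binary +/− phenotypes and
the tiers.

## Scoring and statistics

The per-well ratio is computed from counts pooled across the well's fields,
not averaged per field: screens report per-condition cell totals, and
pooling is the stable choice for rare categories (a field can easily contain
zero dual expressors). Wells with no dual expressors get an undefined ratio,
are flagged, excluded from condition means, and never imputed.
`compare_conditions()` is a two-sided unpaired Student t-test with pooled
variance — the conventional reading of "unpaired t-test" at N = 3 biological
replicates — with Welch available by argument; the test suite checks it
against the textbook closed form at 1e-10. Replicate unit for statistics is
the biological replicate, not the individual nucleus.

## Triage thresholds

Triage applies, per compound and dose (replicate wells averaged, worst QC
grade carried): toxicity exclusion, then L1 (ratio enhancement), L2 (CTIP2
preservation, `norm_ctip2_total >= 0.8` — "maintain" with tolerance for
counting noise), then L3 (SATB2 reduction, `norm_satb2_total <= 1.0`). A
compound screened at several doses is a hit if any dose is a hit.

The L1 cutoff deserves its own paragraph because it is the one place where a
naive default fails. "Enhancement" cannot mean `norm_ratio > 1`: an inert
compound's normalized ratio is *centred* on 1, so it exceeds 1 with
probability ~1/2 however many cells are counted, and a 22-compound null
library would contribute several false hits per plate by chance alone. The
default is therefore 1.5, placed by a delta-method power calculation at the
benchmark plate's counting depth. For a condition with $n$ viable nuclei and
category probabilities $p_1$ (CTIP2-only) and $p_2$ (dual), the relative SE
of the pooled ratio is approximately
$\sqrt{(1-p_1)/(np_1) + (1-p_2)/(np_2) + 2/n}$. At the benchmark's
primary-like fractions ($p_1 = 0.05$, $p_2 = 0.20$) and ~2,500 candidate
nuclei per condition (duplicate wells of ~1,250, in line with screens
counting >1,000 cells per well), this gives a null coefficient of variation
of ~0.12, so 1.5 sits ≈ 3.4 relative SEs above the null — while a genuine
enhancer at $\delta = 0.5$ scores ~6. The acceptance suite verifies the
operating characteristics this predicts: exactly the planted enhancers
recovered, and all planted severe-toxic compounds excluded, in ≥ 90% of 50
seeded plates.

## Problem sizes and numerical conventions

The shipped tests run, by the package's own choice of scale: single fields
at default density for segmentation accuracy (six fields, pooled precision
and recall ≥ 0.95 at 2 um centroid matching); a full 96-well rendered plate
at one 512 x 384 px field per well for end-to-end count conservation;
10,000 randomized candidates for the viability predicate; ≥ 5,000 viable
nuclei per condition for ratio recovery at $\delta \in \{0, 0.25, 0.5\}$;
and 50 seeded benchmark plates at the statistical layer (population draws
fed directly to classification, bypassing rendering — the rendered path is
exercised separately) for triage recovery. Configuration files are YAML.
All analysis stages are seed-free and deterministic; only plate simulation
consumes randomness.

## Known limitations

* Segmentation semantics are a faithful *interpretation* of five printed
  parameters, not a re-implementation of proprietary internals; absolute
  per-object boundaries may differ from the original software even where
  counts agree.
* The toxicity grades quantify two of the four visual exclusion phenotypes
  (count depression, pyknosis); debris is reported but not graded on, and
  rosette disruption is out of scope.
* The generator's intensity model is parametric and well-separated by
  construction; it does not emulate staining batch effects, bleed-through,
  or focus drift, so classification accuracies measured here are upper
  bounds for real data.
* With very small dual-expressor counts the pooled ratio is noisy and its
  delta-method SE optimistic; the undefined-ratio flag, not a continuity
  correction, is the package's answer to empty denominators.
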