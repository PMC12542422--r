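---
title: "Quantifying translocation screens: models, parameters and design choices"
author: "rbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translocation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and its statistics

The screens this package analyzes read out where a fluorescent or
immunostained reporter sits inside the cell. In an unperturbed cell the
40S biogenesis factor ENP1 concentrates in nucleoli; blocking nuclear
export with leptomycin B (LMB) releases it to the nucleoplasm unless
pre-40S assembly is defective, in which case it stays nucleolar.
Ribosomal-protein reporters (RPS2-YFP, RPL29-GFP) are cytoplasmic at
steady state and accumulate in the nucleus when subunit maturation stalls.
Each cell is therefore assigned to one of eight classes — nucleolar,
nucleolar/nucleoplasmic, nucleoplasmic, cytoplasmic, mitotic, apoptotic,
no signal, missegmented — and each readout declares some classes "hits"
and some "non-hits" (`readout_spec()`); mitotic, apoptotic, signal-free
and missegmented cells are always excluded. A well's hit rate is
hits / (hits + non-hits) over its pooled sites.

Three statistics summarize a screen:

* **z′ factor**, `1 - 3(sd_pos + sd_neg) / |mean_pos - mean_neg|`,
  computed from per-well hit rates of a positive control versus DMSO.
  Sample standard deviations (n − 1) are used throughout: control groups
  are small (tens of wells), and the n − 1 form is the unbiased-variance
  convention. z′ ≤ 1 always; ≥ 0.5 is the usual "excellent assay" bar.
* **Hit threshold**: per readout and biological replicate, the mean DMSO
  hit rate plus five sample SDs. Thresholds are per-replicate rather than
  pooled because plate-to-plate and day-to-day effects shift the null;
  both the multiplier and pooling are configurable.
* **Replicate rule**: a compound is a final hit in a readout when its
  rate exceeds the threshold in at least k of N replicates (default 2 of
  3 — a compound seen in two of three replicates is still called). The
  union over readouts gives the hit list. Undefined rates (empty
  denominators) never count as above threshold, and compounds missing a
  replicate are reported as incomplete rather than silently called.

The −LMB ENP1 denominator is genuinely ambiguous in the assay tradition:
one convention scores nucleoplasmic over nucleoplasmic + nucleolar
(+ nucleolar/nucleoplasmic), another over all interphase cells. The
default here follows the stricter hit/non-hit table (non-hit = nucleolar
and nucleolar/nucleoplasmic); `readout_spec(denominator =)` selects the
`"results"` (nucleolar only) or `"interphase"` variants. No attempt is
made to guess which one an individual laboratory intended.

# The synthetic screen generator

Real screen images for this assay family are archived externally and far
too large for routine testing, so the generator is a first-class module
that emulates the screen's statistical structure end to end.

**Layout.** 384-well plates, rows A–P: columns 1 and 23 carry DMSO,
columns 2 and 24 cycle through six positive-control drugs (actinomycin D,
bortezomib, CX-5461, cycloheximide, MG132, silvestrol), columns 3–22 hold
the library in row-major order; a 1172-compound library fills four plates
with 108 empty wells. That gives 32 DMSO wells per plate — enough for a
stable mean + 5 SD null.

**Effect model.** Each readout has a baseline class-probability vector
`p_ctrl` and a fully-active vector `p_act`; a well with activity `a`
draws cell classes from `(1 − a)·p_ctrl + a·p_act`. Since per-class
baseline frequencies are not published for this screen, the defaults are
stipulated once: ENP1 −LMB baseline is nucleolar-dominant (0.55/0.18),
+LMB baseline mostly nucleoplasmic (0.48), the RP reporters cytoplasmic
(0.75), each with ~20% of cells in the four excluded classes; active
vectors shift mass to the respective hit classes. Positive controls get
activity 0.9. DMSO and inactive library wells receive per-well activity
jitter drawn from Beta(2, 98) — mean 0.02, SD ≈ 0.014 — so the DMSO null
has the nonzero variance a 5-SD threshold needs. The shape was chosen by
a forward calculation (before any acceptance measurement) so that the
expected number of false-positive final hits among ~1200 inactive
compounds under the 2-of-3 rule is below 0.01 per readout; heavier-tailed
choices (Beta(0.5, ·)) put spurious compounds over a 5-SD cut at a
noticeable rate and do not match the tight well-to-well reproducibility
of solvent controls.

**Cells and rendering.** ~2000 cells are seeded per well but only a 3×3
montage (~1/9 of the well) is imaged, so sites draw a Poisson(40) cell
count at the default 256×256 px, 0.65 µm/px field. Interphase nuclei are
~5 µm disks with 2–4 nucleolar sub-disks; mitotic cells are small bright
Hoechst blobs; apoptotic cells fragment into sub-resolution blobs;
missegmented cells are two fused nuclei sharing one label. The reporter
channel uses a per-class compartment intensity table (e.g. nucleolar
class: nucleoli 1.0, nucleoplasm 0.25, cytoplasm 0.2) chosen to make the
classes separable at the default signal-to-noise ratio — the original
phenotypes exist only as example images, so these levels are a modelling
choice, not a fit. Acquisition applies a radial gain field (30% corner
fall-off) plus a constant offset, then Poisson noise at 200
photons/intensity-unit and Gaussian read noise (SD 0.005).

What the generator does *not* model — and hence what passing tests do not
demonstrate about real data: optical PSF blur, 3-D structure, cell-cycle
and density gradients, staining batch effects, debris, and focus drift
(the focus filter is exercised on synthetically blurred copies). Results
on real screens will be dominated by exactly these nuisances; the
package's claim is that the *statistical pipeline* is correct, not that
the classifier generalizes beyond the simulation.

# Numerical and algorithmic choices

**Illumination model.** The flat-field estimator is a robust quantile
model in the same two-term class as retrospective methods like CIDRE: the
additive offset is the Gaussian-smoothed per-pixel 5% quantile of the
stack, the multiplicative gain the smoothed 20%-trimmed per-pixel mean of
the offset-subtracted stack, normalized to field mean 1 (smoothing σ = 2%
of image width; ≥ 50 images required). No equivalence with the original
CIDRE optimization is claimed. Two identifiability caveats are inherent
to single-stack estimation and documented rather than hidden: (i) gain is
only defined up to scale, so corrected intensities are relative, and the
inverse-model test checks flatness (CV) rather than absolute recovery;
(ii) a stack of flats at a *single* level cannot separate gain from
offset — recovery is tested on calibration-style stacks with varying
exposure levels including near-dark frames, at calibration SNR (photon
scale 2000), where gain correlation reaches > 0.99 and correcting the
estimation stack shrinks the per-pixel stack-mean CV by > 10×. Estimating
from sparse cell fields at screen SNR recovers the gain shape more
weakly (correlation ≈ 0.8); per-batch estimation in image mode is still
worthwhile, and the classifier confusion used for table-mode comparisons
is measured under that same processing so the bias cancels.

**Focus exclusion** scores each image by the variance of its Laplacian
and rejects images below 0.2× the batch median — relative, so the rule is
exposure-invariant. A single image is always retained.

**Segmentation.** Gaussian pre-smoothing (σ 1.5 px), Otsu threshold, hole
filling, then a watershed on the distance transform. The split knob is
the watershed merge tolerance in distance-map units (default 1 px):
basins whose peaks differ by less are merged. Depth-based tolerance is
the same lever as seeding peaks with a minimum separation of half the
expected nucleus radius, and 1 px was selected on synthetic ground truth
as the value that splits 20%-overlapping disk pairs without
oversegmenting noisy single nuclei. Nuclei outside 30–800 µm² are
discarded; border-touching nuclei keep their features but carry a flag.
The cytoplasm ring dilates each nucleus by round(6.5 µm / pixel size)
pixels; contested pixels go to the nucleus with the smallest Euclidean
distance, ties to the lower label, so rings are disjoint by construction.

**Features.** 15 per cell: area (µm²), eccentricity (from second moments
with a 1/12 pixel-extent correction), solidity (area over convex-hull
area), nuclear mean/integrated/SD per channel, ring reporter
mean/integrated, mean of the top decile of nuclear reporter pixels and
its ratio to the nuclear median, white-top-hat spot count (disc radius
1.8 µm, absolute height 0.15), and the nuclear/ring reporter ratio.
Ratios with denominators below 10⁻⁶ are set to 0 and flagged instead of
propagating NaN. The set is *not* a reconstruction of any particular
CellProfiler configuration — the published pipelines do not enumerate
their features — it is the minimal set that separates the eight rendered
classes.

**Classifier.** A seeded random forest (300 trees) over the standardized
feature table, with training data taken from the simulator's labelled
cells — the synthetic stand-in for interactive annotation in tools like
the Advanced Cell Classifier. Posterior ties break to the earlier
canonical class. Held-out accuracy on rendered data is ~0.99; the 0.85
floor asserted in tests is deliberately loose because accuracy depends on
the stipulated rendering contrasts. Apoptotic cells are rarely segmented
at all (their fragments fall below the 30 µm² area floor), so they are
scarce in training; since they are excluded from every hit-rate
denominator anyway, this biases nothing downstream.

**Counter assays.** The γH2AX fraction replaces manual counting with an
explicit rule: a cell is positive if its nuclear top-hat focus count is
≥ 5 or its nuclear mean exceeds the negative-control mean + 3 SD. The
degron-reporter readout integrates GFP over each nucleus; the degradation
statistic is the ratio of condition medians (+auxin / −auxin), and
"GFP-positive" uses a threshold calibrated on the uninduced condition
because absolute intensities are camera-dependent. Counter assays are
simulated at 0.25 µm/px — they are follow-up experiments imaged at higher
magnification than the 10× screen, and individual ~0.5 µm foci are not
resolvable at 0.65 µm/px.

# Problem sizes in the shipped tests

Tests are sized to what the statistics need, not more: the full-library
recovery test runs 1172 compounds × 4 readouts × 3 replicates in table
mode (~18k wells, seconds); the false-positive property repeats a
300-compound screen over 10 seeds; classifier training uses 40 rendered
sites (~1000 labelled cells) with an 80/20 split; segmentation
precision/recall uses 10 corrected sites against ground truth; the
cross-mode consistency check runs 10 probe wells × 3 sites through the
full image pipeline against the confusion-adjusted analytic expectation.
The acceptance script simulates one 384-well plate per readout at ~100
classified cells per well.

# Interfaces

The package is a library: `run_screen_analysis()` is the single entry
point (returning a printable `screen_result`), with every stage also
exposed as a documented function, and `scripts/acceptance.R` as the
runnable reproduction script. No shell CLI is shipped — the audience for
this artifact drives it from R, and a subcommand wrapper would duplicate
the function surface without adding control.

# Known limitations

* The effect model treats a compound's activity as readout-shared by
  default; readout-specific activity requires the matrix form.
* Illumination gain is recovered up to scale, and only weakly from
  sparse low-background stacks (see above).
* The missegmented class is simulated as fused nuclei only; other real
  segmentation failure modes (debris, over-splitting) are not emulated.
* z′ is reported per (readout, replicate) pooling control wells across
  plates; per-plate z′ is available but the pooled form is the default,
  as replicate-level quality is what gates a screen.
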