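---
title: "Methods: reporter quantification, PBM affinity, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter quantification, PBM affinity, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerquant)
```

# The measurement model

An episomal reporter assay delivers two plasmids into presumptive limb
tissue: an enhancer-driven GFP reporter and a constitutively expressed RFP
transfection control. Because electroporation is mosaic and its dose varies
between embryos, raw GFP intensity is uninterpretable on its own; the
assay's summary statistic is

$$\text{relative activity} \;=\; \frac{\sum_{\text{activity region}} \text{GFP}}{\sum_{\text{transfection region}} \text{RFP}}$$

computed inside an anatomical mask. Dividing by total RFP cancels the
embryo-to-embryo transfection differences; the quantity is dimensionless
and invariant under joint rescaling of both channels (exposure, gain).
Intensities are summed raw — there is no background-subtraction step in the
measurement definition — which introduces a small upward bias at very low
activity (the background floor); this is a property of the measurement, not
of the implementation, and is visible in the simulations below.

## Pipeline stages

`quantify_bundle()` runs, in order:

1. **Grayscale + bilateral denoising.** The bilateral filter smooths within
   tissue while preserving the tissue/background step, because its range
   kernel suppresses averaging across large intensity differences. Defaults:
   `sigma_spatial = 3` px, `sigma_range` = 10% of the channel's dynamic
   range. Both are recorded with the output; denoising can be disabled.
2. **Limb segmentation.** Otsu thresholding of the light image finds the
   tissue foreground; tissue includes both limb and adjacent body wall,
   which an automatic threshold cannot distinguish — that separation is the
   one manual input of the workflow, an annotated boundary polyline. The
   polyline is rasterized as a 4-connected cut (a 4-connected curve
   separates 8-connected components), and the limb is the component
   containing the annotated limb-side point.
3. **Anatomical masks.** `Limb ⊇ Posterior ⊇ ZPA`. The assay defines these
   regions biologically; as a reproducible pixel rule the package crops the
   limb bounding box along the annotated anterior–posterior and
   proximal–distal axes: Posterior keeps the posterior-most fraction
   (default 0.5), ZPA intersects the posterior-most 0.35 with the
   distal-most 0.4, approximating the zone of polarizing activity in the
   posterior-distal quadrant. All fractions are parameters; orientation
   (default: top = anterior, right = distal) comes from the annotation.
4. **Transfection and activity regions.** The transfection region is the
   Otsu foreground of the masked RFP pixels (threshold computed from pixels
   inside the analysis mask only, so the cut reflects the masked intensity
   distribution); the activity region is the Otsu foreground of the GFP
   pixels inside the transfection region. Foreground is strictly greater
   than the threshold; ties go to background (deterministic).
5. **Measurement.** Pixel counts and total intensities of both regions, then
   the GFP/RFP ratio. Whether GFP/RFP are summed over the Otsu-foreground
   regions (default) or over every pixel of the anatomical mask is a
   recorded switch (`quant_params(measure=)`), since either reading of
   "measured within the appropriate mask" is defensible.

Embryos in which the masked RFP is indistinguishable from background are
not errors: they produce a record flagged `"no transfection detected"` with
`NA` activity, for exclusion bookkeeping. Channels with more than 1%
saturated pixels are flagged but kept.

## The bimodality gate

Otsu's method *always* returns a cut, including through the middle of a
unimodal histogram. Two real cases make this a correctness problem, not a
cosmetic one:

* a **silent enhancer**: GFP inside the transfection region is pure
  background noise; a raw Otsu foreground would be the upper half of the
  noise, wrongly reporting ~50% "active" pixels;
* a **uniformly active region**: every transfected pixel in the mask
  expresses; a raw Otsu cut halves the true signal (and on a noiseless
  image the region is exactly constant, where no threshold exists at all).

When a background reference is available (the pipeline estimates level and
sd from the denoised pixels outside the limb), region finding therefore
accepts the Otsu split only if it is genuinely bimodal, measured by a
d′-type statistic: the class-mean separation divided by the pooled
within-class standard deviation. An Otsu cut through unimodal Gaussian
noise yields d′ ≈ 2.7 *independently of the noise level*, while real
transfection or activity contrast in this assay yields d′ well above 10;
the default gate is `min_separation_sd = 4`. A region judged unimodal is
then called in one piece: entirely foreground if its mean exceeds
background + 3 sd, otherwise empty (silent). A constant region follows the
same all-or-nothing rule, with an absolute tolerance so that numerical
jitter on an effectively constant image can never fabricate bimodality.
`otsu_threshold()`, `transfection_region()` and `activity_region()` called
without a background reference perform plain Otsu, which is what the
oracle-equivalence tests exercise. The trade-off is documented rather than
hidden: weak genuine bimodality with separation below ~4 within-class sd is
treated as uniform; at the contrasts this assay produces (signal ≈ 19×
background at the defaults) the regime is far from the boundary.

# The synthetic benchmark

`simulate_limb_bundle()` generates the study conditions the quantification
is validated against. The scene is deliberately minimal: a single-ellipse
limb attached to a rectangular body-wall strip (the simplest geometry that
makes the manual boundary step meaningful), a mosaic transfection field
(white noise blurred with a Gaussian of sigma `transfection_patchiness`,
thresholded at the `1 − transfection_fraction` quantile within the limb —
patchy electroporation without a cell model), and an activity focus in
limb-normalized coordinates. GFP in active pixels is generated proportional
to the local RFP above background, mirroring the co-electroporation design
in which both plasmids share a transfection dose, so `activity_level` *is*
the true GFP:RFP ratio. Channels receive additive Gaussian noise and are
clipped to the bit depth (8-bit default; the source imaging hardware's bit
depth is unreported, so it is a parameter).

Defaults, chosen once as a realistic operating point and then left alone:
160×120 px frames, fluorescence background 2 (fluorescence backgrounds are
dark relative to signal), RFP dose 150 above background,
`transfection_fraction = 0.4`, patchiness 6 px, activity focus at
normalized (0.5, 0.8) with radius 0.6 — geometry that covers the posterior
half of the limb, so the default Posterior-mask measurement sees uniform
activity and the measured ratio estimates `activity_level` directly.
"Moderate noise" in the test suite means `noise_sd = 8` (~3% of the 8-bit
range); the stress level is 12.75 (5%).

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: optics (no point-spread function, no vignetting, no
depth effects), cell-level structure, autofluorescence gradients,
anatomical variation in limb shape beyond ellipse parameters, or imperfect
manual boundaries. The benchmark validates the measurement machinery, not
the microscope.

Measured behaviour on the benchmark (all recomputed by the test suite and
`scripts/acceptance.R` at run time): noiseless bundles at activity 0.3–0.8
are recovered within 5% (1.3% at 0.5); at 5% noise the median error over
seeds stays within 15%; and across a 20-embryo cohort spanning activities
0.1–1.0 at moderate noise, estimated and true activities agree in rank
(Spearman ≥ 0.9). Below activity ≈ 0.2 the unsubtracted background floor
dominates relative error, which is why point-recovery claims are made above
that level while rank claims span the full range.

# PBM relative affinity

A protein binding microarray measures a factor's median signal against all
4^8 = 65,536 DNA 8-mers. Relative affinity of a word is its median
intensity divided by the factor's optimal (maximum-intensity) 8-mer, giving
a 0–1 scale in which the optimum scores exactly 1. Conventions adopted,
following UniProbe practice:

* **Double-strandedness.** An 8-mer and its reverse complement share one
  intensity; collapsed tables are expanded on load, and lookups fall back
  to the reverse complement.
* **Site windows.** Binding sites in this context are 6–9 bp (E-boxes,
  homeobox sites), so no single 8-mer *is* the site. The default policy
  scores a site as the maximum relative affinity over all 8-mer windows
  overlapping the site interval by at least 6 bases; full containment and
  any-overlap policies are available, and the maximizing window is recorded
  per cell (`window_choice` provenance in the matrix object).
* **Ties** for the optimal 8-mer break lexicographically and are flagged.
* **Missing factors** (no PBM data exists for some bHLH factors such as
  Hand2) appear as explicit NA rows in the matrix, never silent omissions.

The synthetic PBM generator plants a known consensus with expected
intensity `optimal × decay^m`, where `m` is the mismatch count to the
consensus or its reverse complement, whichever is smaller, and
multiplicative lognormal noise (CV default 0.15) shared within each
reverse-complement pair so tables stay exactly RC-symmetric. Defaults
`optimal_intensity = 5000` and `decay_per_mismatch = 0.45` give a
realistic UniProbe-like dynamic range in which one mismatch roughly halves
the signal; exact-value tests use CV 0.

# Sequence and construct bookkeeping

Coordinates are 1-based inclusive everywhere (`length = end − start + 1`),
the convention under which the published enhancer coordinates reproduce the
published fragment lengths exactly (1,373 bp chicken, 1,198 bp human); BED
input is converted from 0-based half-open on read. The fragment catalogue
(`zrs_fragments()`) carries both the published totals and the published
component lengths; two entries are internally inconsistent as published
(F2: 309 vs 236+60+11 = 307, with an alternative published figure of 13 bp
for the last component; F1F2: 1065 vs 749+236+11 = 996), and
`fragment_audit()` reports both numbers rather than silently preferring
one. Motif scanning reports all overlapping matches on both strands
(E-boxes and Hox sites can overlap), with minus-strand hits in plus-strand
coordinates. In-silico mutagenesis is substitution-only (no indels); the
modelled strategy alters 3–4 core bases while introducing a restriction
site for colony screening, and `verify_mutation()` checks exactly the three
acceptance rules of that strategy.

# Statistics

Group sizes in this kind of assay are small (4–20 embryos) and activity
distributions are typically non-normal, so the reporting pathway is
rank-based throughout: Shapiro–Wilk per group as a screen (not a gate),
IQR-rule outliers flagged but never removed (dropping them would eliminate
the smallest groups entirely), Kruskal–Wallis (tie-corrected, chi-squared
approximation) for three or more groups with Dunn's z post hoc and
Bonferroni correction over the comparisons actually performed, and
Mann–Whitney U for two groups. Numerical choices:

* **Exact vs approximate U.** Full enumeration of all group reassignments
  when `max(n1, n2) ≤ 8` (at most 12,870 arrangements; handles ties
  exactly, and a completely tied pair correctly returns p = 1), otherwise
  the tie-corrected normal approximation with continuity correction. The
  two branches agree within 0.02 at the crossover, and the enumeration
  matches `wilcox.test`'s exact distribution on tie-free data.
* **Degenerate inputs.** All-identical observations give H = 0, p = 1 with
  a degenerate flag; Dunn's z for identical groups is 0 and Bonferroni
  clamps corrected p at 1.
* **Quantiles** use linear interpolation (type 7), the unstated-but-common
  default, and are configurable.
* **Stars.** The strict scheme (`* < 0.05, ** < 0.005, *** < 0.0005,
  **** < 0.0001`) is the default; because figure legends in this literature
  often use the `0.05/0.01/0.001/0.0001` ladder instead, that is provided
  as the `"figure"` preset. Thresholds are strict inequalities (p = 0.05 is
  `ns`).

Calibration is asserted empirically: both tests' type-I error falls in
[0.03, 0.07] at nominal 0.05 over 1000 null simulations (sizes 3×10 and
10 vs 10). One limit worth knowing: rank statistics bound how extreme small
samples can be — with n = 5 per group, an adjacent pair in a three-group
Dunn comparison cannot exceed |z| ≈ 1.77 regardless of separation, so
"everything significant" expectations only hold from n ≈ 10 upward.

# Pipeline reproducibility

`run_pipeline()` derives every random choice from one master seed
(per-bundle seeds are master + index), writes all outputs under
`output_root/run_id/`, and appends a manifest recording the configuration
digest, seeds, package version and MD5 checksum of every output; rerunning
an identical configuration reproduces identical checksums, which the test
suite and acceptance script assert. Problem sizes used by the default test
run are scaled versions of the study conditions (100×76 px frames, 5–20
embryos per cohort, 1000 null simulations); the acceptance script uses the
full 160×120 default frames for the single-bundle recovery benchmark and
the 20-bundle rank benchmark.

# Known limitations

* The anatomical masks are axis-aligned bounding-box crops, not
  curvature-following anatomical segmentations; they are reproducible and
  parameterized, but a strongly bent limb would be better served by a
  landmark-based mask.
* The bimodality gate trades sensitivity to weak, genuinely bimodal
  activity (d′ < 4) for robustness of the silent and uniform cases.
* Relative activity carries the background floor of the unsubtracted
  measurement; comparisons between groups are unaffected (the floor is
  common), but absolute values below ~0.2 are compressed upward.
* PBM scoring is window-maximum over 8-mers; it does not model binding
  energetics, flanking effects, or factors without PBM data.
* Embryo inclusion/exclusion criteria are configuration-driven flags
  (saturation, no-transfection), not hard-coded rules.
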