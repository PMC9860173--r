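---
title: "Quantifying embryo reporter expression and motif potential: models and methods"
author: "embryoexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying embryo reporter expression and motif potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoexpress)
```

## The measurement problem

Reporter assays in *Drosophila melanogaster* embryos read out the activity
of a candidate regulatory sequence as a spatial pattern of fluorescence:
a candidate enhancer is cloned upstream of a minimal promoter driving
`lacZ`, embryos are stained and imaged as two-channel max-projections
(nuclear stain plus reporter), and the biological questions — does a
mutant variant change expression level? does it drive expression outside
the native pattern? how wide is a stripe? — all reduce to quantitative
image measurements in a coordinate system intrinsic to the embryo.
`embryoexpress` implements that measurement stack, the statistics layered
on top of it, and the sequence-side tools (mutant-library simulation, PWM
information content, exact-p-value motif scanning) used to relate
regulatory activity to sequence content.

Because real embryo images are not redistributable at this scale, the
package also ships first-class synthetic generators with analytic ground
truth. They exist so that every stage of the pipeline can be validated
end to end: axis recovery against known rotations, nuclear intensities
against known pattern values, stripe widths against known geometry.

## Embryo coordinate frame

All spatial quantities live in normalized embryo coordinates: AP
(anterior–posterior) and DV (dorsal–ventral) fractions in $[0, 1]$, with
AP $0$ at the anterior pole and DV $0$ at the dorsal side (image top for
an unrotated embryo; rasters are row-major with row 1 at the top). The
frame is estimated from the nuclear channel in three steps:

1. **Masking** (`mask_embryo`): the nuclear channel is strongly blurred
   (default $\sigma = 6$ px) so nuclei and the diffuse embryo body merge
   into one region, thresholded by Otsu's method on a `log1p` scale
   (the embryo-vs-background gap dominates the body-vs-nuclei gap there),
   holes are filled, and the largest connected component is kept. The
   largest-component rule drops debris and bright specks off the embryo.
2. **Axis fitting** (`fit_embryo_frame`): an ellipse is fitted by second
   moments, and the AP direction is the maximum Feret diameter (longest
   caliper distance) of the mask. The caliper extent is nearly flat
   around its maximum for elongated shapes, so the raw caliper argmax is
   refined by the chord between the centroids of the two tip point
   clusters (pixels within 3 px of the extreme projections); on
   noise-free elliptical masks this recovers rotations in
   $[-60^\circ, 60^\circ]$ to better than $0.1^\circ$. Egg length $L$ is
   the Feret diameter, egg height $H$ the perpendicular caliper extent.
   Masks with fitted axis ratio below 1.1 are rejected as
   orientation-ambiguous rather than guessed.
3. **Anterior resolution**: a mask alone cannot distinguish anterior from
   posterior ($180^\circ$ ambiguity). The frame carries
   `anterior = "unresolved"` until the caller supplies the side
   (`resolve_anterior`), e.g. from generator truth or curation metadata.
   Profile extraction refuses unresolved frames. The analogous
   dorsal/ventral flip is fixed by convention (fitted angles stay in
   $(-90^\circ, 90^\circ]$), which suffices for synthetic data and for
   images pre-oriented by the acquisition protocol.

## Nucleus segmentation

`segment_nuclei` applies Otsu's threshold to the nuclear channel inside
the mask, removes objects below `min_area` (default 4 px$^2$, the 2-D
mapping of a small nuclear volume cutoff), and splits fused objects by a
watershed on the distance transform; the watershed's height tolerance
(default 1 px) plays the role of a minimum seed separation. Mean
intensities per nucleus are plain arithmetic means of the pixels under
each label (`measure_nuclei`). On rendered embryos with inter-nucleus
boundary separation of one nucleus radius and pixel noise at 10% of the
nuclear amplitude, recall and precision are both above 0.95, and with
zero noise measured means match ground truth to better than 1%.

## AP expression profiles

The stripe-level readout follows a four-stage pipeline, applied per
embryo:

1. **Band extraction** (`extract_ap_profile`): reporter intensity is
   averaged over a central band covering 30% of the embryo height
   (default `band_fraction = 0.30`), per pixel position along the AP
   axis. The band is evaluated in the fitted frame directly — each pixel
   inside mask and band contributes to the AP column given by its
   projection — so no image resampling is involved.
2. **Conditioning** (`condition_profile`): Gaussian smoothing followed by
   linear interpolation onto a fixed grid. The smoothing bandwidth is not
   dictated by the underlying protocol, so the default is deliberately
   mild, $\sigma$ = 0.01 of egg length; the resampling grid has 1000
   points. The kernel is renormalized at the edges, so constant profiles
   are exactly invariant and interior-supported signals conserve their
   mass to well under 0.5%.
3. **Normalization** (`normalize_profile`): background removal and
   scaling use the posterior tail of the profile (last 20% of egg
   length): with $Q_{10}$ and $Q_{50}$ the 10% and 50% quantiles of the
   tail (linear interpolation between order statistics),
   $$I' = \frac{I - Q_{10}}{Q_{50} - Q_{10}}.$$
   This particular arithmetic was chosen for affine invariance (staining
   gain and offset cancel) and because it pins the tail background to 0
   and the tail median to 1 exactly. A perfectly flat tail makes the
   denominator vanish and raises a degenerate-normalization error rather
   than returning infinities. The pipeline order is smooth →
   interpolate → normalize, and the provenance of each profile records
   the parameters used.
4. **Bootstrap band** (`bootstrap_band`): embryos (not pixels) are the
   resampling unit, matching the replicate structure of a transgenic
   line. The band is the pointwise 2.5%/97.5% envelope of 1000 resampled
   mean profiles at the default 95% level. With 20 embryos per line the
   band covers a known true profile at roughly 92–93% of grid points —
   the usual mild undercoverage of the percentile bootstrap at small n —
   comfortably above the 90% working threshold used in validation.

## Stripe detection and width

Lateral stripes (neurogenic-ectoderm style patterns) are analyzed from
nucleus tables rather than pixels:

1. nuclei are partitioned into AP bins (default width 0.05, half-open
   intervals, boundary nuclei joining the upper bin);
2. each bin gets a kernel-smoothed DV fluorescence profile
   (Nadaraya–Watson, default grid step 0.01, kernel $\sigma$ = 0.02);
3. profile peaks above a prominence threshold (default 25% of the bin's
   profile range, measured against the bin's own minimum as local
   baseline) are detected with their half-maximum DV intervals;
4. peaks are aligned across adjacent bins by nearest-DV matching under a
   maximum jump of 0.05, and traces spanning fewer than 60% of the
   occupied bins are discarded;
5. a second pass re-profiles each bin on DV *residuals* about the
   interpolated midline. Without this, a stripe crossing bins at an
   angle is widened by the bin's AP extent (at $20^\circ$ and bin width
   0.05 the smearing is $\tan 20^\circ \times 0.05 \approx 0.018$ DV
   units — a fifth of a typical stripe width). Bins whose refined
   half-max interval is more than twice the trace median (stripe corners
   clipped by the field of view, near-empty bins) are dropped.

Membership follows the half-maximum rule: a nucleus belongs to the stripe
when its DV position falls inside the half-max interval, evaluated at the
nucleus's own AP position by linear interpolation of the aligned peaks.
The underlying procedure describes the half-max rule per bin while the
peak itself lives in the DV profile; this package reads the interval as a
DV interval within each AP bin (the geometrically coherent reading) and
interpolates it continuously along the trace. Manual curation is an
explicit include/exclude override list (`assign_membership`), never a
silent edit.

Width (`measure_stripe`) uses a piecewise-linear midline: the members'
AP range is cut into segments (default length 0.1), each segment's line
is the least-squares fit of DV on AP over its members, and the segment
width is the largest perpendicular distance between member nucleus
centers. Segments holding fewer than half the median member count are
skipped — a clipped stripe end cannot support an extreme-distance
statistic. The overall width is the arithmetic mean of segment widths.
Because the width is an extreme-value statistic over ~25–35 nuclei per
segment, individual fixtures scatter by a few percent; validation
therefore checks the mean over replicate fixtures, which is stable to
within ~1% and — crucially — free of the $1/\cos\theta$ inflation a
naive DV-extent measure would show on rotated stripes.

## Germ-layer region statistics

`measure_regions` places circular ROIs of constant pixel radius (default
15 px; the underlying protocol fixes only "constant size") at normalized
coordinates standing for the three germ-layer readouts: ectoderm =
lateral (AP 0.5, DV 0.3), mesoderm = ventral (AP 0.5, DV 0.85), endoderm
= posterior (AP 0.92, DV 0.5). ROIs that leave the embryo mask raise a
placement error instead of silently averaging background. Per-line
comparisons (`classify_line`) use Student's two-sample t test with
pooled variance — the plain reading of "two-tailed t test"; Welch is
available by flag — and call a line *up* or *down* by the sign of the
mean difference when $p < \alpha$ (default 0.05), *unchanged* otherwise.
No multiple-testing correction is applied per call, mirroring per-line
usage; `stats::p.adjust` can be applied across a table of lines when a
corrected view is wanted. Degenerate inputs follow explicit conventions:
zero pooled variance with equal means gives $p = 1$.

## PWMs, information content, and exact-p-value scanning

A PWM is stored column-stochastic with an additive pseudocount
(default 0.01 per cell) and a background distribution (default uniform).
Information content is the Kullback–Leibler divergence from background,
$$I_{\mathrm{motif}} = \sum_{i=1}^{L} \sum_{n \in \{A,C,G,T\}} p_{i,n}
\log_2 \frac{p_{i,n}}{b_n},$$
in bits; $2^{-I}$ approximates the per-position probability of a chance
hit and drives the ECDF view over a motif collection (`ic_ecdf`).

Scanning scores every window of length $L$ on both strands with the
log2-odds score and assigns each score an exact p-value under the
background model: per-column scores are discretized onto a lattice
(default 1000 bins across the attainable range) and the column
distributions are convolved position by position — the standard dynamic
program of exact motif scanners. The scanner reuses the same lattice, so
a scanned window's p-value is exactly the DP tail mass of its lattice
score; for every fixture motif up to $L = 8$ the table agrees with
exhaustive enumeration of all $4^L$ words to floating-point precision.
The discretization makes the achievable test sizes a finite set: at the
default granularity the achieved size at a 0.001 cutoff sits within a
few percent of nominal, and empirical hit rates on i.i.d. background
match the achieved size within binomial error. Windows containing
ambiguity letters are skipped; hits are reported in forward-strand,
0-based, half-open coordinates on either strand; overlapping hits are
all counted. The top-fraction filter of `hit_statistics` keeps the
$\lceil 0.30\,n \rceil$ best-scoring hits per motif across all sequences
(the per-motif reading of a "top 30% of scores" rule; configurable).

## Sequence-library simulators

`simulate_mutant_library` models error-prone PCR as independent per-base
substitution at a fixed rate (default usage: 0.005/base, i.e. a ~0.5%
error rate that yields 1–5 substitutions on a 300–500 bp enhancer);
substitutions go to the three other bases uniformly and indels are not
modeled, since no downstream analysis here consumes them. Per-line
mutation counts are exactly Binomial($L$, rate), which is the oracle the
validation suite checks against (mean and variance within Monte-Carlo
error over $10^4$ lines). Mutation lists are stored with 0-based
positions and reconstruct each variant from the reference exactly.
`summarize_library` reports lines, total mutations, the total/n mean and
the count histogram; on a panel of 91 lines totalling 505 mutations it
reports a mean of 5.5 at one decimal.

`generate_random_sequences` emulates synthesized oligo libraries: unique
random ACGT sequences of fixed length (collisions re-sampled), optionally
carrying a verbatim motif at a controlled offset. "Approximately at the
center" is implemented as the deterministic offset
$\lfloor (L - m)/2 \rfloor$; a uniform and a fixed-offset policy exist
for other designs.

## The synthetic embryo generator

`render_embryo` draws an elliptical embryo (default semi-axes 300 and
120 px, the aspect of a stage-5 embryo at typical magnification) with
~250 non-overlapping nuclear disks (radius 5 px, minimum center
separation 14 px, placed by rejection sampling), a diffuse body level in
the nuclear channel (out-of-focus light), and a reporter channel equal to
the requested pattern sampled at each pixel's normalized coordinates,
restricted to nuclear occupancy. Patterns are additive compositions of
Gaussian AP stripes, Gaussian DV bands, two-band lateral domains, a
ventral band (DV 0.85), a smooth posterior cap (AP > 0.8) and uniform
levels — shape choices of this package, since no underlying protocol
prescribes synthetic pattern shapes. Gaussian pixel noise and an
optional linear shading gradient are added; output is clipped to the
16-bit range. Ground truth records nucleus centers (pixel and
normalized), the mean pattern value over each nucleus's pixels, pattern
values at the region-definition points, and stripe centers with FWHM
widths ($2\sqrt{2\ln 2}\,\sigma$).

`simulate_nucleus_table` is the lighter-weight fixture for stripe
analyses: nucleus centers on a jittered grid over the normalized unit
square (default pitch 0.02 — one nucleus diameter — with near-maximal
jitter, because real blastoderm nuclei are irregularly packed and a
regular lattice aliases into extreme-distance statistics), intensities
equal to the pattern value plus i.i.d. Gaussian noise.

What the generators deliberately do not model: 3-D structure and optical
sectioning, the point-spread function, developmental stage variation,
membrane signal, staining heterogeneity between embryos, and curvature
of the blastoderm surface. Passing validation on synthetic data
therefore demonstrates correctness of the geometry, the estimators and
the statistics — not robustness to every artifact of real microscopy;
the manual-curation hooks exist for exactly that gap.

## Validation sizes and numerical choices

The test suite and the acceptance script run at fixed, documented sizes
chosen to make Monte-Carlo error small relative to every tolerance while
keeping a full run in tens of seconds: $10^4$ simulated lines for the
binomial calibration; 10 embryos per stripe position at noise sd 10% of
amplitude for profile recovery; 200 simulated lines of 20 profiles for
bootstrap coverage; $10^4$ null replicates for t-test size; $10^6$ bp of
background for scan calibration; 10 replicate fixtures for the stripe
rotation check. Seeds are fanned out from a single master seed through
`derive_seed` (a fixed integer hash, keeping children below $2^{31}$),
so each stage is independently reproducible and two runs of the full
pipeline under one seed are byte-identical.

Numerical conventions collected in one place: quantiles are type-7
(linear interpolation); Otsu thresholds are returned as the upper edge
of the selected histogram bin, so strict `>` comparisons classify
exactly; lattice scores round half-up; the flat-tail tolerance of the
profile normalization is $10^{-9}$; near-flat DV profiles (relative
range below $10^{-9}$) have no peaks, which is what makes an exactly
uniform field yield zero stripes.

## Known limitations

* Anterior/posterior and dorsal/ventral disambiguation is metadata-driven;
  there is no staining-based orientation inference.
* The stripe width is an extreme-value statistic by definition and
  inherits its sampling noise; consumers needing smoother width
  estimates should average over replicate embryos, as the validation
  does.
* The scanner's p-values are exact for the i.i.d. background model;
  dinucleotide or GC-stratified backgrounds are out of scope.
* Region placement is purely coordinate-based; co-stain-guided ROI
  placement (e.g. on a gene-expression border) is not implemented.
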