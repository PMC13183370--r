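---
title: "Methods: models, parameters, and design choices in vocalmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in vocalmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vocalmap)
```

`vocalmap` implements the quantitative side of a double-label ensemble-mapping
study of mouse courtship ultrasonic vocalization (USV): activity-tagged
tdTomato from a first courtship session, acute c-Fos from a second, counted in
region-of-interest (ROI) polygons across serial coronal sections, and related
to each animal's USV output. This vignette explains the models each stage
assumes, the tunable parameters and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. USV event segmentation

The detector reconstructs a spectral-bandwidth segmentation rule from its
published parameter values (analysis band 30–120 kHz, 50% energy fraction,
20 ms hold time, 1 ms post-filter); the vendor implementation itself is
proprietary, so this is a faithful reconstruction of the stated rules, not of
any vendor code.

**Spectrogram.** Hann-window STFT, default 512 samples with 75% overlap. At
the default 250 kHz sampling rate this gives a ~0.5 ms hop, which resolves the
1 ms post-filter, and a 488 Hz bin width, ample for tonal 30–120 kHz calls.
Magnitudes are in dB relative to full scale; bins outside the analysis band
are excluded from every downstream energy computation.

**Frame criterion.** A frame is call-positive iff

1. its in-band energy exceeds the recording's median in-band frame energy by
   `energy_threshold_db` (default 6 dB — a conventional robust floor; no
   threshold value is published, so this is a package choice, exposed as a
   parameter), and
2. the minimal contiguous frequency interval around the spectral peak holding
   50% of the frame's in-band energy is narrower than `tonality_khz`
   (default 20 kHz). This is the bandwidth half of the rule: tonal syllables
   concentrate energy in a narrow ridge; broadband noise does not.

The median-based floor makes the detector adaptive per recording without a
calibration file; since calls occupy a small fraction of a session, the median
tracks the noise floor.

**Events.** Positive runs separated by gaps of at most the 20 ms hold time are
merged (inter-syllable intervals longer than 20 ms define separate events);
merged runs shorter than the 1 ms post-filter are dropped. Event boundaries
are reported at frame centers, in seconds from recording start. Features per
event: peak frequency (argmax in-band bin) and its magnitude at three loci —
start frame, end frame, and maximum-amplitude frame.

One physical caveat, stated because it bounds what tests can show: the STFT
window (~2 ms) smears energy in time, so an isolated sub-millisecond burst in
*audio* occupies ~2 ms of frames and survives the post-filter. The
hold-time/post-filter rules are therefore exact at frame level (and tested on
constructed frame sequences), while audio-level tests use tones of realistic
duration (≥ 30 ms).

## 2. ROI quantification

Coordinates are µm with the origin at the image top-left and y increasing
ventrally; bregma coordinates are mm, positive anterior. Conventions, all
deterministic and documented:

- A cell belongs to an ROI iff its centroid is inside **or on** the polygon
  boundary.
- Hemispheres are pooled within a section before densities are computed
  (per-hemisphere handling is not specified in this kind of study; pooling is
  the conservative choice and the pooled count equals the per-hemisphere sum).
- Density = count / area (cells/mm²); per-mouse values are **unweighted**
  means of per-section densities, mirroring "averaged across all sections",
  not area-weighted means.
- Subregion boundaries along the bregma axis are half-open with the boundary
  going to the more rostral subregion (CPu: rostral/caudal/tail at +0.62 and
  −1.02 mm; PAG: rostral/caudal at −4.2 mm).

**Double-label matching.** "Double-labeled" is not defined geometrically in
the source analysis (QuPath reports it directly), so the package defines it:
one-to-one matching of tdTomato and c-Fos centroids, greedy by ascending
distance with deterministic index tie-breaks, accepting pairs within
`tol_um = 8` µm — about a nuclear radius at the 10 µm detection scale. The
matching is symmetric in its arguments, and on instances with ≤ 8 cells per
channel it is tested against an exhaustive maximum-matching oracle. Percentages
divide the double count by each channel's total; a zero denominator flags the
record and excludes it from group statistics. Double-label percentages are
computed per mouse and then averaged (the alternative — pooling cells across
mice first — is not what per-ROI averaging implies; the per-mouse route keeps
mice as the experimental unit).

**Optional blob detector.** `detect_cells_simple()` (synthetic images only)
chains morphological background subtraction (disk radius 10 µm), median
filtering (10 µm tdTomato / 8 µm c-Fos), global thresholding (20 / 10), and
connected components. Real data enter the pipeline as detection tables; this
helper exists so image-level tests have a closed loop.

## 3. Group statistics and heatmap normalization

Every comparison is routed by Shapiro–Wilk normality per group at α = 0.05
(the specific normality test is a package choice — the source analysis states
only that normality was tested): all groups normal → *t* family (independent
or paired); otherwise Mann–Whitney U between groups or Wilcoxon signed-rank
within subjects. The Mann–Whitney route uses exact enumeration for n ≤ 8
without ties and the tie-corrected normal approximation otherwise. Parametric
results are summarized as mean ± SEM, nonparametric as median ± IQR. Two
degenerate conventions: identical zero-variance groups give p = 1, and a fully
constant two-way design gives F = 0, p = 1. No multiple-testing correction is
applied across regions, matching the per-region reporting this analysis family
uses; a BH-adjusted column is a one-liner away via `p.adjust` if wanted.

**Outliers.** Flagged iff outside the Tukey fences [Q1 − 1.5·IQR,
Q3 + 1.5·IQR] (quartiles type 7). The exclusion criterion is not published —
heatmaps only show that outliers were excluded — so the package uses the
parameter-free fence rule and exposes the multiplier. Re-flagging the retained
set is idempotent for fence-stable inputs; on heavy-tailed draws it can
cascade, which is why the property test tolerates a minority of cascading
cases rather than asserting universal idempotence.

**z-scores.** z = (x − µ)/σ with **sample** SD (n − 1): at n = 7–9 the
n vs n − 1 distinction is material, and the population choice is not stated in
the source, so it is recorded here as a config-visible decision. Two
normalization modes: across mice within a region (compare animals per region)
and across regions within a mouse (compare regions per animal). Outliers are
excluded from µ and σ and masked in the output; σ = 0 yields z = 0 with a
warning flag so degenerate synthetic inputs stay renderable. Heatmap rows are
ordered by descending USV count within the exposed group (stable,
id-tie-broken), controls keeping their own block.

## 4. Correlation classification

Correlations use **exposed mice only**: controls emit no USVs, and their zeros
would manufacture correlation. Per region: product-moment r, R² = r², p from
the two-tailed t transform with df = n − 2, and a 95% Fisher-z CI. n is
carried explicitly per region and never assumed global. The decision table:

| condition | category |
|---|---|
| correlation p < α | usv-positive (r > 0) / usv-negative (r < 0) |
| else group p < α | social-interaction-related |
| else | unrelated |

with the strong flag iff |r| > 0.7 **and** R² > 0.5, and α = 0.05 two-tailed,
uncorrected. An undefined correlation (zero variance) can only reach the
social/unrelated branches and is noted.

**Anteroposterior profiling** bins section-level densities into 0.2 mm bregma
bins anchored at multiples of the width (per-coordinate plots don't state a
binning; 0.2 mm matches atlas-round coordinates), averages per mouse within a
bin, and correlates bin means with USV counts. Bins with fewer than 3
contributing mice are flagged insufficient. The peak is the largest-R² bin
among bins with p < 0.05; no significant bin means no peak. Note that with
~6 bins tested per region at α = 0.05, some family-wise false positives are
expected under the null — the package therefore calibrates the *per-bin*
type-I rate in its tests rather than asserting a near-zero family-wise rate.

## 5. Striatal quadrants and compartments

The caudoputamen (CP) is split into DM/DL/VM/VL quadrants from five anatomical
landmarks via six construction lines: Line 1 the tangent through the two
dorsal CP edge points; Line 2 through the anterior commissure parallel to
Line 1; Line 3 from the lateral CP boundary to the dorsal tip of the accumbens
shell (NAcs); Line 4 through the NAcs tip perpendicular to Line 1; and two
internal dividers through midpoints of those reference lines. Two points were
genuinely open and are resolved as follows:

- *Which extent defines a "midpoint"?* Reference lines are clipped to the CP
  hull and the chord midpoints are used — the only construction that is
  well-defined for arbitrary CP shapes.
- *Which divider separates what?* The divider through the Line-1/Line-2 chord
  midpoints connects a dorsal to a ventral point, i.e. runs dorsoventrally,
  and therefore separates **medial from lateral**; the divider through the
  Line-3/Line-4 midpoints runs mediolaterally and separates **dorsal from
  ventral**. Sides are identified from the landmarks themselves (medial = the
  NAcs side; dorsal = the side holding the Line-1 chord midpoint), which makes
  the construction rigid-motion equivariant and hemisphere-agnostic. Boundary
  ties go medial / dorsal. With a square CP and symmetric corner landmarks the
  construction yields four equal quadrants, which is the symmetry check the
  tests pin down.

Quadrant polygons are produced by half-plane clipping (Sutherland–Hodgman
against one edge), so quadrant areas sum to the CP area to floating-point
accuracy; the suite requires closure within 0.1% and Monte-Carlo agreement of
point-assignment fractions with area fractions within ±2%.

**Compartments.** Striosomes (MOR1⁺ patches) are consumed as polygons; matrix
is CP minus striosomes. A cell is striosomal iff inside or on any striosome
polygon. Compartment-within-quadrant areas come from clipping each striosome
by the quadrant's two half-planes (striosomes lie inside the CP by invariant,
so no CP clip is needed). Densities are normalized to the mean of the matching
compartment and quadrant in the no-exposure group. The quadrant analysis is
meant for rostral CP sections, selected with the bregma rules of the ROI
module.

## 6. The synthetic-data generator

The generator emulates the study design — two groups (default 9
female-exposure / 7 no-exposure), 30 µm coronal sections collected in 12
parallel series (360 µm within-series spacing, with a per-mouse random series
phase), two detection channels, and per-region ROI polygons — with known
ground truth. Its defaults are the study conditions where stated, and
package choices where not:

- **USV counts**: negative binomial (mean 120, dispersion 2) for exposed
  mice, 0 for controls. Per-animal call counts for this assay are not
  published; the overdispersed negative binomial reproduces the wide ordering
  range that USV-sorted heatmaps imply, and both parameters are configurable.
  These defaults are placeholders for a plausible cohort, not estimates of any
  particular dataset.
- **Density–USV coupling**: for exposed mouse *i*, expected density
  m_i = baseline × multiplier × exp(β·z_i + ε_i), with z_i the standardized
  USV count, ε lognormal mouse noise, and β solved numerically (grid +
  uniroot) so the *expected sample correlation* between realized density and
  USV count — including lognormal and Poisson counting variance — equals the
  requested coupling. This keeps densities positive and the correlation
  targetable; negative couplings use β < 0.
- **Mouse noise**: lognormal with CV 0.15. The coupling mechanism must be
  able to reach the strong correlations this kind of data reports (r ≈
  0.85–0.9 at n = 9); at CV ≳ 0.25 no β can achieve an expected sample r of
  0.9 against overdispersed counts, so the default sits where the documented
  couplings are attainable while between-mouse variability remains visible.
  When a requested coupling is unattainable for a realized USV design the
  generator warns and uses the best attainable β rather than failing.
- **Cell placement**: Poisson counts (mean = density × area), uniform within
  the ROI polygon. Reactivation: each tdTomato cell gains a c-Fos partner
  with probability `reactivation_prob`, displaced by a Gaussian jitter
  truncated at 2 µm — well inside the 8 µm matching tolerance, so truth is
  unambiguous — plus independent c-Fos-only cells keeping the channels'
  expected totals equal.
- **Audio**: linearly frequency-modulated tones over Gaussian white noise;
  aliasing is rejected. Tones are not biophysically realistic call acoustics
  (no harmonics, jumps, or amplitude modulation) — they exercise the
  segmentation rules, not call classification.
- **Striatal sections**: a convex CP outline (~5.2 mm², the scale of one
  hemisphere's dorsal CP cross-section), striosome disks packed to a target
  12% area fraction (the classic MOR1⁺ share), radius 120 µm, and
  per-quadrant compartment density folds. The default exposed-group folds are
  the published pattern (striosome 1.94/1.20/1.95/1.19 and matrix
  1.17/1.30/1.31/2.06 for DM/DL/VM/VL); controls sit at baseline 4.5
  cells/mm², the published control density scale. Disk-shaped striosomes are
  a deliberate simplification of the real labyrinthine geometry — adequate
  for area accounting and density ratios, not for morphology.

What passing tests on this generator do **not** show about real data:
registration error between sections, detection false positives/negatives,
anisotropic cell distributions within ROIs, section-to-section labeling
variability within a mouse, and real call acoustics are all absent. The
generator validates the *analysis*, not the imaging.

## 7. Problem sizes and numerical choices

The test suite and the acceptance script use 100-seed Monte-Carlo loops for
category recovery, anteroposterior localization, and the compartment pattern,
with cohorts of 4 regions × 16 mice × ~3–5 sections — sizes chosen so each
loop completes in a few minutes on one core while leaving the Monte-Carlo
standard error of the recovery rates at ~4–5 percentage points, small against
the 10–20 point margins being asserted. Geometry comparisons use 1e−6
relative tolerance (rigid motions), 0.1% (area closure), and ±2% (10,000-point
Monte-Carlo area fractions). Polygon clipping removes collinear duplicate
vertices at 1e−9 µm to keep downstream area sums exact.

## 8. Known limitations

- The striatal quadrant construction presumes a convex-ish CP outline; deeply
  concave outlines can make a divider chord ambiguous (the extreme
  intersections are used).
- The greedy double-label matching is not guaranteed maximum-cardinality in
  adversarial chain configurations (it is tested to agree with the exhaustive
  oracle at realistic cell spacings).
- The AP profile treats bins independently; no smoothing or spatial
  autocorrelation model is applied.
- Syllable-type classification and call-sequence syntax are out of scope; the
  detector reports call events and their features only.
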