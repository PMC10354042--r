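---
title: "Methods: grading, heterogeneity and IHC enrichment analysis of mouse LUAD slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grading, heterogeneity and IHC enrichment analysis of mouse LUAD slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`luadgrader` analyzes H&E whole-slide images of mouse lung adenocarcinoma
(LUAD): it normalizes staining, classifies every pixel into one of six
classes (normal alveoli, normal airway, and LUAD Grades 1-4), segments
tumors as connected mosaics of graded pixels, assigns each tumor an overall
grade, quantifies intratumor heterogeneity, and co-registers
immunohistochemistry (IHC) serial sections to test whether positive staining
concentrates in particular grade regions. The reference scan resolution is
0.5022 µm/pixel (20x); all areas are reported in µm² via this factor.

The pixel vocabulary is fixed: code 0 is Background (non-tissue), codes 1-2
the two normal classes, codes 3-6 the four grades. The grading network only
ever predicts the six tissue classes; Background arises exclusively from a
tissue mask (optical-density norm above 0.15), never from the classifier.
This choice keeps the classifier's simplex honest and makes the tissue
threshold an explicit, tunable parameter rather than a learned behavior.

# Stain normalization

H&E color is modelled in base-10 optical density (Beer-Lambert), where stain
concentrations combine linearly: `od = M c` with `M` the 3x2 matrix of unit
stain vectors. The stain matrix of a slide is estimated by the Macenko
procedure: pixels with OD norm above `beta_od_floor` (default 0.15 OD) are
projected onto the plane of the top two right-singular vectors of the OD
cloud, and the stain vectors are the `alpha` = 1st/99th percentile
directions of the projection angles. Normalization rescales each stain's
concentrations so its 99th percentile matches the reference profile and
re-composites with the reference vectors.

Two conventions deserve note. First, hematoxylin and eosin columns are
disambiguated by the *red*-channel OD component: hematoxylin is a blue dye
and absorbs red light most strongly, so its OD vector has the larger red
component. (Disambiguating on the blue component, which one might guess
first, is backwards for the standard H&E vectors and swaps the columns — a
mistake that the forward-synthesis test in the suite would catch as a ~22°
recovery error, exactly the angle between the H and E vectors.) Second,
percentile parameters `alpha` and `beta_od_floor` are explicit knobs with
Macenko's customary defaults; they are not derived from data.

# Patch library

Annotated slides are divided into 224x224-px patches (112x112 µm at
reference resolution) on a non-overlapping grid by default. Right/bottom
remainders are covered by reflection-padding the image; padded label pixels
are Background so they never contribute supervision. Each patch is grouped
by its dominant class — the modal non-Background label — with ties broken
toward the higher class code, i.e. the higher grade, so rare high-grade
patches are not diluted into lower bins.

Library assembly selects up to a per-class quota (default 6000) of patches
after slides have been assigned to train/validation/test splits
(60/20/20). Assignment is greedy on per-slide annotated pixel counts in
seeded random order, so the area split approximates the requested fractions
while patches from one slide never span two splits. Within each split,
class areas are then balanced by appending augmented copies (random
translation up to a quarter patch, shear up to 10°, rotation 90/180/270°
±10°; image bilinear, labels nearest-neighbor, reflection fill) of patches
whose dominant class is deficient. The balancing target is fixed at entry
— the largest class area in the split at that moment — because augmented
copies carry collateral pixels of other classes, and chasing a moving
maximum inflates the library without bound. Augmented copies that lose the
class of interest entirely (a transform can push it out of frame) are
discarded.

# The grading network

The network is a fully convolutional encoder-decoder implemented in
RcppArmadillo with explicit forward and backward passes (im2col
convolutions; every layer's gradient is verified against finite differences
in the test suite):

* a stride-2 stem convolution plus residual stages with ReLU-only
  pre-activation (no normalization layers; `base_width` channels doubling
  per stage, downsampling 2 per stage);
* one atrous 3x3 context layer followed by an atrous spatial pyramid
  pooling (ASPP) block: parallel dilated 3x3 branches whose outputs are
  concatenated and pooled by a 1x1 convolution in the next layer;
* a transposed-convolution decoder (kernel 4, stride 2 per step) back to
  input resolution and a 1x1 six-way softmax head.

Dilation is specified in the "skipped pixels" convention: rate r samples
every (r+1)-th pixel, so a 3x3 filter at rate 4 spans 11x11 pixels. The
default rates are 4 for the context layer and {2, 4, 8} for ASPP.

Training minimizes pixelwise cross-entropy (Background pixels ignored) with
Adam. The default recipe is 20 epochs, 128-patch minibatches, initial
learning rate 0.01; the rate is held fixed by default, with an optional
decay to a fraction of the initial rate over the final third of training.
Two numerical safeguards matter for an un-normalized network: global
gradient-norm clipping (default threshold 5) and a divergence abort on
non-finite loss. Minibatches that happen to contain only Background pixels
are skipped — they carry no gradient and would otherwise read as NaN loss.
The weights returned are those of the best-validation epoch.

Whole-slide inference tiles the image with stride half the patch size,
averages per-pixel class probabilities across overlapping tiles, takes the
argmax, and applies a 5x5 modal filter; this combination is the package's
concrete interpretation of "smoothing to suppress patch-edge artifacts".
With stride equal to the patch size and a 1x1 window the result equals
patchwise argmax exactly, which the suite asserts.

## The faithful and desk presets

The `faithful` preset mirrors ResNet18 stage widths (64/128/256/512, four
stages); it is buildable and differentiable but not exercised by the tests,
which would be pointless on one CPU. The `desk` preset (8 base channels,
two stages) is the unit of all quantitative checks. It has ~18k parameters
— the point of the benchmark is to test the pipeline's machinery, not
representational capacity.

# Synthetic fixtures: what they emulate and what they do not

Every quantitative claim in the tests is made on synthetic data from the
package's own generators:

* **Texture tiles.** Each class has a procedurally distinct texture built
  from eosin/hematoxylin concentration fields rendered through the standard
  H&E vectors: a sparse near-white eosin lattice for alveoli, concentric
  eosin rings for airway, and tumor textures whose eosin base and nuclear
  (hematoxylin) density/intensity increase strictly from Grade 1 to Grade 4.
  Classes are deliberately separable — a linear classifier on color
  histograms exceeds 95% accuracy, and mean hematoxylin OD is strictly
  monotone in grade; both are asserted.
* **Slides.** An elliptical "lung" of alveolar texture on a white
  background, airway rings (placed clear of tumors so both survive
  painting), and circular tumor blobs whose grade composition is laid out
  as angular sectors, realizing the requested fractions to within pixel
  discretization.
* **IHC patterns.** Nuclei are Poisson-placed over tissue with hard-core
  thinning (minimum separation about one nucleus diameter), each positive
  with probability `baseline x enrichment[class]`, and rendered through the
  same H-DAB vectors the detector deconvolves with — so the detection
  oracle is exact by construction.

What passing these tests shows: the plumbing — tiling, balancing,
differentiation, optimization, inference, segmentation, statistics,
registration — is correct, and the pipeline recovers planted ground truth
end to end. What it does not show: performance on real histology, where
class textures are not engineered to be separable, staining chemistry
varies, and annotation is noisy. The published real-cohort numbers (88%
patch accuracy, micro-F1 0.867, the 31% area excess, the cohort biology)
require the study's slides and weights and are explicitly out of desk
scope.

One realistic artifact is retained: most alveolar airspace is nearly white
and falls below the tissue OD threshold, exactly as real air space does, so
grade maps legitimately contain Background inside the lung. Slide-level
recovery is therefore evaluated over tissue pixels (those the classifier
actually grades).

# Tumor analytics

Tumors are connected components (default 8-connectivity; 4 available) of
the union of Grade 1-4 pixels: a tumor is a mosaic of grades, and normal
tissue severs components. Holes of normal tissue inside a tumor are not
filled and never enter the composition, which sums over graded pixels only.
Component ids are deterministic, ordered by topmost-then-leftmost pixel.

The overall grade is the highest grade occupying at least 10% of the
tumor's graded area, boundary inclusive (a tumor that is exactly 10%
Grade 4 is a Grade 4 tumor). Intratumor heterogeneity is the Shannon
diversity of the composition in natural log units: 0 for a monomorphic
tumor, ln 4 at the uniform maximum. Slide summaries report lung area (all
non-Background pixels), tumor burden (tumor area over lung area), and tumor
area both per overall grade and per raw pixel grade; the two attributions
conserve the same total, which is asserted.

# Agreement statistics

Rater agreement embeds both raters' category sets into one ordered list —
"Normal" sits below Grade 1, which is required to reproduce the published
kappas from the bundled 1958-tumor table — and computes Cohen's kappa,
plain and linear-weighted (`w_ij = 1 - |i-j|/(k-1)`). The standard error is
the asymptotic weighted-kappa form (Fleiss-Cohen-Everitt) with a normal
95% CI; the published CI is reproduced by this choice, though whether the
original was asymptotic or bootstrap is not stated, so the CI is documented
as approximate. F1 is area-based per class with micro-averaging over pooled
numerators and denominators; zero-denominator metrics are reported missing,
not zero, and excluded from the micro pool.

# IHC integration

Registration proceeds rigid → affine → local. The rigid stage is a
grayscale correlation search over rotation (±15°, coarse-to-fine) with full
translation recovery by normalized cross-correlation on 8x-downsampled
images. The affine stage refines the pull transform by at most 20 damped
numeric-gradient steps — deliberately few, to avoid deforming the section —
and rejects any refinement with a non-positive determinant. The local stage
re-matches each tumor's neighborhood by NCC within a 50-px radius; weak
correlations keep the global transform. Where the original workflow aligned
tumor regions manually, this stage is automated; per-tumor offsets can be
overridden from a CSV if manual alignment is preferred.

Cell detection color-deconvolves with the standard H-DAB vectors, finds
nuclei as local maxima of the smoothed hematoxylin+DAB density with a
minimum separation, and calls a cell positive when mean DAB density in a
3-px disk exceeds 0.2 OD. All thresholds are explicit parameters; the
defaults are calibrated only in the sense that they exactly invert the
package's own IHC renderer.

Projected cells inherit the grade-map class at their mapped position and
the containing tumor. Tumors below 2000 µm² or with fewer than 50 assigned
cells are excluded (both boundaries inclusive on the keep side, matching
the printed rule: *less than* 2000 µm² or *fewer than* 50 cells are
dropped). For each eligible tumor with at least one positive cell and at
least two grades present, the staining G-test compares observed positive
counts per grade region against expectations proportional to grade area
fractions: `G = 2 Σ O_i ln(O_i/E_i)` with `0 ln 0 := 0`, referred to a
chi-squared distribution with (grades present − 1) degrees of freedom;
significance is p < 0.01. Per-grade likelihood ratios `O_i/E_i` are
reported for localization. Cells landing on non-graded pixels inside the
tumor's bounding region do not enter the test — expectations derive from
graded-area fractions, so the observed counts are restricted the same way.
A tumor "counts as positively stained" when its positive-cell fraction is
at least 5% (an explicit knob; the original figure does not define it).

# Problem sizes and numerical choices

The quantitative suite and the acceptance script run at desk scale, chosen
as the package's own benchmark conditions: 6 synthetic slides of 480² px,
64-px patches with stride 32, a per-class quota of 40 before balancing,
and 50 epochs of Adam (minibatch 8, learning rate 0.003 decaying to 0.0009
in the final third, clip norm 5). Blob radii scale with the canvas
(9–14% of the side length): with downsample-by-4 features the decoder
resolves class boundaries to a band of a few pixels, so the benchmark
keeps the boundary-band area fraction small relative to blob interiors,
where recovery is essentially perfect (interior accuracy above 99%). Under
these conditions the desk network reaches ≥95% held-out pixel accuracy in
a few minutes on one CPU across seeds. The enrichment simulation uses one 600² px mixed-grade tumor
(≈42,000 µm², ≈210 cells at 5000 cells/mm²) with a 3x Grade-4 enrichment
over a 15% baseline, 20 seeds.

Other numerical choices: OD uses base 10 with I0 = 255 per channel;
concentrations are clipped nonnegative after least-squares unmixing;
dominant-class ties prefer the higher grade; modal-filter ties keep the
center pixel's value; the G-test is skipped (not zero-filled) when
untestable; compositions are validated to sum to 1 within 1e-6.

# Known limitations

* The synthetic world is chromatically separable by design; nothing here
  measures robustness to stain variation beyond Macenko normalization.
* The faithful-scale network is never trained in the tests; only its
  construction and differentiability are exercised.
* The kappa CI is asymptotic; small-count tables deserve a bootstrap.
* Local registration recovers translations only (no per-tumor rotation),
  matching the radius-bounded search the original manual step implies.
* The pipeline operates on single sections; serial-section tumor linking
  is out of scope.
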