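---
title: "Quantifying neuron and astrocyte arrangement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuron and astrocyte arrangement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyscope)
```

# The problem

Cultured cortical neurons and astrocytes rearrange themselves over weeks in
vitro: under some perturbations (for example depolarization of the resting
membrane potential) neurons coalesce from a dispersed monolayer into compact
multicellular assemblies, glial density shifts, and the web of soma-to-soma
contacts changes. Quantifying those changes from micrographs by hand does not
scale, so `assemblyscope` implements an automated pipeline with four
measurement stages, each usable on its own:

1. a **normalized clustering factor (NCF)** summarizing how aggregated the
   intensity in one fluorescence channel is, from its radial power spectrum;
2. **nucleus detection and classification** (DAPI band-pass detection,
   neuron/glia labels from green-vs-red channel dominance);
3. **area and density summaries** per cell class;
4. a **soma connectivity ratio** (total/isolated somas) for annotated
   phase-contrast time courses.

A synthetic-scene generator with exact ground truth backs every stage, since
micrograph analysis code can only be trusted as far as it can be tested.

# Image standardization

Micrographs acquired with different objectives and cameras are resampled
(bilinear) to 800 x 600 px at a fixed physical scale of 1.6 px/um, then
cropped to the centred 600 x 600 square (columns 101..700 of the
intermediate; rows untouched). The square, fixed-size raster is what the
Fourier stage requires; the fixed scale is what makes the 12-18 px nucleus
band and all area conversions (2.56 px^2/um^2) meaningful. Two choices are
ours where the recipe is silent:

* **Interpolation**: bilinear, the conventional default for intensity
  rasters. Constant images are exact fixed points.
* **Crop indexing**: the centred window is columns 101..700 (1-based,
  closed) of the 800-wide intermediate.
* **Idempotence**: inputs already at a canonical geometry skip the
  resampling — an 800 x 600 acquisition is only cropped and a 600 x 600
  raster passes through unchanged. Without the short-circuit a second
  application would re-stretch and re-crop, losing the image border.

`minmax_normalize()` maps each channel to [0, 1]. A constant raster has no
dynamic range; it normalizes to all zeros with a warning, so the fixed
detection thresholds downstream behave deterministically rather than
propagating NaN.

# The normalized clustering factor

For a standardized channel the 2D power spectral density is the squared
modulus of its discrete Fourier transform. The DC bin is excluded: it holds
the mean intensity squared, carries no arrangement information, and would
otherwise dominate every clumped spectrum. Each remaining Fourier pixel at
signed index $(k_1, k_2)$ belongs to the annulus with integer radius
$k = \mathrm{round}\sqrt{k_1^2 + k_2^2}$ (half away from zero); radii beyond
the Nyquist ring ($k > 300$, the spectrum corners) are discarded. The radial
curve records the mean PSD and the pixel count $c_k$ of each annulus at
spatial frequency $f_k = k/600\ \mathrm{px}^{-1}$.

The reduction to a scalar weights every annulus by its **total** power
$w_k = c_k \, P_k$ — equivalently, every 2D PSD pixel by its own power — and
averages the **log** frequency:

$$\bar{f}_{\log} = \frac{\sum_k w_k \ln f_k}{\sum_k w_k}, \qquad
\mathrm{NCF} = \frac{\ln f_{\max} - \bar{f}_{\log}}
                    {\ln f_{\max} - \ln f_{\min}},$$

clamped to $[0, 1]$, with $f_{\min} = 1/600$ and $f_{\max} = 1/2$. Three
anchor behaviours pin this construction:

* **White noise** has a flat spectrum; the power-weighted mean ln-frequency
  sits near the high end and the NCF is near 0. On the finite grid the value
  is about $1/(2 \ln 300) \approx 0.088$, approaching 0 only as the
  frequency range grows — the tests use a 0.1 band around 0 for this reason.
* **A single large Gaussian clump** ($\sigma$ = 100 px) concentrates
  essentially all off-DC power in the first few annuli; NCF $\approx$ 0.99.
* **A power-law spectrum** $P \propto f^{-2}$ (self-similar texture) has
  weight density $w \propto 1/f$, i.e. uniform in $\ln f$, so the continuum
  NCF is exactly $1/2$. On the discrete grid the harmonic sum over-weights
  the lowest frequencies and the value is 0.5478 at $k \le 300$ (0.5347 for
  the per-pixel lattice variant), converging to 0.5 logarithmically as the
  grid grows. The tests freeze the discrete value from an independent
  quadrature and separately assert the convergence; treating 0.5478 as a
  failure to hit 0.5 would be holding a finite grid to an asymptotic
  statement.

Weighting by annulus-total power on the ln-frequency axis is the only simple
construction we found that reproduces all three anchors; log-transforming the
*power* instead breaks both the midpoint anchor and the exact invariance of
the NCF under global intensity scaling (weights scale by $c^2$ and cancel).
The NCF is also invariant under 90-degree rotation and flips (radial
sampling is symmetric) — both invariances are asserted to 1e-10 in the
suite, along with Parseval's identity for the PSD.

# Nucleus detection and classification

The DAPI channel is min-max normalized, then band-passed with the
**difference of disk mean filters** (12- and 18-px diameters, the span of
nuclei at 1.6 px/um). Normalized mean filters — not sum filters — keep the
fixed 0.005 intensity threshold meaningful on the [0, 1] scale. All
convolutions use symmetric (mirror) boundary padding. Candidate pixels
exceed 0.005 in the filtered image; candidate components (8-connected) are
kept when they contain at least one pixel whose Prewitt gradient magnitude
(Euclidean combination of the two unnormalized 3 x 3 responses, computed on
the filtered image) exceeds 0.02. One record per surviving component, at its
unweighted sub-pixel centroid.

Interpretive choices, documented because the recipe's prose underdetermines
them:

* The intensity/gradient AND is applied at **component level**. A per-pixel
  AND keeps only blob rims (gradients vanish on interior plateaus), turning
  nuclei into annuli; component-level support matches the stated intent of
  locating nuclei by object centroids.
* Prewitt kernels are the unnormalized MATLAB-convention ones; magnitude is
  the Euclidean norm of the two responses.
* 8-connectivity; ties in the later channel-dominance rule give
  `unclassified`; no declumping — touching nuclei merge into one record
  (tested and documented, not hidden).

Classification reads the green (beta-III tubulin) and red (GFAP) intensities
at the pixel nearest each centroid: strictly greater green labels a neuron,
strictly greater red a glia.

Coverage masks mirror the published rule: a pixel is class-covered when its
class channel exceeds 10% of that channel's maximum *and* strictly exceeds
the other channel. "The image's maximum" is read per-channel, the only
reading that keeps each rule self-contained. Mean per-class cell area is
class mask area over class nucleus count (um^2 via 2.56 px^2/um^2); density
is count over the fixed 0.140625 mm^2 field. Zero-count classes yield
flagged `NA`s, never a division error.

# Connectivity

Somas are annotated manually (id, centroid, boundary radius, excluded flag,
plus optional dendrite links); automation of phase-contrast soma
segmentation is explicitly out of scope. A soma is **connected** when it has
a dendrite link or another non-excluded soma within 10 px
**boundary-to-boundary** (centroid distance minus both radii). The 10-px
rule derives from the shared phase-contrast halo of adjacent somas, which is
a property of their boundaries, so boundary distance is used rather than
centroid distance (which would conflate soma size with proximity).
Connectivity is pairwise, not transitive. The field metric is
total/isolated; 0 isolated somas flag the ratio undefined. Somas whose
centroid pixel is at or above 95% of the image maximum can be auto-excluded
as presumed dead cells ("at or above" so that a floor of 1.0 excludes
exactly-saturated pixels, the boundary case).

Group comparisons per time point report mean ratios, the percent change
`100 * (control - treated) / control`, and a two-sided two-sample Student's
t-test (pooled variance, matching the classical form; Welch available via
`welch = TRUE`). Zero-variance degenerate inputs are resolved explicitly
(equal means: p = 1; separated: p = 0, flagged) instead of erroring.

# The synthetic-scene generator

`generate_cell_scene()` emulates the features the analysis assumes and
nothing more: DAPI nuclei as **hard disks** of diameter uniform in
[12, 18] px at intensity 1 (hard disks, not Gaussian spots, so the band-pass
detector's assumptions hold exactly at zero noise); neuron/glia body
footprints as larger disks with the class channel strictly dominant (0.9 vs
0.2) inside; optional additive Gaussian noise, rectified at zero since
intensities are non-negative. Default footprints are ~600 um^2 (neurons) and
~1600 um^2 (glia), mid-range of the class means this kind of coculture
shows; counts default to 20 neurons + 10 glia per field. Arrangement is
either uniform-random (Poisson) or aggregated via a **Thomas (Neyman-Scott)
process**: uniform parents, Gaussian-scattered offspring, matching reported
assembly sizes of roughly 5-50 cells with the default 5 parents per field
and ~6 offspring each.

The default minimum centroid separation is 40 px, which makes default scenes
operationally non-overlapping in both senses that matter: the band-pass
supports of neighbouring nuclei stay disjoint (requires > 30 px), and no
centroid falls inside another class's body footprint (requires more than the
36-px glia body radius — closer pairs make the centroid pixel an exact
green/red tie and the record is, correctly by rule, unclassified). Clustered
scenes for spectral tests pass a small `min_sep_px` explicitly, since
overlap is immaterial to a power spectrum.

`generate_soma_scene()` places connected pairs either closer than 10 px
boundary gap or 12-20 px apart with an explicit dendrite link, all unrelated
somas separated by more than `min_sep_px` (> 10), so the ground-truth
isolated set is exactly the singles.

What the generator does **not** emulate: point-spread functions, shot noise,
uneven illumination, phase-contrast halo optics, nuclear texture, or
cell-shape irregularity. Tests passing on these scenes show the algorithms
implement their definitions correctly and are robust to moderate i.i.d.
noise; they do not certify performance on real micrographs.

# Numerical choices and degenerate inputs

* Annulus radii round half away from zero (R's `round()` rounds half to
  even, which would misbin `k + 0.5` radii).
* FFT-based filtering mirror-pads to at least the kernel half-width, widened
  to a 5-smooth size for speed; interior results are exact symmetric-padding
  results either way.
* All-zero spectra (constant images) raise a "degenerate spectrum" error in
  `ncf()`; constant rasters normalize to zeros with a warning.
* The NCF is clamped to [0, 1]; `f_bar_log` is reported unclamped.
* Seeds: every generator takes an explicit seed; equal seeds give identical
  scenes, and the pipeline writes its seed into the run manifest.

# Problem sizes used by the test suite

The suite's simulation scales were chosen to make the statistical assertions
stable while keeping a full run in the low minutes on one core: 20 seeds per
detection condition (30 nuclei per scene), 20 seeds per arm for the
point-process and NCF-monotonicity comparisons (Thomas cluster sigma 5, 15,
40 px), 10 seeds for spectral flatness, and 5 seeds for connectivity
recovery. The 8 x 8 brute-force DFT oracle is exhaustive at its grid size.

# Known limitations

* **Satellite detections under noise.** At additive noise sigma = 0.05 the
  dual-threshold detector keeps recall 1.0 but precision drops to about
  0.92 on default scenes: the band-pass response of a real nucleus has a
  faint halo ring ~15 px from the centroid, and single noise pixels there
  can clear the 0.005 intensity threshold while the halo's own slope
  supplies the 0.02 gradient, yielding 1-4 px spurious components. The
  published recipe specifies no minimum object size, so none is imposed;
  callers who need higher precision at this noise level can filter records
  on `area_px`, which cleanly separates the two populations (satellites are
  1-4 px, nuclei over 100 px).
* **Fused nuclei are counted once** (no declumping/watershed is specified).
* The NCF's white-noise and power-law anchors are asymptotic statements;
  finite-grid values (0.088 and 0.548) are documented above.
* Dendrite links are consumed from annotations; no tracing is attempted.
* Density and area absolute units assume the fixed 1.6 px/um scale is
  correct for the standardized data.
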