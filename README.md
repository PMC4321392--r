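# assemblyscope

Automated quantification of neuron and astrocyte arrangement in coculture
micrographs.

When cortical neurons are grown with astrocytes, perturbations such as
resting-membrane-potential depolarization change how the cells arrange
themselves: dispersed monolayers coalesce into multicellular assemblies,
glial density shifts, and soma-to-soma connectivity changes. This package
implements the image-analysis side of that biology for anyone who needs to
score such changes reproducibly from standard fluorescence and
phase-contrast micrographs:

* **Normalized clustering factor (NCF)** — a scalar in [0, 1] summarizing
  how aggregated the intensity in one fluorescence channel is. The channel
  is standardized to 600 x 600 px at 1.6 px/um, its 2D power spectral
  density (squared modulus of the DFT, DC excluded) is radially sampled into
  annuli at frequencies f_k = k/600 px^-1, and each annulus is weighted by
  its total power w_k = c_k P_k:

      f_bar = sum(w_k ln f_k) / sum(w_k)
      NCF   = (ln f_max - f_bar) / (ln f_max - ln f_min)

  White noise (spatially random cells) scores near 0, a power-law spectrum
  (self-similar texture) near 1/2, a single large clump near 1.
* **Nucleus detection and classification** — DAPI nuclei (12-18 px
  diameter) detected by a difference-of-disks band-pass (12/18-px mean
  filters), dual thresholds (intensity > 0.005, Prewitt gradient > 0.02 at
  component level), centroids of 8-connected components; each nucleus
  labeled neuron or glia by strict green (beta-III tubulin) vs red (GFAP)
  dominance at its centroid.
* **Area and density summaries** — per-class coverage masks (channel > 10%
  of its max and dominant), mean cell area (um^2), density (cells/mm^2),
  neuron/glia ratio.
* **Connectivity** — annotated phase-contrast somas classified isolated vs
  connected (dendrite link, or boundary-to-boundary gap < 10 px); field
  metric = total/isolated somas; group comparisons with Student's t-test.
* **Synthetic scenes** — Poisson or Thomas (Neyman-Scott) cell scenes and
  soma layouts with exact ground truth, plus white-noise / Gaussian-clump /
  power-law calibration fields.

See `vignettes/arrangement-quantification.Rmd` for the full model
description, parameter rationale, and known limitations.

## Worked example

```r
library(assemblyscope)

# A clustered (Thomas process) and a dispersed (Poisson) scene, same counts
clustered <- generate_cell_scene(scene_config(
  n_neurons = 20, n_glia = 10, arrangement = "thomas",
  thomas_params = list(n_parents = 5, cluster_sigma = 10),
  min_sep_px = 2, seed = 42
))
dispersed <- generate_cell_scene(scene_config(n_neurons = 20, n_glia = 10, seed = 42))

ncf_image(clustered$image$channels$neuron)
#> <ncf_result> NCF = 0.7414 (f_bar = 0.0072864 px^-1)
ncf_image(dispersed$image$channels$neuron)
#> <ncf_result> NCF = 0.6374 (f_bar = 0.013185 px^-1)
```

The aggregated scene scores a higher NCF than the uniform one at identical
cell counts — the quantity the factor exists to detect. (Scenes made of
compact cell bodies sit well above the white-noise floor of ~0.09 even when
dispersed; comparisons are made at matched content, as here.)

```r
recs <- detect_nuclei(dispersed$image$channels$nuclei)
recs <- classify_nuclei(recs, dispersed$image$channels$neuron,
                        dispersed$image$channels$astrocyte)
head(recs, 3)
#>   id      row      col area_px  label
#> 1  1 577.4036 78.22892     166 neuron
#> 2  2 437.2007 88.04762     294   glia
#> 3  3 534.1835 90.41367     278 neuron

summarize_area_density(
  recs,
  neuron_mask(dispersed$image$channels$neuron, dispersed$image$channels$astrocyte),
  astrocyte_mask(dispersed$image$channels$astrocyte, dispersed$image$channels$neuron)
)
#> <area_density_summary>
#>   neurons: 20 (142.2 cells/mm^2, mean area 556 um^2)
#>   glia:    10 (71.1 cells/mm^2, mean area 1462 um^2)
#>   neuron/glia ratio: 2
```

All 30 nuclei are recovered and labeled; the mean areas recover the
generator's ~600 um^2 neuron and ~1600 um^2 glia footprints from the
rendered pixels (slightly below nominal where footprints overlap).

```r
soma <- generate_soma_scene(40, 15, min_sep_px = 40, seed = 7)
connectivity_ratio(soma_status(soma$annotations))
#> <connectivity_result> 40 somas, 10 isolated, ratio = 4
```

`run_pipeline()` drives the same stages over a manifest of image files and
writes one CSV per stage plus a JSON run manifest.

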