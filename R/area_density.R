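#' Area-mask parameters
#'
#' @param fraction_of_max Per-channel intensity floor as a fraction of that
#'   channel's maximum (default 0.10: a pixel must exceed 10% of the
#'   channel's maximum intensity to count as covered).
#' @return A list of class `area_params`.
#' @export
area_params <- function(fraction_of_max = 0.10) {
  stopifnot(fraction_of_max > 0, fraction_of_max < 1)
  structure(list(fraction_of_max = fraction_of_max), class = "area_params")
}

#' Astrocyte- and neuron-covered pixel masks
#'
#' A pixel is astrocyte-covered when its red (GFAP) intensity exceeds 10% of
#' the red channel's maximum *and* strictly exceeds the green intensity at
#' that pixel; the neuron mask is the mirror image. The two dominance rules
#' are mutually exclusive, so the masks never overlap, and both are invariant
#' to rescaling the two channels by a common positive factor.
#'
#' @param red,green Co-registered channel rasters.
#' @param params An [area_params()].
#' @return Logical matrix.
#' @export
astrocyte_mask <- function(red, green, params = area_params()) {
  r <- as_raster(red)
  g <- as_raster(green)
  if (!all(dim(r) == dim(g))) {
    stop("red and green channels must be co-registered (same shape)")
  }
  if (max(r) == 0) {
    warning("all-zero red channel: astrocyte mask is empty")
    return(matrix(FALSE, nrow(r), ncol(r)))
  }
  (r > params$fraction_of_max * max(r)) & (r > g)
}

#' @rdname astrocyte_mask
#' @export
neuron_mask <- function(green, red, params = area_params()) {
  g <- as_raster(green)
  r <- as_raster(red)
  if (!all(dim(r) == dim(g))) {
    stop("red and green channels must be co-registered (same shape)")
  }
  if (max(g) == 0) {
    warning("all-zero green channel: neuron mask is empty")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  (g > params$fraction_of_max * max(g)) & (g > r)
}

#' Per-class area, density and count summary
#'
#' Combines the classified nucleus records with the coverage masks: mean cell
#' area per class is the class mask's pixel total divided by the class
#' nucleus count, converted to um^2 with the fixed scale
#' `(1.6 px/um)^2 = 2.56 px^2/um^2`; density is the class count divided by
#' the standardized field area (600 x 600 px = 0.140625 mm^2 at 1.6 px/um).
#' Classes with zero nuclei get `NA` mean area (and `NA` neuron/glia ratio
#' when glia are absent), with the affected quantities listed in `undefined`
#' rather than raising a division error.
#'
#' @param records Labeled records from [classify_nuclei()].
#' @param neuron_mask,astro_mask Logical masks from [neuron_mask()] /
#'   [astrocyte_mask()].
#' @param pixel_scale Pixels per micrometre (default 1.6).
#' @return A list of class `area_density_summary` with counts, pixel areas,
#'   mean areas (um^2), densities (cells/mm^2), `neuron_glia_ratio`, the
#'   field area in mm^2, and `undefined` (character vector of flagged
#'   quantities).
#' @export
summarize_area_density <- function(records, neuron_mask, astro_mask,
                                   pixel_scale = 1.6) {
  stopifnot(is.matrix(neuron_mask), is.matrix(astro_mask))
  n_neurons <- sum(records$label == "neuron")
  n_glia <- sum(records$label == "glia")
  neuron_area_px <- sum(neuron_mask)
  glia_area_px <- sum(astro_mask)
  px2_per_um2 <- pixel_scale^2
  field_mm2 <- prod(dim(neuron_mask)) / px2_per_um2 / 1e6
  undefined <- character()
  mean_neuron <- if (n_neurons > 0) {
    neuron_area_px / n_neurons / px2_per_um2
  } else {
    undefined <- c(undefined, "mean_neuron_area_um2")
    NA_real_
  }
  mean_glia <- if (n_glia > 0) {
    glia_area_px / n_glia / px2_per_um2
  } else {
    undefined <- c(undefined, "mean_glia_area_um2")
    NA_real_
  }
  ratio <- if (n_glia > 0) {
    n_neurons / n_glia
  } else {
    undefined <- c(undefined, "neuron_glia_ratio")
    NA_real_
  }
  structure(
    list(
      n_neurons = n_neurons,
      n_glia = n_glia,
      n_unclassified = sum(records$label == "unclassified"),
      neuron_area_px = neuron_area_px,
      glia_area_px = glia_area_px,
      mean_neuron_area_um2 = mean_neuron,
      mean_glia_area_um2 = mean_glia,
      neuron_density_mm2 = n_neurons / field_mm2,
      glia_density_mm2 = n_glia / field_mm2,
      neuron_glia_ratio = ratio,
      field_area_mm2 = field_mm2,
      undefined = undefined
    ),
    class = "area_density_summary"
  )
}

#' @export
print.area_density_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<area_density_summary>\n",
      "  neurons: %d (%.1f cells/mm^2, mean area %s um^2)\n",
      "  glia:    %d (%.1f cells/mm^2, mean area %s um^2)\n",
      "  neuron/glia ratio: %s\n"
    ),
    x$n_neurons, x$neuron_density_mm2, format(x$mean_neuron_area_um2, digits = 4),
    x$n_glia, x$glia_density_mm2, format(x$mean_glia_area_um2, digits = 4),
    format(x$neuron_glia_ratio, digits = 4)
  ))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
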