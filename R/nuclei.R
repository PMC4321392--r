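#' Nucleus detection parameters
#'
#' Defaults follow the published recipe: DAPI-stained nuclei span 12-18 px in
#' diameter at the canonical 1.6 px/um scale, so the band-pass is the
#' difference of 12- and 18-px-diameter disk mean filters; candidate pixels
#' must exceed 0.005 in the filtered image and their object must be supported
#' by a Prewitt gradient above 0.02.
#'
#' @param disk_small_px,disk_large_px Disk diameters (px) of the two mean
#'   filters; small < large.
#' @param intensity_threshold Threshold on the band-passed image.
#' @param gradient_threshold Threshold on the Prewitt gradient magnitude of
#'   the band-passed image.
#' @return A list of class `nuclei_params`.
#' @export
nuclei_params <- function(disk_small_px = 12, disk_large_px = 18,
                          intensity_threshold = 0.005,
                          gradient_threshold = 0.02) {
  stopifnot(
    disk_small_px < disk_large_px,
    intensity_threshold > 0, gradient_threshold > 0
  )
  structure(
    list(
      disk_small_px = disk_small_px, disk_large_px = disk_large_px,
      intensity_threshold = intensity_threshold,
      gradient_threshold = gradient_threshold
    ),
    class = "nuclei_params"
  )
}

#' Difference-of-disks band-pass filter for nuclei
#'
#' `mean-filter(x, disk 12) - mean-filter(x, disk 18)`, with symmetric
#' (mirror) boundary padding. The disks are normalized mean filters so the
#' fixed 0.005 threshold keeps its meaning on \[0, 1\]-normalized input; the
#' difference responds maximally to blobs in the 12-18 px diameter band and
#' is identically zero on constant images.
#'
#' @param dapi_norm Numeric matrix normalized to \[0, 1\].
#' @param params A [nuclei_params()].
#' @return Filtered matrix, same size as the input.
#' @export
bandpass_nuclei <- function(dapi_norm, params = nuclei_params()) {
  px <- as_raster(dapi_norm)
  filter_same(px, disk_kernel(params$disk_small_px)) -
    filter_same(px, disk_kernel(params$disk_large_px))
}

#' Prewitt gradient magnitude
#'
#' Euclidean magnitude of the horizontal and vertical Prewitt responses
#' (unnormalized 3 x 3 kernels, symmetric boundary padding).
#'
#' @param x Numeric matrix.
#' @return Matrix of gradient magnitudes, same size as the input.
#' @export
prewitt_magnitude <- function(x) {
  px <- as_raster(x)
  kx <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3L, 3L)
  gx <- filter_same(px, kx)
  gy <- filter_same(px, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Detect DAPI-stained nuclei
#'
#' Pipeline: min-max normalize the raw DAPI channel, band-pass with the
#' difference of disks, threshold the filtered image at
#' `intensity_threshold`, and keep the 8-connected candidate components that
#' contain at least one pixel whose Prewitt gradient (of the filtered image)
#' exceeds `gradient_threshold`. Each surviving component yields one record
#' with its unweighted sub-pixel centroid. The edge condition is applied at
#' component level: a per-pixel AND would hollow blob interiors into annuli,
#' because strong gradients live on blob rims, not at their centres. Touching
#' nuclei fuse into a single component (no declumping is attempted).
#'
#' @param dapi Raw DAPI channel (`channel_image` or matrix); normalization is
#'   applied internally.
#' @param params A [nuclei_params()].
#' @return `data.frame` with columns `id`, `row`, `col` (sub-pixel centroid),
#'   `area_px`, `label` (all `"unclassified"`); zero rows on blank input.
#' @export
detect_nuclei <- function(dapi, params = nuclei_params()) {
  px <- as_raster(dapi)
  empty <- data.frame(
    id = integer(), row = numeric(), col = numeric(),
    area_px = integer(), label = character(),
    stringsAsFactors = FALSE
  )
  if (min(px) == max(px)) {
    return(empty) # blank field: nothing to normalize or detect
  }
  filt <- bandpass_nuclei(minmax_normalize(px), params)
  cand <- filt > params$intensity_threshold
  if (!any(cand)) {
    return(empty)
  }
  grad <- prewitt_magnitude(filt)
  lab <- label_components(cand)
  keep <- sort(unique(lab[cand & grad > params$gradient_threshold]))
  if (length(keep) == 0L) {
    return(empty)
  }
  sel <- lab %in% keep
  grp <- factor(lab[sel], levels = keep)
  data.frame(
    id = seq_along(keep),
    row = as.numeric(tapply(row(lab)[sel], grp, mean)),
    col = as.numeric(tapply(col(lab)[sel], grp, mean)),
    area_px = as.integer(table(grp)),
    label = "unclassified",
    stringsAsFactors = FALSE
  )
}

#' Classify nuclei as neurons or glia by channel dominance
#'
#' At the pixel nearest each nucleus centroid, a strictly greater green
#' (beta-III tubulin) than red (GFAP) intensity labels the cell a neuron, the
#' reverse a glia; exact ties stay `"unclassified"` (the dominance rule is
#' defined only for strict inequalities).
#'
#' @param records Detection table from [detect_nuclei()].
#' @param green,red Co-registered neuron/astrocyte channels, same shape as
#'   the DAPI raster the records came from.
#' @return The records with `label` filled in.
#' @export
classify_nuclei <- function(records, green, red) {
  g <- as_raster(green)
  r <- as_raster(red)
  if (!all(dim(g) == dim(r))) {
    stop("green and red channels must be co-registered (same shape)")
  }
  if (nrow(records) == 0L) {
    return(records)
  }
  ri <- pmin(pmax(as.integer(round_half_away(records$row)), 1L), nrow(g))
  ci <- pmin(pmax(as.integer(round_half_away(records$col)), 1L), ncol(g))
  gv <- g[cbind(ri, ci)]
  rv <- r[cbind(ri, ci)]
  records$label <- ifelse(gv > rv, "neuron", ifelse(rv > gv, "glia", "unclassified"))
  records
}
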