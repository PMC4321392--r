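#' Uniform white-noise calibration field
#'
#' I.i.d. uniform\[0,1\] pixels; the spatially random reference texture whose
#' NCF sits at the bottom of the scale.
#'
#' @param shape `c(rows, cols)` in px.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric matrix.
#' @export
generate_white_noise <- function(shape = c(600L, 600L), seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(prod(shape)), shape[1], shape[2])
}

#' Single Gaussian clump calibration field
#'
#' `exp(-d^2 / (2 sigma^2))` with `d` the distance to `center`; the maximally
#' aggregated reference texture (one large clump, NCF near the top of the
#' scale). The default centre is the pixel `round(shape/2)` so the maximum
#' value 1 is attained exactly.
#'
#' @param shape `c(rows, cols)` in px.
#' @param sigma_px Clump standard deviation in px.
#' @param center `c(row, col)` of the clump centre.
#' @return Numeric matrix with maximum 1 at `center`.
#' @export
generate_gaussian_clump <- function(shape = c(600L, 600L), sigma_px = 100,
                                    center = round(shape / 2)) {
  stopifnot(sigma_px > 0, length(shape) == 2, length(center) == 2)
  d2 <- outer(
    (seq_len(shape[1]) - center[1])^2,
    (seq_len(shape[2]) - center[2])^2, "+"
  )
  exp(-d2 / (2 * sigma_px^2))
}

#' Power-law (self-similar) random field
#'
#' Spectral synthesis: a white-noise field is transformed to Fourier space,
#' its amplitudes are shaped proportional to `f^(-beta/2)` (so the 2D PSD is
#' proportional to `f^-beta` in expectation) with the random phases kept, the
#' DC component is zeroed, and the field is transformed back. `beta = 2`
#' mimics a self-similar fractal texture; `beta = 0` degenerates to (mean
#' removed) white noise.
#'
#' @param shape `c(rows, cols)` in px.
#' @param exponent_beta Spectral slope `beta >= 0` of the target PSD.
#' @param seed Optional RNG seed.
#' @return Real-valued matrix with mean 0.
#' @export
generate_power_law_field <- function(shape = c(600L, 600L), exponent_beta = 2,
                                     seed = NULL) {
  stopifnot(exponent_beta >= 0, length(shape) == 2, all(shape >= 2))
  if (!is.null(seed)) set.seed(seed)
  n1 <- shape[1]
  n2 <- shape[2]
  wn <- matrix(stats::rnorm(n1 * n2), n1, n2)
  s1 <- (function(i, n) ifelse(i > n / 2, i - n, i) / n)(0:(n1 - 1), n1)
  s2 <- (function(i, n) ifelse(i > n / 2, i - n, i) / n)(0:(n2 - 1), n2)
  f <- sqrt(outer(s1^2, s2^2, "+"))
  amp <- f
  amp[1L, 1L] <- 1 # placeholder, zeroed below
  amp <- amp^(-exponent_beta / 2)
  amp[1L, 1L] <- 0
  Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (n1 * n2)
}

#' Synthetic scene configuration
#'
#' Parameters of a ground-truthed coculture scene. Defaults emulate the kind
#' of field the analysis was designed for: a 600 x 600 standardized image,
#' nuclei 12-18 px in diameter, neurons with ~600 um^2 somata and glia with
#' ~1600 um^2 footprints (mid-range of the reported class means at
#' 2.56 px^2/um^2), a 2:1 neuron:glia count mix, and either uniform-random
#' (`poisson`) or aggregated (`thomas`, Neyman-Scott cluster process)
#' placement. `min_sep_px = 40` keeps scenes operationally non-overlapping:
#' the band-pass supports of neighbouring nuclei stay disjoint (needs >= 30
#' px) and no centroid falls inside another cell's body footprint (needs more
#' than the 36-px glia body radius), so noiseless detection *and*
#' classification are exact. Pass a smaller value for strongly clustered
#' spectra where overlap is acceptable.
#'
#' @param image_shape `c(rows, cols)` px.
#' @param n_neurons,n_glia Cell counts per class.
#' @param nucleus_diameter_range Closed interval (px) nucleus diameters are
#'   drawn from.
#' @param neuron_body_area_px,glia_body_area_px Mean footprint areas (px^2).
#' @param arrangement `"poisson"` (uniform random) or `"thomas"` (clustered).
#' @param thomas_params List with `n_parents` and `cluster_sigma` (px,
#'   Gaussian scatter of offspring around parents).
#' @param noise_sigma Additive Gaussian intensity noise s.d. (channels are
#'   clamped at 0 afterwards).
#' @param min_sep_px Minimum centroid separation enforced by rejection
#'   sampling.
#' @param seed Optional RNG seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(600L, 600L),
                         n_neurons = 20L, n_glia = 10L,
                         nucleus_diameter_range = c(12, 18),
                         neuron_body_area_px = 1536,
                         glia_body_area_px = 4096,
                         arrangement = c("poisson", "thomas"),
                         thomas_params = list(n_parents = 5L, cluster_sigma = 15),
                         noise_sigma = 0,
                         min_sep_px = 40,
                         seed = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot(
    n_neurons >= 0, n_glia >= 0,
    length(nucleus_diameter_range) == 2,
    nucleus_diameter_range[1] >= 1,
    nucleus_diameter_range[2] < min(image_shape),
    diff(nucleus_diameter_range) >= 0,
    neuron_body_area_px > 0, glia_body_area_px > 0,
    noise_sigma >= 0, min_sep_px >= 0
  )
  if (arrangement == "thomas") {
    stopifnot(
      !is.null(thomas_params$cluster_sigma), thomas_params$cluster_sigma > 0,
      !is.null(thomas_params$n_parents), thomas_params$n_parents >= 1
    )
  }
  structure(
    list(
      image_shape = image_shape, n_neurons = n_neurons, n_glia = n_glia,
      nucleus_diameter_range = nucleus_diameter_range,
      neuron_body_area_px = neuron_body_area_px,
      glia_body_area_px = glia_body_area_px,
      arrangement = arrangement, thomas_params = thomas_params,
      noise_sigma = noise_sigma, min_sep_px = min_sep_px, seed = seed
    ),
    class = "scene_config"
  )
}

# Rejection-sample n centroids with pairwise separation >= min_sep inside
# [margin, shape - margin]; Thomas placement draws a uniform parent set first
# and scatters offspring around random parents.
place_centroids <- function(config) {
  n <- config$n_neurons + config$n_glia
  if (n == 0L) {
    return(matrix(numeric(), 0L, 2L))
  }
  shp <- config$image_shape
  margin <- max(config$nucleus_diameter_range) / 2 + 1
  lo <- c(margin, margin)
  hi <- shp - margin
  stopifnot(all(hi > lo))
  parents <- NULL
  if (config$arrangement == "thomas") {
    parents <- cbind(
      stats::runif(config$thomas_params$n_parents, lo[1], hi[1]),
      stats::runif(config$thomas_params$n_parents, lo[2], hi[2])
    )
  }
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * (n + 1L)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(
        "unable to place ", n, " centroids with min_sep_px = ",
        config$min_sep_px, " in a ", shp[1], " x ", shp[2],
        " field: requested packing is infeasible"
      )
    }
    cand <- if (is.null(parents)) {
      c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    } else {
      p <- parents[sample.int(nrow(parents), 1L), ]
      p + stats::rnorm(2L, sd = config$thomas_params$cluster_sigma)
    }
    if (any(cand < lo) || any(cand > hi)) next
    if (placed > 0L && config$min_sep_px > 0) {
      d2 <- (pts[seq_len(placed), 1L] - cand[1])^2 +
        (pts[seq_len(placed), 2L] - cand[2])^2
      if (min(d2) < config$min_sep_px^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  pts
}

# Paint value onto img over a disk (max-composited, so overlaps don't add).
paint_disk <- function(img, r0, c0, radius, value) {
  nr <- nrow(img)
  nc <- ncol(img)
  rs <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  m <- outer((rs - r0)^2, (cs - c0)^2, "+") <= radius^2
  img[rs, cs] <- pmax(img[rs, cs], value * m)
  img
}

#' Generate a ground-truthed synthetic coculture scene
#'
#' Renders a three-channel scene from a [scene_config()]: the DAPI channel
#' holds intensity-1 hard disks (diameters drawn uniformly from the
#' configured range) at the sampled centroids; the neuron (green) and
#' astrocyte (red) channels hold larger cell-body footprints around the same
#' centroids with the class's own channel strictly dominant (0.9 vs 0.2)
#' inside the footprint. Optional i.i.d. Gaussian noise is added per channel
#' and clamped at zero. Ground truth (centroids, labels, per-class dominant
#' pixel areas measured before noise) is returned exactly.
#'
#' @param config A [scene_config()].
#' @return List with `image` (a [std_image()] with channels `nuclei`,
#'   `neuron`, `astrocyte`) and `truth` (list with `centroids` data.frame
#'   `id,row,col,class,diameter_px`, `per_class_pixel_area`, and the config).
#' @export
generate_cell_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  shp <- config$image_shape
  pts <- place_centroids(config)
  n <- nrow(pts)
  classes <- if (n > 0) {
    sample(rep(c("neuron", "glia"), c(config$n_neurons, config$n_glia)))
  } else {
    character()
  }
  diam <- if (n > 0) {
    stats::runif(
      n, config$nucleus_diameter_range[1],
      config$nucleus_diameter_range[2]
    )
  } else {
    numeric()
  }
  dapi <- matrix(0, shp[1], shp[2])
  green <- matrix(0, shp[1], shp[2])
  red <- matrix(0, shp[1], shp[2])
  r_neuron <- sqrt(config$neuron_body_area_px / pi)
  r_glia <- sqrt(config$glia_body_area_px / pi)
  for (i in seq_len(n)) {
    dapi <- paint_disk(dapi, pts[i, 1], pts[i, 2], diam[i] / 2, 1)
    if (classes[i] == "neuron") {
      green <- paint_disk(green, pts[i, 1], pts[i, 2], r_neuron, 0.9)
      red <- paint_disk(red, pts[i, 1], pts[i, 2], r_neuron, 0.2)
    } else {
      red <- paint_disk(red, pts[i, 1], pts[i, 2], r_glia, 0.9)
      green <- paint_disk(green, pts[i, 1], pts[i, 2], r_glia, 0.2)
    }
  }
  # dominant-coverage areas on the noiseless channels (= painted footprints)
  gmax <- max(green)
  rmax <- max(red)
  area_neuron <- if (gmax > 0) sum(green > red & green > 0.1 * gmax) else 0L
  area_glia <- if (rmax > 0) sum(red > green & red > 0.1 * rmax) else 0L
  if (config$noise_sigma > 0) {
    addn <- function(m) {
      pmax(m + matrix(stats::rnorm(length(m), sd = config$noise_sigma), nrow(m)), 0)
    }
    dapi <- addn(dapi)
    green <- addn(green)
    red <- addn(red)
  }
  truth <- list(
    centroids = data.frame(
      id = seq_len(n),
      row = pts[, 1], col = pts[, 2],
      class = classes, diameter_px = diam,
      stringsAsFactors = FALSE
    ),
    per_class_pixel_area = c(neuron = area_neuron, glia = area_glia),
    config = config
  )
  list(
    image = std_image(
      list(nuclei = dapi, neuron = green, astrocyte = red),
      pixel_scale = 1.6
    ),
    truth = truth
  )
}

#' Generate a ground-truthed soma annotation scene
#'
#' Places `n_somas` somas of fixed radius so that each of the
#' `n_connected_pairs` designated pairs is connected either by proximity
#' (boundary gap drawn below 10 px) or by a listed dendrite link (boundary
#' gap 12-20 px, above the proximity threshold), while all somas from
#' different pairs/singles keep boundary gaps well above `min_sep_px`.
#' Optionally adds `n_dead` somas pre-flagged as excluded (dead cells).
#' Ground truth: the isolated set is exactly the non-dead singles.
#'
#' @param n_somas Number of live somas (`2 * n_connected_pairs <= n_somas`).
#' @param n_connected_pairs Number of connected pairs.
#' @param min_sep_px Minimum boundary gap between unrelated somas; must
#'   exceed the 10-px proximity threshold.
#' @param seed Optional RNG seed.
#' @param shape Field size `c(rows, cols)` px.
#' @param soma_radius Soma boundary radius (px).
#' @param link_fraction Probability that a connected pair is realised as a
#'   distant dendrite-linked pair rather than a proximity pair.
#' @param n_dead Somas flagged excluded (not counted in the ground truth).
#' @return List with `annotations` (a [soma_set()]) and `truth` (list with
#'   `isolated_ids`, `pair_ids`, `dead_ids`).
#' @export
generate_soma_scene <- function(n_somas, n_connected_pairs, min_sep_px = 40,
                                seed = NULL, shape = c(600L, 600L),
                                soma_radius = 6, link_fraction = 0.5,
                                n_dead = 0L) {
  stopifnot(
    n_somas >= 1, n_connected_pairs >= 0,
    2 * n_connected_pairs <= n_somas,
    min_sep_px > 10, soma_radius > 0,
    link_fraction >= 0, link_fraction <= 1, n_dead >= 0
  )
  if (!is.null(seed)) set.seed(seed)
  n_singles <- n_somas - 2L * n_connected_pairs
  n_sites <- n_connected_pairs + n_singles + n_dead
  # sites far enough apart that somas from different sites can never fall
  # within min_sep of each other (pair partner offset <= 2r + 20)
  site_sep <- min_sep_px + 4 * soma_radius + 24
  margin <- 2 * soma_radius + 30
  lo <- c(margin, margin)
  hi <- shape - margin
  stopifnot(all(hi > lo))
  sites <- matrix(NA_real_, n_sites, 2L)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * (n_sites + 1L)
  while (placed < n_sites) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(
        "unable to place ", n_sites, " soma sites ", site_sep,
        " px apart in a ", shape[1], " x ", shape[2],
        " field: requested packing is infeasible"
      )
    }
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (placed > 0L) {
      d2 <- (sites[seq_len(placed), 1] - cand[1])^2 +
        (sites[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < site_sep^2) next
    }
    placed <- placed + 1L
    sites[placed, ] <- cand
  }
  somas <- data.frame(
    id = integer(), row = numeric(), col = numeric(),
    radius = numeric(), excluded = logical()
  )
  links <- data.frame(id_a = integer(), id_b = integer())
  next_id <- 1L
  add_soma <- function(rc, excluded = FALSE) {
    somas[nrow(somas) + 1L, ] <<- list(next_id, rc[1], rc[2], soma_radius, excluded)
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  pair_ids <- list()
  for (i in seq_len(n_connected_pairs)) {
    a <- add_soma(sites[i, ])
    theta <- stats::runif(1, 0, 2 * pi)
    by_link <- stats::runif(1) < link_fraction
    gap <- if (by_link) stats::runif(1, 12, 20) else stats::runif(1, 2, 8)
    offset <- (2 * soma_radius + gap) * c(cos(theta), sin(theta))
    b <- add_soma(sites[i, ] + offset)
    if (by_link) {
      links[nrow(links) + 1L, ] <- list(a, b)
    }
    pair_ids[[i]] <- c(a, b)
  }
  isolated_ids <- integer()
  for (i in seq_len(n_singles)) {
    isolated_ids <- c(isolated_ids, add_soma(sites[n_connected_pairs + i, ]))
  }
  dead_ids <- integer()
  for (i in seq_len(n_dead)) {
    dead_ids <- c(
      dead_ids,
      add_soma(sites[n_connected_pairs + n_singles + i, ], excluded = TRUE)
    )
  }
  list(
    annotations = soma_set(somas, links),
    truth = list(
      isolated_ids = isolated_ids,
      pair_ids = pair_ids,
      dead_ids = dead_ids
    )
  )
}

#' Write a synthetic scene to disk
#'
#' Writes one 16-bit grayscale TIFF per channel (intensities rescaled to the
#' \[0, 1\] range tiff expects; the NCF and the detection thresholds are
#' invariant to this rescale because both pipelines min-max normalize on
#' load) plus a ground-truth CSV (`id,row,col,class,diameter_px`).
#'
#' @param scene Output of [generate_cell_scene()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(scene$image$channels)) {
    px <- scene$image$channels[[nm]]
    top <- max(px, 1)
    path <- file.path(dir, paste0(prefix, "_", nm, ".tif"))
    tiff::writeTIFF(px / top, path, bits.per.sample = 16L)
    paths[nm] <- path
  }
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(scene$truth$centroids, truth_path, row.names = FALSE)
  paths["truth"] <- truth_path
  invisible(paths)
}
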