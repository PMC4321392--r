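# Internal numerical helpers shared across modules.

# round() in R rounds half to even; annulus binning and centroid->pixel lookup
# need half-away-from-zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Mirror-pad a matrix by p pixels on every side (edge pixel duplicated,
# MATLAB 'symmetric' convention).
pad_symmetric <- function(m, p) {
  nr <- nrow(m)
  nc <- ncol(m)
  stopifnot(p >= 1, p <= nr, p <= nc)
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci, drop = FALSE]
}

# Same-size linear filtering with symmetric boundary handling. EBImage::filter2
# only offers circular/replicate boundaries, so the image is mirror-padded by
# at least the kernel half-width first; the interior of the padded result is
# then exact. Padding is widened to reach a 5-smooth size so filter2's FFT
# stays fast (any pad >= the half-width leaves the interior unchanged).
filter_same <- function(m, kernel) {
  kd <- dim(kernel)
  stopifnot(all(kd %% 2L == 1L))
  p <- max((kd - 1L) %/% 2L)
  grow <- function(n) {
    target <- stats::nextn(n + 2L * p)
    if ((target - n) %% 2L == 1L) target <- stats::nextn(target + 1L)
    (target - n) %/% 2L
  }
  q <- max(grow(nrow(m)), grow(ncol(m)), p)
  q <- min(q, nrow(m), ncol(m)) # pad_symmetric cannot mirror past the image
  pm <- pad_symmetric(m, q)
  out <- EBImage::filter2(pm, kernel, boundary = "circular")
  out[(q + 1L):(q + nrow(m)), (q + 1L):(q + ncol(m)), drop = FALSE]
}

# Normalized mean-filter kernel over a disk of the given diameter (px).
# Even diameters get an odd support grid (2*floor(d/2)+1) so the kernel has a
# well-defined centre pixel; a pixel belongs to the disk when its centre lies
# within d/2 of the kernel centre.
disk_kernel <- function(diameter) {
  stopifnot(diameter >= 1)
  r <- diameter / 2
  s <- 2L * as.integer(floor(r)) + 1L
  ax <- seq_len(s) - (s + 1) / 2
  k <- outer(ax^2, ax^2, function(a, b) as.numeric(sqrt(a + b) <= r))
  k / sum(k)
}

# 8-connected component labelling of a logical matrix. EBImage::bwlabel is
# 4-connected, so foreground pixels are joined into an 8-neighbour graph and
# labelled via igraph's connected components. Returns an integer matrix with
# 0 background and labels 1..n_components.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(lab)
  }
  lab[idx] <- seq_along(idx)
  nr <- nrow(mask)
  nc <- ncol(mask)
  pairs <- function(a, b) {
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  e <- rbind(
    pairs(lab[-nr, , drop = FALSE], lab[-1, , drop = FALSE]),
    pairs(lab[, -nc, drop = FALSE], lab[, -1, drop = FALSE]),
    pairs(lab[-nr, -nc, drop = FALSE], lab[-1, -1, drop = FALSE]),
    pairs(lab[-nr, -1, drop = FALSE], lab[-1, -nc, drop = FALSE])
  )
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(e)))
  }
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Extract a plain numeric matrix from a channel_image or matrix argument.
as_raster <- function(x) {
  if (inherits(x, "channel_image")) {
    return(x$pixels)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  x
}
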