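# Shared fixtures and oracles for the suite. Everything is generated in code;
# no binary fixtures are stored.

# Greedy one-to-one matching of detections to ground-truth centroids within
# `radius` px. Returns counts used for precision/recall.
match_detections <- function(records, truth, radius = 6) {
  n_det <- nrow(records)
  n_true <- nrow(truth)
  if (n_det == 0 || n_true == 0) {
    return(list(tp = 0L, fp = n_det, fn = n_true, matched_label = character(0)))
  }
  d <- sqrt(
    outer(records$row, truth$row, "-")^2 + outer(records$col, truth$col, "-")^2
  )
  used_det <- rep(FALSE, n_det)
  used_true <- rep(FALSE, n_true)
  matched_label <- rep(NA_character_, n_true)
  ord <- order(d)
  for (k in ord) {
    if (d[k] > radius) break
    i <- (k - 1) %% n_det + 1
    j <- (k - 1) %/% n_det + 1
    if (used_det[i] || used_true[j]) next
    used_det[i] <- TRUE
    used_true[j] <- TRUE
    matched_label[j] <- records$label[i]
  }
  tp <- sum(used_true)
  list(
    tp = tp, fp = n_det - tp, fn = n_true - tp,
    matched_label = matched_label
  )
}

# Paint a hard disk of the given value onto a matrix (test-local renderer,
# independent of the package's internal painter).
paint_test_disk <- function(img, r0, c0, radius, value = 1) {
  rows <- seq_len(nrow(img))
  cols <- seq_len(ncol(img))
  m <- outer((rows - r0)^2, (cols - c0)^2, "+") <= radius^2
  img[m] <- value
  img
}

# Brute-force radial PSD oracle: direct double-loop DFT plus explicit
# radius binning, usable only on tiny grids.
brute_force_radial_psd <- function(x) {
  n <- nrow(x)
  stopifnot(n == ncol(x))
  ft <- matrix(0 + 0i, n, n)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      s <- 0 + 0i
      for (a in 0:(n - 1)) {
        for (b in 0:(n - 1)) {
          s <- s + x[a + 1, b + 1] * exp(-2i * pi * (u * a + v * b) / n)
        }
      }
      ft[u + 1, v + 1] <- s
    }
  }
  psd <- Mod(ft)^2
  half <- n %/% 2
  sums <- rep(0, half)
  counts <- rep(0L, half)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      su <- if (u > n / 2) u - n else u
      sv <- if (v > n / 2) v - n else v
      r <- sqrt(su^2 + sv^2)
      k <- floor(r + 0.5) # half away from zero (radii are non-negative)
      if (k >= 1 && k <= half) {
        sums[k] <- sums[k] + psd[u + 1, v + 1]
        counts[k] <- counts[k] + 1L
      }
    }
  }
  list(power = sums / counts, counts = counts, frequencies = (1:half) / n)
}
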