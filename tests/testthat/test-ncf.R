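test_that("compute_psd2d satisfies Parseval and isolates DC", {
  set.seed(10)
  px <- matrix(runif(360000), 600)
  p <- compute_psd2d(px)
  expect_equal(sum(p$psd) / 600^2, sum(px^2), tolerance = 1e-8)
  expect_equal(p$dc_power, sum(px)^2, tolerance = 1e-8)

  # constant image: all non-DC power vanishes
  pc <- compute_psd2d(matrix(2, 600, 600))
  off_dc <- sum(pc$psd) - pc$dc_power
  expect_lt(abs(off_dc), 1e-10 * pc$dc_power)

  expect_error(compute_psd2d(matrix(1, 100, 100)), "standardize")
  expect_error(compute_psd2d(matrix(1, 600, 500)), "square")
  expect_silent(compute_psd2d(matrix(1, 8, 8), check_size = FALSE))
})

test_that("radial sampling is rotation-symmetric and bounded by the grid", {
  set.seed(11)
  px <- matrix(runif(360000), 600)
  c1 <- radial_psd(compute_psd2d(px))
  c2 <- radial_psd(compute_psd2d(t(px[600:1, ]))) # 90 degree rotation
  expect_equal(c1$power, c2$power, tolerance = 1e-10)
  expect_lte(sum(c1$counts), 600^2 - 1)
  expect_equal(c1$frequencies, (1:300) / 600)
  expect_equal(c1$f_min, 1 / 600)
  expect_equal(c1$f_max, 0.5)
})

test_that("a pure cosine of period 100 px peaks at 0.01 px^-1", {
  px <- outer(rep(1, 600), 1 + cos(2 * pi * (0:599) / 100))
  cv <- radial_psd(compute_psd2d(px))
  expect_equal(which.max(cv$power), 6L) # f = 6/600 = 0.01 px^-1
  expect_equal(cv$frequencies[6], 0.01)
})

test_that("white-noise spectra are flat across the annuli", {
  acc <- rep(0, 300)
  for (s in 1:10) {
    acc <- acc + radial_psd(compute_psd2d(generate_white_noise(seed = 100 + s)))$power
  }
  mid <- acc[10:290] / 10
  expect_lt(max(mid) / min(mid), 1.5)
})

test_that("a wide Gaussian clump concentrates its power at low frequency", {
  g <- generate_gaussian_clump(c(600, 600), sigma_px = 100)
  cv <- radial_psd(compute_psd2d(g))
  total <- sum(cv$counts * cv$power)
  low <- sum(cv$counts[1:5] * cv$power[1:5])
  expect_gte(low / total, 0.99)
})

test_that("radial PSD matches the brute-force DFT oracle on tiny grids", {
  set.seed(12)
  for (rep in 1:3) {
    x <- matrix(runif(64), 8)
    fast <- radial_psd(compute_psd2d(x, check_size = FALSE))
    slow <- brute_force_radial_psd(x)
    expect_equal(fast$counts, slow$counts)
    expect_equal(fast$power, slow$power, tolerance = 1e-10)
    expect_equal(fast$frequencies, slow$frequencies)
  }
})

test_that("the NCF reproduces its analytic discrete quadrature on curves", {
  # analytic radial curve: power ~ f^-2, annulus counts ~ f on the 600-px grid
  f <- (1:300) / 600
  curve <- list(
    frequencies = f, power = f^-2, counts = f, f_min = 1 / 600, f_max = 0.5
  )
  res <- ncf(curve)
  # independent quadrature: weights w = count*power = 1/f, mean of ln f
  w <- 1 / f
  oracle <- (log(0.5) - sum(w * log(f)) / sum(w)) / (log(0.5) - log(1 / 600))
  expect_equal(res$ncf, oracle, tolerance = 1e-12)
  expect_equal(res$ncf, 0.5478365616, tolerance = 1e-9) # frozen pre-build value
})

test_that("the power-law NCF converges to the continuum midpoint 0.5", {
  ncf_at <- function(K) {
    f <- (1:K) / (2 * K)
    ncf(list(
      frequencies = f, power = f^-2, counts = f, f_min = f[1], f_max = 0.5
    ))$ncf
  }
  dev <- abs(c(ncf_at(300), ncf_at(3000), ncf_at(30000)) - 0.5)
  expect_true(all(diff(dev) < 0))
})

test_that("NCF errors on degenerate spectra", {
  f <- (1:300) / 600
  expect_error(
    ncf(list(frequencies = f, power = rep(0, 300), counts = f, f_min = f[1], f_max = 0.5)),
    "degenerate"
  )
  expect_warning(
    expect_error(ncf_image(matrix(0, 600, 600)), "degenerate"),
    "constant"
  )
})

test_that("NCF is invariant to intensity scale, rotations and flips", {
  set.seed(13)
  px <- generate_gaussian_clump(c(600, 600), 60) +
    0.1 * matrix(runif(360000), 600)
  base <- ncf_image(px, normalize = FALSE)$ncf
  expect_equal(ncf_image(37.5 * px, normalize = FALSE)$ncf, base, tolerance = 1e-10)
  expect_equal(ncf_image(t(px[600:1, ]), normalize = FALSE)$ncf, base, tolerance = 1e-10)
  expect_equal(ncf_image(px[600:1, ], normalize = FALSE)$ncf, base, tolerance = 1e-10)
  expect_equal(ncf_image(px[, 600:1], normalize = FALSE)$ncf, base, tolerance = 1e-10)
})

test_that("NCF stays within [0,1] on arbitrary fields", {
  for (s in 1:5) {
    fld <- generate_power_law_field(c(600, 600), exponent_beta = s - 1, seed = s)
    v <- ncf_image(fld)$ncf
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("ncf_per_channel maps channels independently", {
  sc <- generate_cell_scene(scene_config(n_neurons = 5, n_glia = 5, seed = 21))
  img <- sc$image
  res <- ncf_per_channel(img)
  expect_named(res, c("nuclei", "neuron", "astrocyte"))

  dup <- std_image(list(
    neuron = img$channels$neuron,
    astrocyte = img$channels$neuron
  ))
  rdup <- ncf_per_channel(dup)
  expect_identical(rdup$neuron, rdup$astrocyte)

  one <- std_image(list(nuclei = img$channels$nuclei))
  expect_named(ncf_per_channel(one), "nuclei")

  bad <- std_image(list(nuclei = matrix(0, 600, 600), neuron = img$channels$neuron))
  expect_warning(
    expect_error(ncf_per_channel(bad), "channel 'nuclei'"),
    "constant"
  )
})

test_that("clustered scenes score a higher NCF than uniform ones", {
  ncf_of <- function(arr, seed) {
    cfg <- scene_config(
      n_neurons = 20, n_glia = 10, arrangement = arr,
      thomas_params = list(n_parents = 5, cluster_sigma = 10),
      min_sep_px = 2, seed = seed
    )
    ncf_image(generate_cell_scene(cfg)$image$channels$neuron)$ncf
  }
  m_thomas <- mean(vapply(1:20, function(s) ncf_of("thomas", 300 + s), numeric(1)))
  m_poisson <- mean(vapply(1:20, function(s) ncf_of("poisson", 300 + s), numeric(1)))
  expect_gt(m_thomas, m_poisson)
})
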