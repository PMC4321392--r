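make_set <- function(rows, links = NULL) {
  soma_set(
    data.frame(
      id = seq_len(nrow(rows)), row = rows[, 1], col = rows[, 2],
      radius = if (ncol(rows) > 2) rows[, 3] else 5
    ),
    links
  )
}

test_that("proximity and dendrite links define connected somas", {
  # boundary gap 5 px (< 10): connected
  near <- make_set(rbind(c(100, 100, 5), c(100, 115, 5)))
  st <- soma_status(near)
  expect_equal(st$status, c("connected", "connected"))

  # gap 50 px, no links: isolated
  far <- make_set(rbind(c(100, 100, 5), c(100, 160, 5)))
  expect_equal(soma_status(far)$status, c("isolated", "isolated"))

  # distant but dendrite-linked: connected
  linked <- make_set(
    rbind(c(100, 100, 5), c(100, 300, 5)),
    links = data.frame(id_a = 1L, id_b = 2L)
  )
  expect_equal(soma_status(linked)$status, c("connected", "connected"))

  # boundary-to-boundary metric: big somas 30 px apart centre-to-centre
  # with radius 12 have a 6-px gap -> connected even though centres are far
  big <- make_set(rbind(c(100, 100, 12), c(100, 130, 12)))
  expect_equal(soma_status(big)$status, c("connected", "connected"))
})

test_that("links to excluded somas are dropped with a warning", {
  somas <- data.frame(
    id = 1:3, row = c(100, 100, 300), col = c(100, 300, 100),
    radius = 5, excluded = c(FALSE, TRUE, FALSE)
  )
  s <- soma_set(somas, data.frame(id_a = 1L, id_b = 2L))
  expect_warning(st <- soma_status(s), "excluded")
  expect_equal(st$id, c(1L, 3L))
  expect_equal(st$status, c("isolated", "isolated"))
})

test_that("connectivity ratio arithmetic and degenerate flags", {
  st <- data.frame(
    id = 1:40,
    status = c(rep("connected", 30), rep("isolated", 10))
  )
  r <- connectivity_ratio(st)
  expect_equal(r$ratio, 4.0)
  expect_equal(r$n_total, 40)
  expect_equal(r$n_isolated, 10)

  all_iso <- data.frame(id = 1:7, status = rep("isolated", 7))
  expect_equal(connectivity_ratio(all_iso)$ratio, 1.0)

  none_iso <- data.frame(id = 1:7, status = rep("connected", 7))
  rn <- connectivity_ratio(none_iso)
  expect_true(rn$undefined)
  expect_true(is.na(rn$ratio))

  expect_error(connectivity_ratio(data.frame(id = integer(), status = character())), "empty")
})

test_that("ground-truth isolated sets are recovered exactly", {
  for (s in 1:5) {
    sc <- generate_soma_scene(30, 10, min_sep_px = 40, seed = 50 + s)
    st <- soma_status(sc$annotations)
    expect_setequal(
      st$id[st$status == "isolated"],
      sc$truth$isolated_ids
    )
  }
})

test_that("adding a dendrite link never increases the isolated count", {
  sc <- generate_soma_scene(20, 4, min_sep_px = 40, seed = 60)
  base <- connectivity_ratio(soma_status(sc$annotations))$n_isolated
  iso <- sc$truth$isolated_ids
  aug <- sc$annotations
  aug$links <- rbind(aug$links, data.frame(id_a = iso[1], id_b = iso[2]))
  after <- connectivity_ratio(soma_status(aug))$n_isolated
  expect_lte(after, base)
  expect_equal(after, base - 2L)
})

test_that("bright (dead) somas are auto-excluded at the configured floor", {
  img <- matrix(0.3, 200, 200)
  img[50, 50] <- 1.0 # saturated dead cell
  s <- make_set(rbind(c(50, 50, 5), c(150, 150, 5)))
  out <- auto_exclude_bright(img, s)
  expect_equal(out$somas$excluded, c(TRUE, FALSE))

  mod_img <- matrix(0.3, 200, 200)
  mod_img[1, 1] <- 1.0 # bright reference away from any soma
  moderate <- auto_exclude_bright(mod_img, s)
  expect_false(any(moderate$somas$excluded))

  # floor 1.0: only exactly-maximal pixels qualify
  img2 <- matrix(0.3, 200, 200)
  img2[50, 50] <- 1.0
  img2[150, 150] <- 0.999
  out2 <- auto_exclude_bright(img2, s, connectivity_params(bright_floor = 1.0))
  expect_equal(out2$somas$excluded, c(TRUE, FALSE))

  off <- auto_exclude_bright(img, s, connectivity_params(exclude_bright = FALSE))
  expect_false(any(off$somas$excluded))
})

test_that("group comparison reports percent change and Student's t", {
  set.seed(70)
  ratios <- rbind(
    data.frame(
      group = "control", time_point_h = 24,
      ratio = rnorm(10, mean = 4.0, sd = 0.2)
    ),
    data.frame(
      group = "treated", time_point_h = 24,
      ratio = rnorm(10, mean = 2.68, sd = 0.2)
    )
  )
  cmp <- compare_groups(ratios)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$percent_change, 33, tolerance = 0.15)
  expect_lt(cmp$p, 0.05)

  # identical groups: no change, p = 1
  same <- rbind(
    data.frame(group = "control", time_point_h = 0, ratio = c(2, 3, 4)),
    data.frame(group = "treated", time_point_h = 0, ratio = c(2, 3, 4))
  )
  cs <- compare_groups(same)
  expect_equal(cs$percent_change, 0)
  expect_equal(cs$p, 1, tolerance = 1e-12)

  # under-replicated cells are flagged
  thin <- rbind(
    data.frame(group = "control", time_point_h = 2, ratio = 3),
    data.frame(group = "treated", time_point_h = 2, ratio = c(2, 2.5))
  )
  ct <- compare_groups(thin)
  expect_true(is.na(ct$p))
  expect_match(ct$flag, "insufficient")

  expect_error(compare_groups(transform(same, group = "drugged")), "unknown group")
})
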