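sim_slice <- make_slice_image(slice_spec(collagen_fraction = 0.12, seed = 8))
ring_masks <- attr(sim_slice$vessels, "masks")

test_that("vessel mask recovers the drawn wall mask", {
  # vessel 1: SMA 0.9 + MX04 0.1 fills the whole ring
  vm <- vessel_mask(sim_slice$image, vessel_roi(mask = ring_masks[[1]], id = "v1"),
                    policy = threshold_fixed(0.3))
  expect_true(all(vm == ring_masks[[1]]))
  expect_equal(attr(vm, "policy"), "fixed")

  # threshold 0 with nonzero signal: mask = ROI & (signal > 0-level)
  vm0 <- vessel_mask(sim_slice$image, vessel_roi(mask = ring_masks[[1]]),
                     policy = threshold_fixed(0))
  merged <- pmax(sim_slice$image$channels$SMA, sim_slice$image$channels$MX04)
  expect_true(all(vm0 == (ring_masks[[1]] & merged > 0)))

  # blank image: empty-mask error naming the ROI
  blank <- channel_image(list(SMA = matrix(0, 50, 50), MX04 = matrix(0, 50, 50)),
                         pixel_size_um = 1)
  expect_error(
    vessel_mask(blank, vessel_roi(mask = matrix(TRUE, 50, 50), id = "b1"),
                policy = threshold_fixed(0.5)),
    "b1"
  )
})

test_that("channel coverage matches forced pixel fractions and ground truth", {
  # forced by formula: 250 positive of 1000 mask px -> 25%
  ch <- matrix(0, 40, 40)
  mask <- matrix(FALSE, 40, 40)
  mask[1:25, 1:40] <- TRUE # 1000 px
  ch[1:10, 1:25] <- 1 # 250 px inside the mask
  img <- channel_image(list(X = ch), pixel_size_um = 1)
  expect_equal(channel_coverage(img, mask, "X", threshold_fixed(0.5))$coverage_pct,
               25)
  # threshold above every intensity: nothing positive
  expect_equal(channel_coverage(img, mask, "X",
                                threshold_fixed(2))$coverage_pct, 0)

  # generator ground truth per vessel, 1 pp tolerance
  for (i in seq_len(nrow(sim_slice$vessels))) {
    vm <- vessel_mask(sim_slice$image, vessel_roi(mask = ring_masks[[i]]),
                      policy = threshold_fixed(0.3))
    got <- channel_coverage(sim_slice$image, vm, "MX04", threshold_fixed(0.3))
    expect_lt(abs(got$coverage_pct - 100 * sim_slice$vessels$mx04_coverage[i]),
              1)
  }
  expect_error(channel_coverage(sim_slice$image, ring_masks[[1]], "NOPE"),
               "unknown channel")
})

test_that("coverage is monotone non-increasing in the threshold", {
  vm <- vessel_mask(sim_slice$image, vessel_roi(mask = ring_masks[[2]]),
                    policy = threshold_fixed(0.3))
  covs <- vapply(seq(0, 0.9, by = 0.1), function(th) {
    channel_coverage(sim_slice$image, vm, "SMA", threshold_fixed(th))$coverage_pct
  }, numeric(1))
  expect_true(all(diff(covs) <= 0))
  expect_true(all(covs >= 0 & covs <= 100))
})

test_that("coverage over a union of disjoint masks is the pixel-weighted mean", {
  m1 <- ring_masks[[1]]; m2 <- ring_masks[[2]]
  expect_false(any(m1 & m2))
  c1 <- channel_coverage(sim_slice$image, m1, "SMA", threshold_fixed(0.3))
  c2 <- channel_coverage(sim_slice$image, m2, "SMA", threshold_fixed(0.3))
  cu <- channel_coverage(sim_slice$image, m1 | m2, "SMA", threshold_fixed(0.3))
  weighted <- (c1$coverage_pct * c1$n_mask_px + c2$coverage_pct * c2$n_mask_px) /
    (c1$n_mask_px + c2$n_mask_px)
  expect_equal(cu$coverage_pct, weighted, tolerance = 1e-12)
})

test_that("vascular density recovers the drawn network fraction", {
  got <- vascular_density(sim_slice$image, c(200, 200),
                          policy = threshold_fixed(0.3))$density_pct
  expect_lt(abs(got - 100 * sim_slice$summary$collagen_fraction), 0.5)
  # blank and saturated channels hit the range ends
  img <- channel_image(list(COLIV = matrix(0, 100, 100)), pixel_size_um = 10)
  expect_equal(vascular_density(img, c(50, 50), policy = threshold_fixed(0.1),
                                roi_size_um = 400)$density_pct, 0)
  img2 <- channel_image(list(COLIV = matrix(1, 100, 100)), pixel_size_um = 10)
  expect_equal(vascular_density(img2, c(50, 50), policy = threshold_fixed(0.5),
                                roi_size_um = 400)$density_pct, 100)
  expect_error(vascular_density(img, c(5, 5), policy = threshold_fixed(0.1)),
               "bounds")
})

test_that("plaque coverage implements the thresholded-fraction formula", {
  # 500 thresholded px over a 100000 px ROI -> 0.5%
  mx <- matrix(0.1, 250, 400)
  mx[1:20, 1:25] <- 0.9
  img <- channel_image(list(MX04 = mx), pixel_size_um = 1)
  roi <- matrix(TRUE, 250, 400)
  got <- plaque_coverage(img, roi, policy = threshold_fixed(0.4))
  expect_equal(got$plaque_pct, 0.5)

  # uniform channel at background level -> 0%
  flat <- channel_image(list(MX04 = matrix(0.2, 50, 50)), pixel_size_um = 1)
  expect_equal(plaque_coverage(flat, matrix(TRUE, 50, 50),
                               policy = threshold_fixed(0.1))$plaque_pct, 0)

  # vessel-free synthetic plaques: recovery within 0.3 pp
  sim <- make_slice_image(slice_spec(vessels = default_vessel_layout()[0, ],
                                     plaque_fraction = 0.03, seed = 12))
  got2 <- plaque_coverage(sim$image, matrix(TRUE, 400, 400),
                          policy = threshold_fixed(0.3))
  expect_lt(abs(got2$plaque_pct - 100 * sim$summary$plaque_fraction), 0.3)
})

test_that("line profiles read wall architecture and respect translation", {
  # full ring (no arc gap) so a horizontal cut always meets both walls
  ring_sim <- make_slice_image(slice_spec(
    canvas_px = c(160L, 160L),
    vessels = tibble::tibble(x = 80, y = 80, radius_px = 25,
                             type = "surface_artery", sma_fraction = 1,
                             mx04_fraction = 0, tracer_positive = FALSE),
    seed = 9
  ))
  line <- rbind(c(80 - 40, 80), c(80 + 40, 80))
  lp <- line_profile(ring_sim$image, line, channels = "SMA")
  # a horizontal cut across a ring meets the wall twice: the profile has
  # exactly two separated above-half-maximum excursions
  prof <- lp$intensity
  above <- prof > (max(prof) + min(prof)) / 2
  runs <- rle(above)
  expect_equal(sum(runs$values), 2)

  # constant image -> flat profile at the constant
  flat <- channel_image(list(A = matrix(0.4, 60, 60)), pixel_size_um = 2)
  lpf <- line_profile(flat, rbind(c(5, 30), c(55, 30)), channels = "A")
  expect_true(all(abs(lpf$intensity - 0.4) < 1e-12))
  expect_equal(diff(range(diff(lpf$position_um))), 0, tolerance = 1e-9)

  # translation invariance: shift image and polyline together
  ch <- ring_sim$image$channels$SMA
  shifted <- channel_image(list(SMA = rbind(ch[21:160, ], ch[1:20, ])),
                           pixel_size_um = 1)
  l2 <- line - cbind(c(0, 0), c(20, 20))
  lp2 <- line_profile(shifted, l2, channels = "SMA")
  expect_equal(lp2$intensity, lp$intensity, tolerance = 1e-9)

  expect_error(line_profile(sim_slice$image, rbind(c(5, 5), c(5, 5))),
               "degenerate|zero-length")
})

test_that("complementary SMA/MX04 rings give anticorrelated profiles", {
  layout <- tibble::tibble(
    x = 60, y = 60, radius_px = 30, type = "surface_artery",
    sma_fraction = 0.5, mx04_fraction = 0.5, tracer_positive = FALSE
  )
  sim <- make_slice_image(slice_spec(canvas_px = c(120L, 120L),
                                     vessels = layout, seed = 4))
  ring <- attr(sim$vessels, "masks")[[1]]
  sma <- sim$image$channels$SMA[ring]
  mx <- sim$image$channels$MX04[ring]
  expect_lt(suppressWarnings(cor(sma, mx, method = "spearman")), 0)
})
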