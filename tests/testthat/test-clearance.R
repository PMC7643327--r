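test_that("tracer-positive artery counting matches construction", {
  # 3 of the 5 default vessels are tracer-positive
  sim <- make_slice_image(slice_spec(seed = 14))
  got <- count_ipad_arteries(sim$image, sma_policy = threshold_fixed(0.3),
                             tracer_policy = threshold_fixed(0.3))
  expect_equal(got$count, sim$summary$n_tracer_positive)
  audit <- attr(got, "components")
  expect_equal(sum(audit$accepted), got$count)

  # blank tracer -> 0
  img <- sim$image
  img$channels$FITC3K[] <- 0
  expect_equal(count_ipad_arteries(img, sma_policy = threshold_fixed(0.3),
                                   tracer_policy = threshold_fixed(0.3))$count, 0)

  # colocal_fraction 0 counts every SMA component (upper bound)
  all_sma <- count_ipad_arteries(sim$image, sma_policy = threshold_fixed(0.3),
                                 tracer_policy = threshold_fixed(0.3),
                                 colocal_fraction = 0)
  expect_equal(all_sma$count, nrow(sim$vessels))
  expect_error(count_ipad_arteries(channel_image(list(SMA = matrix(1, 5, 5)),
                                                 1)), "FITC3K")
})

test_that("counting is monotone in the colocalization threshold", {
  sim <- make_slice_image(slice_spec(seed = 15))
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(cf) {
    count_ipad_arteries(sim$image, sma_policy = threshold_fixed(0.3),
                        tracer_policy = threshold_fixed(0.3),
                        colocal_fraction = cf)$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

cohort_spec <- cortical_slice_spec(seed = 20)
cs <- make_cortical_slice(cohort_spec)

test_that("whole-slice influx signal is background-subtracted and offset-invariant", {
  ti <- total_influx_signal(cs$slice, "FITC3K")
  expect_gt(ti$mean_signal, 0)

  # uniform image at the background estimate -> 0
  flat <- channel_image(list(FITC3K = matrix(0.3, 80, 80)), pixel_size_um = 10)
  bm <- disk_mask(c(80, 80), 40, 40, 25)
  expect_equal(total_influx_signal(flat, "FITC3K", brain_mask = bm)$mean_signal, 0)

  # constant offset to the whole image leaves the result unchanged
  img2 <- cs$slice$image
  img2$channels$FITC3K <- img2$channels$FITC3K + 0.1
  ti2 <- total_influx_signal(img2, "FITC3K", brain_mask = cs$slice$brain_mask)
  expect_equal(ti2$mean_signal, ti$mean_signal, tolerance = 1e-9)

  # doubling signal above background doubles the mean
  img3 <- cs$slice$image
  bg <- median(img3$channels$FITC3K[!cs$slice$brain_mask])
  img3$channels$FITC3K <- bg + 2 * pmax(img3$channels$FITC3K - bg, 0)
  ti3 <- total_influx_signal(img3, "FITC3K", brain_mask = cs$slice$brain_mask)
  expect_equal(ti3$mean_signal, 2 * ti$mean_signal, tolerance = 1e-6)

  expect_error(total_influx_signal(cs$slice, "FITC3K",
                                   brain_mask = matrix(FALSE, 360, 360)),
               "non-empty")
})

test_that("penetrating-vessel counting respects geometry and is exact on truth", {
  got <- count_penetrating_vessels(cs$slice)
  expect_equal(got$count, cs$truth$n_penetrating)

  # blank tracers -> 0
  blank <- cs$slice
  blank$image$channels$FITC3K[] <- 0
  blank$image$channels$TMR40K[] <- 0
  expect_equal(count_penetrating_vessels(blank,
                                         policy = threshold_fixed(0.3))$count, 0)

  # stripes parallel to the surface are rejected by the angle rule:
  # demand near-zero deviation so radial stripes fail
  strict <- count_penetrating_vessels(cs$slice, angle_tol_deg = 90)
  loose <- count_penetrating_vessels(cs$slice, angle_tol_deg = 30)
  expect_gte(strict$count, loose$count)
  tangential <- count_penetrating_vessels(cs$slice, angle_tol_deg = 5,
                                          min_aspect = 2)
  expect_equal(tangential$count, cs$truth$n_penetrating) # radial, dev ~ 0
})

test_that("tangential stripes are excluded by the perpendicularity rule", {
  # draw stripes along the band (tangential), not across it
  spec <- cortical_slice_spec(n_penetrating = 0L, seed = 21,
                              plaque_burden_pct = c(dorsal = 0, lateral = 0,
                                                    ventral = 0))
  sl <- make_cortical_slice(spec)$slice
  n <- 360; ctr <- c(180, 180)
  for (a in c(100, 140, 220, 260)) {
    th <- a * pi / 180
    r <- 140
    st <- segment_mask(c(n, n),
                       ctr[1] + r * cos(th - 0.08), ctr[2] + r * sin(th - 0.08),
                       ctr[1] + r * cos(th + 0.08), ctr[2] + r * sin(th + 0.08),
                       width = 3)
    sl$image$channels$FITC3K[st] <- pmax(sl$image$channels$FITC3K[st], 0.85)
  }
  got <- count_penetrating_vessels(sl, policy = threshold_fixed(0.3))
  expect_equal(got$count, 0)
})

test_that("cortical partition is a disjoint cover matching arc fractions", {
  masks <- partition_cortex(cs$slice)
  band <- cs$slice$cortex_mask
  stacked <- masks$dorsal + masks$lateral + masks$ventral
  expect_true(all(stacked[band] == 1))
  expect_true(all(stacked[!band] == 0))

  # landmarks at 60/120 degrees on a symmetric band: each region ~ 1/3 arc
  areas <- vapply(masks, sum, numeric(1))
  expect_equal(unname(areas / sum(areas)), rep(1 / 3, 3), tolerance = 0.02)

  # degenerate landmark placements are flagged, not fatal
  expect_warning(partition_cortex(cs$slice, landmarks_deg = c(0, 180)),
                 "dorsal, ventral")
  expect_warning(partition_cortex(cs$slice, landmarks_deg = c(90, 90)),
                 "lateral")
  expect_error(partition_cortex(cs$slice, landmarks_deg = c(120, 60)),
               "ordered")
})

test_that("cortical linearization reads the dorsoventral gradient", {
  pr <- linearize_cortex(cs$slice, channels = "FITC3K")
  expect_true(all(diff(pr$arclength_um) > 0))
  means <- tapply(pr$mean_intensity, pr$region, mean)
  expect_lt(means[["dorsal"]], means[["lateral"]])
  expect_lt(means[["lateral"]], means[["ventral"]])

  # rotationally symmetric signal -> flat profile
  sym <- cs$slice
  sym$image$channels$FITC3K <- matrix(0.2, 360, 360)
  prs <- linearize_cortex(sym, channels = "FITC3K")
  expect_lt(diff(range(prs$mean_intensity)), 1e-9)

  expect_error(linearize_cortex(cs$slice, band_depth_um = 0), "positive")
})

test_that("regional table recovers generator means, counts and orderings", {
  slices <- purrr::map(1:3, function(i) {
    make_cortical_slice(cortical_slice_spec(seed = 30 + i),
                        slice_id = sprintf("s%02d", i))
  })
  tbl <- regional_table(purrr::map(slices, "slice"))
  # schema: slices x 3 regions x 2 channels
  expect_equal(nrow(tbl), 3 * 3 * 2)

  # noise-free: region means equal generator means up to the small additive
  # contribution of the bright penetrating-vessel stripes
  for (i in 1:3) {
    tr <- slices[[i]]$truth
    sub <- tbl[tbl$slice_id == sprintf("s%02d", i) & tbl$channel == "FITC3K", ]
    for (rg in c("dorsal", "lateral", "ventral")) {
      got <- sub$mean_signal[sub$region == rg]
      expect_lt(abs(got - tr$influx_means$FITC3K[[rg]]), 0.05)
    }
    counts <- setNames(sub$n_penetrating_vessels, as.character(sub$region))
    expect_equal(unname(counts[c("dorsal", "lateral", "ventral")]),
                 unname(tr$n_penetrating_per_region))
  }

  # without stripes the region means are exact to the quantization grid
  plain <- make_cortical_slice(cortical_slice_spec(n_penetrating = 0L,
                                                   seed = 35))
  tplain <- regional_table(list(plain$slice), count_penetrating = FALSE)
  fp <- tplain[tplain$channel == "FITC3K", ]
  for (rg in c("dorsal", "lateral", "ventral")) {
    expect_equal(fp$mean_signal[fp$region == rg],
                 plain$truth$influx_means$FITC3K[[rg]], tolerance = 1e-3)
  }

  # shuffled slice order yields the identical table after sorting
  tbl_shuf <- regional_table(purrr::map(slices, "slice")[c(3, 1, 2)])
  expect_equal(as.data.frame(tbl_shuf), as.data.frame(tbl))

  # inconsistent channel sets across slices -> error
  broken <- purrr::map(slices, "slice")
  broken[[2]]$image$channels$TMR40K <- NULL
  expect_error(regional_table(broken), "lacks")
})
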