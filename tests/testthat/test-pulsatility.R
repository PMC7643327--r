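test_that("diameter extraction recovers a constant rectangular lumen exactly", {
  # 10 px lumen at 0.5 um/px -> D = 5 um on every line
  img <- matrix(0.1, 40, 100)
  img[16:25, ] <- 0.9
  k <- kymograph(img, pixel_size_um = 0.5, line_period_ms = 1)
  tr <- extract_diameter_trace(k, smooth_cutoff_hz = NULL, profile_sigma_px = 0)
  expect_true(all(tr$valid))
  expect_equal(tr$D_um, rep(5, 100), tolerance = 1e-9)
})

test_that("diameter extraction tracks a noiseless sinusoid to sub-pixel accuracy", {
  for (amp in c(0.2, 0.5, 1.0)) {
    sim <- make_kymograph(sinus_spec(amplitude = amp))
    tr <- extract_diameter_trace(sim$kymograph)
    err_px <- abs(tr$D_um - sim$truth$D_um) / sim$kymograph$pixel_size_um
    expect_lt(max(err_px), 0.5)
  }
})

test_that("degenerate kymographs are rejected with a diagnostic", {
  k <- kymograph(matrix(0, 30, 50), pixel_size_um = 0.5, line_period_ms = 1)
  expect_error(extract_diameter_trace(k), "rejected")
})

test_that("moving-average baseline reproduces windowed means and handles edges", {
  # constant trace: d == c for any window
  tr <- diameter_trace(0:999, rep(7, 1000))
  trb <- moving_average_baseline(tr, window_ms = 100)
  expect_equal(trb$d_um, rep(7, 1000))

  # interior samples equal the direct windowed mean (oracle)
  tr2 <- random_trace(11, n = 2000)
  half <- round(500 / 2)
  direct <- vapply(600:1400, function(i) mean(tr2$D_um[(i - half):(i + half)]),
                   numeric(1))
  expect_equal(tr2$d_um[600:1400], direct, tolerance = 1e-6)

  # window = record length: centered value equals the global mean
  tr3 <- diameter_trace(0:99, rnorm(100, 10))
  trb3 <- moving_average_baseline(tr3, window_ms = 99)
  expect_equal(trb3$d_um[50], mean(tr3$D_um), tolerance = 1e-9)

  expect_error(moving_average_baseline(tr3, window_ms = 1000), "longer")
})

test_that("pulsatility indices are zero iff the vessel is constant", {
  tr <- moving_average_baseline(diameter_trace(0:3999, rep(12, 4000)), 500)
  p <- pulsatility(tr)
  expect_equal(p$pulsatility_index, 0)
  expect_equal(p$relative_pulsatility_index, 0)

  tr2 <- random_trace(21)
  expect_gt(pulsatility_index(tr2), 1e-9)
})

test_that("sinusoid with fixed baseline reproduces the analytic integral", {
  t <- 0:2999
  tr <- diameter_trace(t, 10 + sin(2 * pi * t / 1000))
  tr$d_um <- rep(10, 3000)
  attr(tr, "mean_D_um") <- 10
  p <- pulsatility(tr)
  analytic <- 3 * (2 / pi) * 1000 # integral of |sin| over three half-periods
  expect_equal(p$pulsatility_index, analytic, tolerance = 0.001)
  expect_equal(p$relative_pulsatility_index, p$pulsatility_index / 10,
               tolerance = 1e-12)
})

test_that("absolute index is homogeneous and relative index scale-free", {
  tr <- random_trace(31)
  p <- pulsatility(tr)
  # scaling the deviation by c scales the absolute index by exactly c
  tr_dev <- tr
  tr_dev$D_um <- tr$d_um + 3 * (tr$D_um - tr$d_um)
  tr_dev$d_um <- tr$d_um
  expect_equal(pulsatility(tr_dev)$pulsatility_index,
               3 * p$pulsatility_index, tolerance = 1e-9)

  # rescaling the whole trace: absolute scales by c, relative unchanged
  tr_scaled <- moving_average_baseline(
    diameter_trace(tr$t_ms, 2.5 * tr$D_um), window_ms = 500
  )
  p_s <- pulsatility(tr_scaled)
  expect_equal(p_s$pulsatility_index, 2.5 * p$pulsatility_index,
               tolerance = 1e-9)
  expect_equal(p_s$relative_pulsatility_index, p$relative_pulsatility_index,
               tolerance = 1e-9)
})

test_that("indices are invariant under time reversal", {
  for (seed in c(41, 42, 43)) {
    tr <- random_trace(seed)
    rev_tr <- moving_average_baseline(
      diameter_trace(tr$t_ms, rev(tr$D_um)), window_ms = 500
    )
    p <- pulsatility(tr); pr <- pulsatility(rev_tr)
    expect_equal(pr$pulsatility_index, p$pulsatility_index, tolerance = 1e-9)
    expect_equal(pr$relative_pulsatility_index, p$relative_pulsatility_index,
                 tolerance = 1e-9)
  }
})

test_that("incomplete trailing epochs are discarded and short traces rejected", {
  tr <- random_trace(51, n = 7500) # 2 complete epochs + remainder
  p <- pulsatility(tr)
  expect_equal(p$n_epochs, 2)
  per <- attr(p, "per_epoch")
  expect_equal(length(per), 2)
  expect_equal(p$pulsatility_index, mean(per))

  short <- moving_average_baseline(diameter_trace(0:999, rnorm(1000, 10)), 200)
  expect_error(pulsatility(short), "epoch")
})

test_that("batch pulsatility assembles an ordered per-vessel table", {
  specs <- list(
    a = sinus_spec(amplitude = 0, seed = 1, duration_ms = 3000),
    b = sinus_spec(amplitude = 1, seed = 2, duration_ms = 3000)
  )
  kymos <- purrr::imap(specs, function(s, nm) {
    make_kymograph(s, vessel_id = nm,
                   annotations = list(caa = nm == "b"))$kymograph
  })
  tbl <- batch_pulsatility(kymos)
  expect_equal(nrow(tbl), 2)
  expect_lt(tbl$pulsatility_index[1], tbl$pulsatility_index[2])
  expect_equal(tbl$caa, c(FALSE, TRUE))

  # empty input keeps the schema
  empty <- batch_pulsatility(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("vessel_id", "pulsatility_index") %in% names(empty)))

  # single vessel matches the direct computation
  one <- batch_pulsatility(kymos[2])
  tr <- moving_average_baseline(extract_diameter_trace(kymos[[2]]), 500)
  expect_equal(one$pulsatility_index, pulsatility_index(tr), tolerance = 1e-12)
})

test_that("CAA-annotated groups recover the generative amplitude ordering", {
  kymos <- purrr::map(1:6, function(i) {
    amp <- if (i <= 3) 0.3 else 0.9
    make_kymograph(sinus_spec(amplitude = amp, seed = 100 + i,
                              duration_ms = 3000),
                   vessel_id = paste0("v", i),
                   annotations = list(caa = i > 3))$kymograph
  })
  tbl <- batch_pulsatility(kymos)
  g <- group_summary(tbl, caa, value = "pulsatility_index")
  expect_lt(g$mean[!g$caa], g$mean[g$caa])
})
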