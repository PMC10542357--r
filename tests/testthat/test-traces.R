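test_that("ROI extraction averages exactly the ROI pixels", {
  fr <- array(5, dim = c(6, 6, 3))
  rois <- roi_set(list(a = cbind(2:3, 2:3)))
  tm <- extract_traces(ca_movie(fr), rois)
  expect_equal(unname(tm$values["a", ]), rep(5, 3))

  fr2 <- array(0, dim = c(4, 4, 2))
  fr2[1, 1, ] <- 10; fr2[2, 2, ] <- 20
  tm2 <- extract_traces(ca_movie(fr2),
                        roi_set(list(p = rbind(c(1, 1), c(2, 2)))))
  expect_equal(unname(tm2$values["p", ]), c(15, 15))
})

test_that("invalid pixels are excluded; all-invalid samples are masked", {
  fr <- array(10, dim = c(4, 4, 2))
  fr[1, 1, 1] <- NA          # one invalid pixel, frame 1
  fr[, , 2] <- NA            # fully invalid frame
  fr[3:4, 3:4, 2] <- 7
  mv <- ca_movie(fr)
  rois <- roi_set(list(a = rbind(c(1, 1), c(1, 2)), b = cbind(3:4, 3:4)))
  tm <- extract_traces(mv, rois)
  expect_equal(unname(tm$values["a", 1]), 10)   # mean over the valid pixel
  expect_true(is.na(tm$values["a", 2]))
  expect_false(tm$valid["a", 2])
  expect_equal(unname(tm$values["b", 2]), 7)
})

test_that("out-of-grid and malformed ROIs are rejected", {
  mv <- ca_movie(array(1, dim = c(4, 4, 2)))
  expect_error(extract_traces(mv, roi_set(list(a = rbind(c(5, 1))))),
               "outside")
  expect_error(roi_set(list(a = matrix(numeric(0), 0, 2))), "non-empty")
  expect_error(roi_set(list(a = rbind(c(1, 1)), a = rbind(c(2, 2)))),
               "unique")
})

test_that("trial baseline is the mean of the 10-s pre-onset window", {
  expect_equal(trial_baseline(rep(100, 400), (0:399) * 33.3, 12000)$f0, 100)

  # 30 Hz sampling, linear ramp 90 -> 110 over the 10 s before a 12-s onset:
  # oracle enumerates the in-window samples and takes their plain mean
  dt <- 1000 / 30
  t_ms <- (0:400) * dt
  f <- 90 + (t_ms - 2000) / 10000 * 20   # ramp anchored to the window
  onset <- 12000
  in_win <- t_ms >= onset - 10000 & t_ms < onset
  expect_equal(sum(in_win), 300)
  bl <- trial_baseline(f, t_ms, onset)
  expect_equal(bl$f0, mean(f[in_win]))
  expect_equal(bl$n_samples, 300)
  expect_false(bl$truncated)
})

test_that("short recordings truncate the baseline and set the flag", {
  # recording starts 4 s before onset: 120 samples at 30 Hz are available
  dt <- 1000 / 30
  t_ms <- 8000 + (0:200) * dt
  set.seed(1)
  f <- rnorm(length(t_ms), 100, 1)
  onset <- 12000
  in_win <- t_ms >= 2000 & t_ms < onset
  bl <- trial_baseline(f, t_ms, onset)
  expect_equal(bl$f0, mean(f[in_win]))
  expect_equal(bl$n_samples, 120)
  expect_true(bl$truncated)
})

test_that("baseline errors on missing pre-onset data or non-positive F0", {
  expect_error(trial_baseline(rep(1, 10), 100 + 0:9, onset = 50), "no valid")
  expect_error(trial_baseline(rep(0, 10), 0:9, onset = 5), "F0")
})

test_that("the baseline window is half-open: the onset sample is excluded", {
  t_ms <- 0:20
  f <- rep(100, 21)
  f[11] <- 1e6   # a huge value exactly at onset must not contaminate F0
  expect_equal(trial_baseline(f, t_ms, onset = 10, baseline_duration = 10)$f0,
               100)
})

test_that("dF/F identities hold", {
  expect_equal(compute_dff(rep(100, 5), 100), rep(0, 5))
  expect_equal(compute_dff(140, 100), 0.4)
  expect_error(compute_dff(1:3, 0), "positive")
})

test_that("dF/F is gain-invariant and offset-equivariant (property)", {
  set.seed(2)
  for (i in 1:10) {
    f <- runif(50, 80, 150)
    f0 <- mean(f[1:20])
    gain <- runif(1, 0.1, 10)
    expect_equal(compute_dff(gain * f, gain * f0), compute_dff(f, f0))
    b <- runif(1, 1, 50)
    expect_equal(compute_dff(f + b, f0 + b), (f - f0) / (f0 + b))
  }
})

test_that("trace matrices round-trip through CSV exactly", {
  set.seed(3)
  vals <- matrix(rnorm(60, 100, 17), 3, 20,
                 dimnames = list(c("a", "b", "c"), NULL))
  vals[2, 5] <- NA
  tm <- trace_matrix(vals, (0:19) * 33.3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_traces_csv(tm, path)
  back <- read_traces_csv(path)
  expect_identical(back$values, tm$values)
  expect_equal(back$time_ms, tm$time_ms)
  expect_equal(back$valid, tm$valid, ignore_attr = TRUE)
})

test_that("per-trial dF/F matches a manual baseline computation", {
  cfg <- scene_config(n_rois = 2, n_trials = 2, baseline_ms = 2000,
                      window_ms = 1000, noise_sd_frac = 0.01,
                      amplitude = list(dist = "fixed", value = 0.5),
                      seed = 4)
  sim <- simulate_traces(cfg)
  dff <- dff_by_trial(sim$traces, sim$trials, window_ms = 1000,
                      baseline_duration = 2000)
  tm <- sim$traces
  for (tr in 1:2) {
    onset <- sim$trials$onset_ms[tr]
    sel <- tm$time_ms >= onset - 2000 & tm$time_ms < onset
    f0_manual <- mean(tm$values["roi_001", sel])
    sub <- dff[dff$roi_id == "roi_001" & dff$trial_id == tr, ]
    expect_equal(unique(sub$f0), f0_manual)
    i <- which(tm$time_ms == sub$t_ms[1])
    expect_equal(sub$dff[1],
                 unname(tm$values["roi_001", i] - f0_manual) / f0_manual)
  }
})

test_that("polygon ROIs rasterize by pixel-center inclusion", {
  # closed square with corners at (1.5, 1.5) and (4.5, 4.5): the pixel
  # centers strictly inside are the 3 x 3 block at rows/cols 2..4
  poly <- list(list(roi_id = "sq",
                    x = c(1.5, 4.5, 4.5, 1.5),
                    y = c(1.5, 1.5, 4.5, 4.5)))
  rois <- roi_from_polygons_json(poly, shape = c(6, 6))
  got <- rois$pixels[["sq"]]
  expected <- as.matrix(expand.grid(row = 2:4, col = 2:4))
  expect_equal(got[order(got[, "row"], got[, "col"]), ],
               expected[order(expected[, "row"], expected[, "col"]), ],
               ignore_attr = TRUE)

  # JSON file path route
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(poly, path, auto_unbox = TRUE)
  expect_equal(roi_from_polygons_json(path, shape = c(6, 6))$pixels,
               rois$pixels)
})

test_that("label images and movies round-trip through TIFF", {
  labels <- matrix(0L, 8, 8)
  labels[2:3, 2:3] <- 1L
  labels[6:7, 5:6] <- 2L
  lp <- tempfile(fileext = ".tif")
  on.exit(unlink(lp))
  tiff::writeTIFF(labels / 65535, lp, bits.per.sample = 16L)
  rois <- roi_from_label_tiff(lp, layer_tag = "layer4")
  expect_named(rois$pixels, c("roi_1", "roi_2"))
  expect_equal(nrow(rois$pixels$roi_1), 4)
  expect_equal(rois$layer_tag, "layer4")

  mv <- ca_movie(array(sample(0:4000, 8 * 8 * 3, replace = TRUE),
                       c(8, 8, 3)), frame_period = 33.3)
  mp <- tempfile(fileext = ".tif")
  on.exit(unlink(mp), add = TRUE)
  write_movie_tiff(mv, mp)
  back <- read_movie_tiff(mp, frame_period = 33.3)
  expect_equal(back$frames, mv$frames)
  expect_equal(back$frame_period, 33.3)
})

test_that("line-scan CSV ingestion builds a ms-resolution trace matrix", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  tab <- data.frame(t_ms = 0:99, cell1 = rep(100, 100), cell2 = rep(50, 100))
  write.csv(tab, path, row.names = FALSE)
  tm <- read_linescan_csv(path, sample_period_ms = 1)
  expect_equal(tm$sample_period, 1)
  expect_equal(unname(tm$values["cell1", ]), rep(100, 100))
  expect_warning(read_linescan_csv(path, sample_period_ms = 2), "declared")
})
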