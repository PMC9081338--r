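test_that("well-separated discs segment to exactly one record each", {
  img <- disc_image(five_disc_centers)
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$records), 5)
  # area filter: a 2-px speck does not add a record
  img2 <- img
  img2[40, 5] <- 100; img2[40, 6] <- 100
  seg2 <- segment_nuclei(img2)
  expect_equal(nrow(seg2$records), 5)
  # label image and record list agree
  expect_setequal(unique(seg$labels[seg$labels > 0]), seg$records$nucleus_id)
  # centroids are 0-based (row, col) and match construction
  ord <- order(seg$records$centroid_row, seg$records$centroid_col)
  expect_equal(seg$records$centroid_row[ord],
               five_disc_centers[order(five_disc_centers[, 1],
                                       five_disc_centers[, 2]), 1] - 1,
               tolerance = 0.51)
})

test_that("an all-zero image yields an empty result, not an error", {
  seg <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(seg$records), 0)
  expect_true(all(seg$labels == 0))
})

test_that("adaptive thresholding survives a background gradient", {
  snap <- render_snapshot_image(10, seed = 3, uneven_background = 0.7)
  n_adaptive <- nrow(segment_nuclei(snap$image[, , "dna"],
                                    segmentation_config("adaptive"))$records)
  n_otsu <- nrow(segment_nuclei(snap$image[, , "dna"],
                                segmentation_config("global-otsu"))$records)
  expect_equal(n_adaptive, 10)
  expect_false(n_otsu == 10)   # the global threshold fails on this fixture
})

test_that("intensity measurement subtracts background and floors at zero", {
  img <- disc_image(five_disc_centers)
  seg <- segment_nuclei(img)
  # uniform channel, zero background
  uni <- matrix(7, nrow(img), ncol(img))
  m <- measure_intensities(seg$labels, list(ch = uni), "global-percentile")
  expect_equal(m$ch, rep(0, 5))   # 5th percentile of a constant image is 7
  m2 <- measure_intensities(seg$labels, list(ch = uni), "local-annulus")
  expect_equal(m2$ch, rep(0, 5))
  # disc value 100 on background 20 -> 80 under local-annulus
  img3 <- disc_image(five_disc_centers, value = 100, background = 20)
  m3 <- measure_intensities(seg$labels, list(ch = img3), "local-annulus")
  expect_equal(m3$ch, rep(80, 5), tolerance = 1e-9)
  expect_error(measure_intensities(seg$labels, list(ch = matrix(0, 2, 2))),
               "shape")
})

test_that("background-subtracted intensities are linear in channel scale", {
  snap <- render_snapshot_image(30, seed = 9)
  seg <- segment_nuclei(snap$image[, , "dna"])
  ch <- snap$image[, , "mcherry"]
  m1 <- measure_intensities(seg$labels, list(x = ch), "local-annulus")
  m4 <- measure_intensities(seg$labels, list(x = 4 * ch), "local-annulus")
  pos <- m1$x > 0
  expect_equal(m4$x[pos], 4 * m1$x[pos], tolerance = 1e-9)
})

test_that("segmentation recovers >= 95% of non-overlapping nuclei at SNR >= 5", {
  snap <- render_snapshot_image(150, seed = 21)
  seg <- segment_nuclei(snap$image[, , "dna"])
  found <- nrow(seg$records)
  # recall: every true nucleus has a segmented centroid within its radius
  hits <- vapply(seq_len(nrow(snap$truth)), function(i) {
    d2 <- (seg$records$centroid_row - snap$truth$row[i])^2 +
      (seg$records$centroid_col - snap$truth$col[i])^2
    any(d2 <= snap$truth$radius_px[i]^2)
  }, TRUE)
  expect_gte(mean(hits), 0.95)              # recall
  expect_gte(sum(hits) / found, 0.95)       # precision proxy
})

test_that("cell area converts pixel counts through the pixel size", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  expect_equal(measure_cell_area(mask, 1), 100)
  expect_equal(measure_cell_area(mask, 0.5), 25)
  expect_error(measure_cell_area(matrix(FALSE, 3, 3), 1), "empty")
  # a configured cardiomyocyte-scale mask round-trips its area
  side <- round(sqrt(2525.4) / 0.5)
  big <- matrix(TRUE, side, side)
  expect_equal(measure_cell_area(big, 0.5), side^2 * 0.25)
})

test_that("sarcomere spacing equals the constructed period", {
  # 1.97 um period sampled at 0.1 um/px
  px <- 0.1
  x <- seq(0, 40, by = px)
  prof <- sin(2 * pi * x / 1.97)
  expect_equal(sarcomere_spacing(prof, px), 1.97, tolerance = 0.02)
  prof2 <- sin(2 * pi * x / 2.0)
  expect_equal(sarcomere_spacing(prof2, px), 2.0, tolerance = 0.02)
  expect_error(sarcomere_spacing(sin(2 * pi * x[1:50] / 2.0), px),
               "peaks")
})

test_that("noisy sarcomere profiles agree with an autocorrelation oracle", {
  px <- 0.1
  x <- seq(0, 40, by = px)
  set.seed(5)
  prof <- sin(2 * pi * x / 1.97) + rnorm(length(x), 0, 0.1)
  est <- sarcomere_spacing(prof, px)
  # independent oracle: first autocorrelation peak
  ac <- acf(prof, lag.max = 60, plot = FALSE)$acf[-1]
  lag_peak <- which.max(ac[10:60]) + 9
  oracle <- lag_peak * px
  expect_lt(abs(est - oracle) / oracle, 0.05)
  expect_lt(abs(est - 1.97) / 1.97, 0.05)
})

test_that("snapshot rendering honors mixtures, emptiness and crowding limits", {
  all_red <- snapshot_mixture(p_red = 1, p_green = 0, p_yellow = 0, p_blue = 0)
  s <- render_snapshot_image(5, all_red, seed = 2)
  expect_equal(nrow(s$truth), 5)
  expect_true(all(s$truth$state == "RED"))
  q <- quantify_snapshot(s$image)
  thr <- fucci_thresholds(100, 100)
  cl <- classify_nuclei(q$records, thr)
  expect_equal(sum(cl$fucci_state == "RED"), 5)

  s0 <- render_snapshot_image(0, seed = 1)
  expect_equal(nrow(s0$truth), 0)

  expect_error(render_snapshot_image(100, image_shape = c(60, 60), seed = 1),
               "larger image")

  # multinomial oracle at n = 200 under the default mixture
  s200 <- render_snapshot_image(200, seed = 14)
  p <- as.numeric(snapshot_mixture())
  obs <- as.numeric(table(factor(s200$truth$state,
                                 levels = names(snapshot_mixture()))))
  se <- sqrt(p * (1 - p) / 200)
  expect_true(all(abs(obs / 200 - p) <= pmax(3 * se, 1e-9)))

  # determinism
  expect_identical(render_snapshot_image(20, seed = 8),
                   render_snapshot_image(20, seed = 8))
})

test_that("multi-channel TIFF round-trips through 16-bit pages", {
  snap <- render_snapshot_image(10, seed = 6, image_shape = c(120, 160))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(snap$image, path)
  back <- read_image_tiff(path)
  expect_equal(dim(back), dim(snap$image))
  expect_lt(max(abs(back - snap$image)), 4096 / 65535 * 1.01)
})
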