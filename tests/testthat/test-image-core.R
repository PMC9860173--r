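# Embryo masking, frame fitting, nucleus segmentation and measurement.

test_that("masking keeps the embryo and discards distant debris", {
  g <- embryo_geometry(300, 120, center = c(350, 400), angle = 0)
  raster <- ellipse_mask(g, c(700, 800)) * 1
  m <- mask_embryo(raster)
  expect_lt(abs(m$area - pi * 300 * 120) / (pi * 300 * 120), 0.02)

  # 10-px bright speck far outside the embryo is not part of the mask
  speck <- raster
  speck[40:42, 40:43] <- 1
  ms <- mask_embryo(speck)
  expect_false(any(ms$mask[35:47, 35:48]))
  expect_lt(abs(ms$area - m$area) / m$area, 0.02)

  expect_error(mask_embryo(matrix(0, 50, 50)), class = "ee_no_embryo_error")
})

test_that("frame fitting recovers rotation within half a degree", {
  for (ang in seq(-60, 60, by = 15)) {
    em <- ellipse_mask(embryo_geometry(300, 120, center = c(400, 420),
                                       angle = ang), c(800, 840))
    fr <- fit_embryo_frame(em)
    expect_lt(abs(fr$angle - ang), 0.5)
    expect_equal(fr$rotation, -fr$angle)
    expect_lt(abs(fr$L - 600) / 600, 0.01)
    # moment orientation and Feret direction agree for eccentric masks
    expect_lt(abs(fr$orientation - fr$angle), 5)
    expect_gte(fr$L, fr$H)
  }
})

test_that("near-circular masks are orientation-ambiguous", {
  rr <- row(matrix(0, 301, 301)) - 151
  cc <- col(matrix(0, 301, 301)) - 151
  disk <- (rr^2 + cc^2) <= 100^2
  expect_error(fit_embryo_frame(disk), class = "ee_orientation_error")
})

test_that("segmentation finds, splits, and filters nuclei", {
  img <- matrix(0, 200, 200)
  mask <- matrix(TRUE, 200, 200)
  disk <- function(img, r0, c0, r, val = 1000) {
    rr <- row(img) - r0; cc <- col(img) - c0
    img[rr^2 + cc^2 <= r^2] <- val
    img
  }
  # two disks 40 px apart
  img2 <- disk(disk(img, 100, 80, 8), 100, 120, 8)
  rec <- segment_nuclei(img2, mask, min_area = 4)
  expect_equal(nrow(rec), 2)
  expect_lt(min(abs(rec$col - 80)), 1)
  expect_lt(min(abs(rec$col - 120)), 1)
  expect_lt(max(abs(rec$row - 100)), 1)

  # overlapping disks (centers 1.4 r apart) are split by the watershed
  img3 <- disk(disk(img, 100, 95, 10), 100, 109, 10)
  rec3 <- segment_nuclei(img3, mask, min_area = 4)
  expect_equal(nrow(rec3), 2)

  # a 2-px speck below min_area yields no records
  img4 <- img; img4[50, 50:51] <- 1000
  expect_equal(nrow(segment_nuclei(img4, mask, min_area = 4)), 0)

  expect_error(segment_nuclei(img2, mask, min_area = 0),
               class = "ee_input_error")
  expect_error(segment_nuclei(img2, matrix(TRUE, 10, 10)),
               class = "ee_input_error")
})

test_that("segmentation recall and precision reach 0.95 on rendered embryos", {
  g <- embryo_geometry(300, 120, angle = 0)
  sp <- pattern_spec(uniform_level(50))
  # separation >= one nucleus radius between boundaries; noise 10% of the
  # nuclear amplitude
  sim <- render_embryo(g, sp, nuclei = list(n = 250, radius = 5, min_sep = 15),
                       noise = list(sd = 100), seed = 21)
  msk <- mask_embryo(sim$image)
  rec <- segment_nuclei(sim$image$nuclear, msk, min_area = 4)
  truth <- sim$truth$nuclei
  dd <- sqrt(outer(rec$row, truth$row, "-")^2 +
             outer(rec$col, truth$col, "-")^2)
  matched_rec <- apply(dd, 1, min) < 5
  matched_truth <- apply(dd, 2, min) < 5
  precision <- mean(matched_rec)
  recall <- mean(matched_truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
  # counting conservation: records = labels >= min_area
  labels <- attr(rec, "labels")
  expect_equal(nrow(rec), length(unique(labels[labels > 0])))
})

test_that("zero-noise measured nuclear intensities match ground truth", {
  g <- embryo_geometry(300, 120, angle = 20)
  sp <- pattern_spec(ap_stripe(0.4, 0.06, 100), baseline = 10)
  sim <- render_embryo(g, sp, noise = list(sd = 0), seed = 13)
  msk <- mask_embryo(sim$image)
  fr <- resolve_anterior(fit_embryo_frame(msk), "left")
  rec <- measure_nuclei(segment_nuclei(sim$image$nuclear, msk, frame = fr),
                        sim$image$reporter)
  truth <- sim$truth$nuclei
  dd <- sqrt(outer(rec$row, truth$row, "-")^2 +
             outer(rec$col, truth$col, "-")^2)
  nn <- apply(dd, 1, which.min)
  expect_lt(max(dd[cbind(seq_len(nrow(rec)), nn)]), 1)
  rel <- abs(rec$mean_reporter - truth$true_mean[nn]) / truth$true_mean[nn]
  expect_lt(max(rel), 0.01)
})

test_that("uniform reporter measures uniformly and empty input passes through", {
  img <- matrix(0, 120, 120)
  img[40:44, 40:44] <- 1000
  img[80:84, 80:84] <- 1000
  rec <- segment_nuclei(img, matrix(TRUE, 120, 120), min_area = 4)
  rec <- measure_nuclei(rec, matrix(42, 120, 120))
  expect_equal(rec$mean_reporter, rep(42, nrow(rec)))
  empty <- segment_nuclei(matrix(0.5, 50, 50), matrix(TRUE, 50, 50))
  expect_equal(nrow(measure_nuclei(empty, matrix(1, 50, 50))), 0)
  expect_error(measure_nuclei(rec, matrix(1, 10, 10)),
               class = "ee_input_error")
})

test_that("nucleus tables round-trip through CSV", {
  img <- matrix(0, 60, 60); img[30:34, 30:34] <- 900
  rec <- segment_nuclei(img, matrix(TRUE, 60, 60))
  f <- tempfile(fileext = ".csv")
  write_nuclei_csv(rec, f)
  back <- read_nuclei_csv(f)
  expect_equal(back$row, rec$row)
  expect_equal(back$area, rec$area)
})
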