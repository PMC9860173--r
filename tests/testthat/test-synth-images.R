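# Synthetic embryo rendering and its analytic ground truth.

test_that("pattern primitives evaluate analytically", {
  sp <- pattern_spec(ap_stripe(0.35, 0.05, 100), baseline = 0)
  expect_equal(pattern_value(sp, 0.35, 0.5), 100)
  expect_equal(pattern_value(sp, 0.40, 0.5), 100 * exp(-0.5))
  expect_equal(pattern_value(pattern_spec(uniform_level(7), baseline = 3),
                             c(0, 0.4, 1), c(1, 0.2, 0)), c(10, 10, 10))
  # additivity over primitives
  sp2 <- pattern_spec(ap_stripe(0.35, 0.05, 100), uniform_level(7),
                      baseline = 3)
  expect_equal(pattern_value(sp2, 0.35, 0.1), 110)
  expect_error(pattern_value(sp, 1.2, 0.5), class = "ee_input_error")
})

test_that("pixel/normalized coordinate transform round-trips", {
  for (ang in c(0, 25, -60)) {
    g <- embryo_geometry(300, 120, center = c(211.3, 402.8), angle = ang)
    row <- c(100.2, 250, 211.3); col <- c(300.7, 500, 402.8)
    nn <- pixel_to_norm(g, row, col)
    px <- norm_to_pixel(g, nn$ap, nn$dv)
    expect_lt(max(abs(px$row - row), abs(px$col - col)), 0.5)
  }
  # orientation conventions: image top is dorsal for an unrotated embryo
  g0 <- embryo_geometry(300, 120, center = c(200, 400), angle = 0)
  expect_lt(pixel_to_norm(g0, 100, 400)$dv, 0.5)   # above center = dorsal
  expect_lt(pixel_to_norm(g0, 200, 150)$ap, 0.5)   # left = anterior
  gr <- embryo_geometry(300, 120, center = c(200, 400), angle = 0,
                        anterior = "right")
  expect_gt(pixel_to_norm(gr, 200, 150)$ap, 0.5)
})

test_that("rendered mask area and nuclear ground truth are consistent", {
  g <- embryo_geometry(300, 120, center = c(350, 400), angle = 0)
  em <- ellipse_mask(g, c(700, 800))
  expect_lt(abs(sum(em) - pi * 300 * 120) / (pi * 300 * 120), 0.02)

  sim <- render_embryo(embryo_geometry(300, 120, angle = 0),
                       pattern_spec(uniform_level(50)),
                       noise = list(sd = 0), seed = 2)
  # zero noise + uniform pattern: every ground-truth nuclear mean is 50
  expect_equal(sim$truth$nuclei$true_mean,
               rep(50, nrow(sim$truth$nuclei)))
  # nuclei respect the requested separation
  ctr <- sim$truth$nuclei
  dd <- as.matrix(dist(cbind(ctr$row, ctr$col)))
  diag(dd) <- Inf
  expect_gte(min(dd), 14)
})

test_that("rendering is deterministic under a fixed seed", {
  g <- embryo_geometry(200, 90, angle = 15)
  sp <- pattern_spec(ap_stripe(0.3, 0.05, 80), baseline = 4)
  s1 <- render_embryo(g, sp, nuclei = list(n = 80, radius = 4, min_sep = 11),
                      noise = list(sd = 8), seed = 42)
  s2 <- render_embryo(g, sp, nuclei = list(n = 80, radius = 4, min_sep = 11),
                      noise = list(sd = 8), seed = 42)
  expect_identical(s1$image$nuclear, s2$image$nuclear)
  expect_identical(s1$image$reporter, s2$image$reporter)
  expect_identical(s1$truth, s2$truth)
  s3 <- render_embryo(g, sp, nuclei = list(n = 80, radius = 4, min_sep = 11),
                      noise = list(sd = 8), seed = 43)
  expect_false(identical(s1$image$reporter, s3$image$reporter))
})

test_that("infeasible nucleus packing raises a generation error", {
  g <- embryo_geometry(60, 25, angle = 0)
  expect_error(
    render_embryo(g, pattern_spec(uniform_level(10)),
                  nuclei = list(n = 500, radius = 5, min_sep = 14),
                  seed = 1, max_tries = 20L),
    class = "ee_generation_error")
})

test_that("in-stripe nuclei measure at amplitude + baseline under noise", {
  amp <- 100; base <- 5
  g <- embryo_geometry(300, 120, angle = 0)
  sp <- pattern_spec(ap_stripe(0.35, 0.05, amp), baseline = base)
  sim <- render_embryo(g, sp, noise = list(sd = 5), seed = 9)
  msk <- mask_embryo(sim$image)
  fr <- resolve_anterior(fit_embryo_frame(msk), "left")
  rec <- measure_nuclei(segment_nuclei(sim$image$nuclear, msk, frame = fr),
                        sim$image$reporter)
  in_stripe <- rec[abs(rec$ap - 0.35) < 0.01, ]
  expect_gt(nrow(in_stripe), 3)
  n_px <- sum(in_stripe$area)
  se <- 5 / sqrt(n_px)
  # stripe crest value, allowing the within-nucleus curvature of the peak
  expect_lt(abs(mean(in_stripe$mean_reporter) - (amp + base)),
            3 * se + 0.02 * amp)
})

test_that("TIFF round trip preserves the rendered channels", {
  g <- embryo_geometry(80, 35, angle = 0)
  sim <- render_embryo(g, pattern_spec(uniform_level(900), baseline = 0),
                       nuclei = list(n = 15, radius = 3, min_sep = 8),
                       noise = list(sd = 10), seed = 4)
  stem <- tempfile()
  files <- write_embryo_sim(sim, stem)
  expect_true(all(file.exists(files)))
  img <- read_embryo_image(files[1], files[2])
  expect_equal(dim(img$nuclear), dim(sim$image$nuclear))
  # 16-bit quantization: within one grey level
  expect_lt(max(abs(img$nuclear - sim$image$nuclear)), 1.01)
  expect_lt(max(abs(img$reporter - sim$image$reporter)), 1.01)
})

test_that("simulated nucleus tables reflect the pattern at their centers", {
  sp <- pattern_spec(dv_band(0.6, 0.05, 100), baseline = 2)
  nuc <- simulate_nucleus_table(sp, spacing = 0.04, noise_sd = 0, seed = 3)
  expect_equal(nuc$mean_reporter,
               pattern_value(sp, nuc$ap, nuc$dv))
  expect_true(all(nuc$ap >= 0 & nuc$ap <= 1 & nuc$dv >= 0 & nuc$dv <= 1))
})
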