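# Stripe calling: binning, DV profiles, detection, membership, width.

test_that("AP binning partitions nuclei with the half-open rule", {
  nuc <- data.frame(id = 1:4, ap = c(0.1, 0.9, 0.5, 1.0),
                    dv = rep(0.5, 4), mean_reporter = 1)
  b1 <- bin_nuclei(nuc, bin_width = 1)
  expect_equal(nrow(b1$bins), 1)
  expect_equal(b1$assignment, rep(1L, 4))

  b2 <- bin_nuclei(nuc, bin_width = 0.5)
  expect_equal(b2$assignment[1:2], c(1L, 2L))
  # a nucleus exactly on a boundary joins the upper (right-open) bin
  expect_equal(b2$assignment[3], 2L)
  # ap = 1 stays in the last bin
  expect_equal(b2$assignment[4], 2L)

  b3 <- bin_nuclei(nuc, bin_width = 0.05)
  expect_equal(nrow(b3$bins), 20)
  expect_equal(b3$bins$lo, seq(0, 0.95, by = 0.05))
  # partition: every nucleus in exactly one bin
  expect_true(all(b3$assignment >= 1 & b3$assignment <= 20))

  expect_error(bin_nuclei(data.frame(ap = NA_real_, dv = 0.5), 0.1),
               class = "ee_input_error")
  expect_error(bin_nuclei(nuc, 0), class = "ee_input_error")
})

test_that("DV profiles track member intensities and flag empty bins", {
  nuc <- data.frame(id = 1:40, ap = rep(0.1, 40),
                    dv = seq(0.05, 0.95, length.out = 40),
                    mean_reporter = 5)
  bins <- bin_nuclei(nuc, 0.2)
  pr <- bin_dv_profile(bins, 1, nuc)
  expect_false(pr$empty)
  covered <- pr$grid > 0.1 & pr$grid < 0.9
  expect_true(all(abs(pr$value[covered] - 5) < 1e-9))

  # a bright cluster at DV 0.6 produces a unique maximum there
  nuc2 <- nuc
  nuc2$mean_reporter <- 5 + 100 * exp(-(nuc2$dv - 0.6)^2 / (2 * 0.03^2))
  pr2 <- bin_dv_profile(bin_nuclei(nuc2, 0.2), 1, nuc2)
  expect_lt(abs(pr2$grid[which.max(pr2$value)] - 0.6), 0.02)

  empty <- bin_dv_profile(bins, 4, nuc)
  expect_true(empty$empty)
  expect_equal(empty$n_members, 0L)
})

test_that("detection finds single and parallel stripes and nothing in noise-free uniform fields", {
  nuc <- fixture_stripe_nuclei(0.10, seed = 2, center = 0.60)
  st <- call_stripes(nuc)
  expect_length(st, 1)
  expect_true(all(abs(st[[1]]$trace$dv - 0.60) <= 0.02))

  sp2 <- pattern_spec(dv_band(0.4, 0.1 / FWHM_FACTOR, 100),
                      dv_band(0.7, 0.1 / FWHM_FACTOR, 100), baseline = 2)
  nuc2 <- simulate_nucleus_table(sp2, spacing = 0.02, noise_sd = 5, seed = 3)
  st2 <- call_stripes(nuc2)
  expect_length(st2, 2)
  dvs <- sort(vapply(st2, function(s) mean(s$trace$dv), numeric(1)))
  expect_lt(abs(dvs[1] - 0.4), 0.02)
  expect_lt(abs(dvs[2] - 0.7), 0.02)

  uni <- simulate_nucleus_table(pattern_spec(uniform_level(50)),
                                spacing = 0.02, seed = 4)
  expect_length(call_stripes(uni), 0)

  expect_error(detect_stripes(bin_nuclei(nuc, 0.5), nuc),
               class = "ee_input_error")
})

test_that("membership obeys the half-max rule and honors overrides", {
  nuc <- fixture_stripe_nuclei(0.10, seed = 5, center = 0.5)
  bins <- bin_nuclei(nuc, 0.05)
  traces <- detect_stripes(bins, nuc)
  expect_length(traces, 1)
  tr <- traces[[1]]
  members <- assign_membership(tr, bins, nuc)
  expect_gt(length(members), 50)
  # soundness: every member lies inside the trace's half-max interval at
  # its own AP position
  mrows <- nuc[nuc$id %in% members, ]
  iv <- embryoexpress:::trace_interval(tr, mrows$ap)
  expect_true(all(mrows$dv >= iv$lo - 1e-9 & mrows$dv <= iv$hi + 1e-9))
  # a nucleus at the peak is a member; one three half-widths away is not
  peak_bin_nuc <- nuc[abs(nuc$dv - 0.5) < 0.01, ]
  expect_true(any(peak_bin_nuc$id %in% members))
  far <- nuc[abs(nuc$dv - 0.5) > 0.3, ]
  expect_false(any(far$id %in% members))
  # overrides are verbatim
  drop_id <- members[1]
  add_id <- far$id[1]
  m2 <- assign_membership(tr, bins, nuc,
                          override = list(include = add_id,
                                          exclude = drop_id))
  expect_false(drop_id %in% m2)
  expect_true(add_id %in% m2)
})

test_that("width measurement is exact for degenerate lines and errors sensibly", {
  # one member per AP position on a perfect line: every segment width 0
  nuc <- data.frame(id = 1:21, ap = seq(0.2, 0.8, length.out = 21),
                    dv = 0.5, mean_reporter = 10)
  m <- measure_stripe(nuc$id, nuc, segment_length = 0.2)
  expect_equal(m$overall_width, 0)
  expect_equal(m$segments$width, rep(0, nrow(m$segments)))

  nuc1 <- data.frame(id = 1:3, ap = 0.4, dv = c(0.3, 0.5, 0.6),
                     mean_reporter = 1)
  expect_error(measure_stripe(nuc1$id, nuc1), class = "ee_degenerate_error")
  expect_error(measure_stripe(integer(0), nuc1), class = "ee_input_error")
})

test_that("measured widths recover generator truth and grow with the stripe", {
  widths <- vapply(c(0.05, 0.10, 0.15), function(w) {
    nuc <- fixture_stripe_nuclei(w, seed = 11, center = 0.6)
    st <- call_stripes(nuc)
    expect_length(st, 1)
    st[[1]]$measurement$overall_width
  }, numeric(1))
  spacing <- 0.02   # one nucleus diameter in normalized units
  expect_true(all(abs(widths - c(0.05, 0.10, 0.15)) <= spacing))
  # monotonicity
  expect_true(all(diff(widths) > 0))
})

test_that("width is measured perpendicular to the midline, not along DV", {
  nuc <- fixture_stripe_nuclei(0.10, seed = 8, center = 0.5)
  sheared <- rotate_nuclei(nuc, 20)
  st <- call_stripes(sheared)
  expect_length(st, 1)
  w <- st[[1]]$measurement$overall_width
  expect_lte(abs(w - 0.10), 0.02)
  # strictly less than the stripe's vertical (DV) extent
  members <- sheared[sheared$id %in% st[[1]]$members, ]
  expect_lt(w, diff(range(members$dv)))
})

test_that("rotating coordinates changes the mean width by less than 5%", {
  ratios <- vapply(1:10, function(i) {
    nuc <- fixture_stripe_nuclei(0.10, seed = 100 + i, center = 0.5)
    w0 <- call_stripes(nuc)[[1]]$measurement$overall_width
    wr <- call_stripes(rotate_nuclei(nuc, 20))[[1]]$measurement$overall_width
    c(w0, wr)
  }, numeric(2))
  expect_lt(abs(mean(ratios[2, ]) / mean(ratios[1, ]) - 1), 0.05)
})

test_that("stripe JSON export carries traces, members, and widths", {
  nuc <- fixture_stripe_nuclei(0.10, seed = 2, center = 0.6)
  st <- call_stripes(nuc)
  f <- tempfile(fileext = ".json")
  write_stripes_json(st, f)
  back <- jsonlite::read_json(f)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$overall_width, st[[1]]$measurement$overall_width)
  expect_equal(sort(unlist(back[[1]]$members)), st[[1]]$members)
})
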