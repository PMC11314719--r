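rmap_2x <- resolution_map(c(352, 352), c(704, 704))

test_that("displacement extraction rescales, interpolates and smooths", {
  # constant track stays constant
  tt <- seq(0, 1, by = 0.1)
  tr <- box_track(seq_along(tt), tt, cx = rep(100, 11), cy = rep(80, 11),
                  w = rep(50, 11), h = rep(6, 11),
                  window_resolution = c(352, 352))
  s <- extract_displacement(tr, rmap_2x)
  expect_equal(s$v_pos, rep(160, length(s$v_pos)))   # 80 * 704/352
  # a dropped frame is linearly interpolated at the midpoint
  tt2 <- seq(0, 1, by = 0.1)[-6]                     # t = 0.5 missing
  cy2 <- seq(100, 110, by = 1)[-6]
  tr2 <- box_track(seq_along(tt2), tt2, cx = rep(0, 10), cy = cy2,
                   w = rep(50, 10), h = rep(6, 10),
                   window_resolution = c(352, 352))
  s2 <- extract_displacement(tr2, rmap_2x, smoothing_window = 0)
  i5 <- which.min(abs(s2$time - 0.5))
  expect_equal(s2$v_raw[i5], 105 * 2, tolerance = 1e-9)
  # a long gap breaks the track with an informative error
  tt3 <- c(0, 0.1, 0.2, 0.8, 0.9)
  tr3 <- box_track(1:5, tt3, cx = rep(0, 5), cy = rep(0, 5),
                   w = rep(50, 5), h = rep(6, 5),
                   window_resolution = c(352, 352))
  expect_error(extract_displacement(tr3, rmap_2x), "track broken.*0\\.200")
})

test_that("moving-average smoothing attenuates a fast sine as predicted", {
  fps <- 100; f0 <- 1; win <- 0.05
  tt <- seq(0, 10, by = 1 / fps)
  cy <- 100 + 40 * sin(2 * pi * f0 * tt)
  tr <- box_track(seq_along(tt), tt, cx = rep(0, length(tt)), cy = cy,
                  w = rep(50, length(tt)), h = rep(6, length(tt)),
                  window_resolution = c(704, 704))
  s <- extract_displacement(tr, resolution_map(c(704, 704), c(704, 704)),
                            smoothing_window = win)
  mid <- s$v_pos[100:900]
  amp <- (max(mid) - min(mid)) / 2
  expect_gt(amp / 40, 0.98)   # window << period: < 2% attenuation
})

test_that("cycle detection counts sinusoid periods and ignores flat traces", {
  fps <- 50; tt <- seq(0, 10, by = 1 / fps)
  mk_series <- function(cy) {
    tr <- box_track(seq_along(tt), tt, cx = rep(0, length(tt)), cy = cy,
                    w = rep(50, length(tt)), h = rep(6, length(tt)),
                    window_resolution = c(704, 704))
    extract_displacement(tr, resolution_map(c(704, 704), c(704, 704)),
                         smoothing_window = 0.06)
  }
  # 10 full periods, starting and ending at the top
  cy <- 100 + 20 * (1 - cos(2 * pi * tt))
  cyc <- detect_cycles(mk_series(cy), min_amplitude_px = 10, warmup_s = 0)
  expect_equal(count_compressions(cyc), 10)
  expect_true(all(cyc$trough_time > cyc$peak_time &
                    cyc$trough_time < cyc$peak2_time))
  expect_true(all(cyc$amplitude_px > 0))
  # flat series has no cycles
  expect_equal(count_compressions(
    detect_cycles(mk_series(rep(100, length(tt))), min_amplitude_px = 10,
                  warmup_s = 0)), 0)
  # pixel noise below the threshold does not change the count
  set.seed(7)
  cyn <- detect_cycles(mk_series(cy + stats::rnorm(length(tt), 0, 1)),
                       min_amplitude_px = 10, warmup_s = 0)
  expect_equal(count_compressions(cyn), 10)
})

test_that("cycle counts agree with an independent peak finder", {
  set.seed(17)
  fps <- 50; tt <- seq(0, 20, by = 1 / fps)
  cy <- 100 + 25 * (1 - cos(2 * pi * 1.5 * tt)) + stats::rnorm(length(tt), 0, 0.8)
  tr <- box_track(seq_along(tt), tt, cx = rep(0, length(tt)), cy = cy,
                  w = rep(50, length(tt)), h = rep(6, length(tt)),
                  window_resolution = c(704, 704))
  s <- extract_displacement(tr, resolution_map(c(704, 704), c(704, 704)),
                            smoothing_window = 0.06)
  ours <- count_compressions(detect_cycles(s, min_amplitude_px = 12,
                                           warmup_s = 0))
  ref <- nrow(pracma::findpeaks(-s$v_pos, minpeakheight = -120,
                                minpeakdistance = round(0.3 * fps)))
  expect_equal(ours, 30)
  expect_equal(abs(ours - ref) <= 1, TRUE)
})

test_that("compression frequency is count per unit time", {
  cyc100 <- structure(data.frame(x = seq_len(100)),
                      class = c("compression_cycles", "data.frame"))
  expect_equal(compression_frequency(cyc100, 60), 100)
  cyc55 <- structure(data.frame(x = seq_len(55)),
                     class = c("compression_cycles", "data.frame"))
  expect_equal(compression_frequency(cyc55, 30), 110)
  empty <- structure(data.frame(), class = c("compression_cycles", "data.frame"))
  expect_equal(compression_frequency(empty, 10), 0)
  expect_error(compression_frequency(cyc55, 0), "duration")
})

test_that("simulated compressions are counted within tolerance", {
  sim <- simulate_track(scene_spec(), n_compressions = 100, seed = 1)
  m <- measure_track(sim$track, scene_spec()$cam, scene_spec()$rmap)
  expect_lte(abs(m$metrics$count - 100), 2)
})

test_that("cycle depths recover generated strokes through the geometry", {
  # noiseless 5 cm stroke at 50 cm with a 500 px focal length
  sp1 <- noiseless_spec(range_cm = 50, depth_cm = 5, fx = 500)
  sim1 <- simulate_track(sp1, n_compressions = 8, seed = 2)
  m1 <- measure_track(sim1$track, sp1$cam, sp1$rmap, sp1$marker_length_cm)
  expect_equal(m1$metrics$count, 8)
  expect_equal(m1$metrics$depths_cm, sim1$truth$depths_cm, tolerance = 1e-6)
  # 4 cm stroke at 75 cm with a 600 px focal length
  sp2 <- noiseless_spec(range_cm = 75, depth_cm = 4, fx = 600)
  sim2 <- simulate_track(sp2, n_compressions = 8, seed = 3)
  m2 <- measure_track(sim2$track, sp2$cam, sp2$rmap, sp2$marker_length_cm)
  expect_equal(m2$metrics$depths_cm, rep(4, 8), tolerance = 1e-6)
  # frames without marker-length observations flag depth unavailable
  cyc <- m2$cycles
  tr_nolen <- sim2$track
  tr_nolen$w <- NA_real_
  dep <- cycle_depths(cyc, tr_nolen, sp2$cam, sp2$rmap)
  expect_true(all(!dep$depth_available))
  expect_true(all(is.na(dep$depth_cm)))
  expect_equal(nrow(dep), nrow(cyc))
})

test_that("count and frequency are invariant to uniform pixel scaling", {
  sp <- noiseless_spec()
  sim <- simulate_track(sp, n_compressions = 10, seed = 5)
  s <- extract_displacement(sim$track, sp$rmap)
  c1 <- detect_cycles(s, min_amplitude_px = 12)
  lam <- 2.5
  s2 <- s
  s2$v_pos <- s$v_pos * lam
  s2$v_raw <- s$v_raw * lam
  c2 <- detect_cycles(s2, min_amplitude_px = 12 * lam)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c2$amplitude_px, c1$amplitude_px * lam, tolerance = 1e-9)
})

test_that("metrics conserve count = frequency * duration / 60", {
  cyc <- structure(data.frame(x = seq_len(37)),
                   class = c("compression_cycles", "data.frame"))
  m <- cpr_metrics(cyc, rep(5, 37), duration_s = 21.7)
  expect_equal(m$frequency_cpm * m$duration_s / 60, m$count,
               tolerance = 1e-9)
})

test_that("accuracy evaluation applies strict depth and inclusive count bounds", {
  mk <- function(depths, dur = 60) {
    cyc <- structure(data.frame(x = seq_along(depths)),
                     class = c("compression_cycles", "data.frame"))
    cpr_metrics(cyc, depths, dur)
  }
  truth <- mk(rep(5, 10))
  expect_equal(evaluate_accuracy(mk(rep(5, 10)), truth)$depth_accuracy, 1)
  expect_true(evaluate_accuracy(mk(rep(5, 10)), truth)$count_correct)
  # errors of exactly 1.0 cm count as failures (strict <)
  expect_equal(evaluate_accuracy(mk(rep(6, 10)), truth)$depth_accuracy, 0)
  # count tolerance is inclusive at 2
  expect_true(evaluate_accuracy(mk(rep(5, 8)), truth)$count_correct)
  expect_false(evaluate_accuracy(mk(rep(5, 7)), truth)$count_correct)
  expect_warning(evaluate_accuracy(mk(rep(5, 10), dur = 10), truth),
                 "durations differ")
})

test_that("box tracks survive a CSV round trip and reject malformed input", {
  sim <- simulate_track(scene_spec(), n_compressions = 5, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_box_track(sim$track, f)
  tr2 <- read_box_track(f)
  expect_equal(as.data.frame(tr2), as.data.frame(sim$track), tolerance = 1e-12)
  expect_equal(attr(tr2, "window_resolution"),
               attr(sim$track, "window_resolution"))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,cx,cy,w,h,conf",
               "1,0.0,10,20,50,6,0.9",
               "2,0.1,oops,20,50,6,0.9"), bad)
  expect_error(read_box_track(bad), "row 2")
})
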