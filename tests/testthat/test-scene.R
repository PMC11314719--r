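test_that("simulated tracks are deterministic and consistent with the spec", {
  sp <- scene_spec()
  a <- simulate_track(sp, n_compressions = 20, seed = 4)
  b <- simulate_track(sp, n_compressions = 20, seed = 4)
  expect_identical(a$track, b$track)
  expect_identical(a$truth$depths_cm, b$truth$depths_cm)
  # rate arithmetic: 100 compressions at 100 cpm span 60 s of compressions
  sp100 <- noiseless_spec(rate_cpm = 100)
  s <- simulate_track(sp100, n_compressions = 100, seed = 1)
  expect_equal(s$truth$count, 100)
  expect_equal(s$truth$duration_s, 60)
  expect_equal(s$truth$frequency_cpm, 100)
  # duration-driven interface
  s2 <- simulate_track(sp100, duration_s = 60, seed = 1)
  expect_equal(s2$truth$count, 100)
})

test_that("the noiseless closed loop recovers count, frequency and depth exactly", {
  sp <- noiseless_spec()
  sim <- simulate_track(sp, n_compressions = 15, seed = 1)
  m <- measure_track(sim$track, sp$cam, sp$rmap, sp$marker_length_cm)
  expect_equal(m$metrics$count, 15)
  expect_equal(m$metrics$frequency_cpm, sim$truth$frequency_cpm,
               tolerance = 1e-9)
  expect_equal(max(abs(m$metrics$depths_cm - sim$truth$depths_cm)), 0,
               tolerance = 1e-6)
})

test_that("rendered frames carry tight labels and honour clutter settings", {
  sp0 <- scene_spec(clutter = 0L, illum_jitter = 0)
  ds <- render_frames(sp0, 8, seed = 3, size = 96)
  expect_length(ds$images, 8)
  green <- c(0.35, 0.95, 0.25)
  for (f in seq_len(8)) {
    img <- ds$images[[f]]
    mask <- img[, , 1] == green[1] & img[, , 2] == green[2] &
      img[, , 3] == green[3]
    expect_gt(sum(mask), 0)
    # exactly one rectangle: the mask is a filled axis-aligned block
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    expect_equal(sum(mask), (diff(rows) + 1) * (diff(cols) + 1))
    # IoU between the label box and the rendered marker mask
    lab <- ds$labels[[f]]
    lb <- c(lab$cx - lab$w / 2, lab$cy - lab$h / 2,
            lab$cx + lab$w / 2, lab$cy + lab$h / 2) * 96
    mb <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
    iw <- min(lb[3], mb[3]) - max(lb[1], mb[1])
    ih <- min(lb[4], mb[4]) - max(lb[2], mb[2])
    inter <- max(0, iw) * max(0, ih)
    un <- (lb[3] - lb[1]) * (lb[4] - lb[2]) +
      (mb[3] - mb[1]) * (mb[4] - mb[2]) - inter
    expect_gte(inter / un, 0.95)
  }
})

test_that("rendered label files are byte-identical under the same seed", {
  sp <- scene_spec()
  d1 <- tempfile(); d2 <- tempfile()
  write_yolo_dataset(render_frames(sp, 3, seed = 11, size = 48), d1)
  write_yolo_dataset(render_frames(sp, 3, seed = 11, size = 48), d2)
  for (f in list.files(file.path(d1, "labels"))) {
    expect_identical(readBin(file.path(d1, "labels", f), "raw", 1e4),
                     readBin(file.path(d2, "labels", f), "raw", 1e4))
  }
})

test_that("augmentation multiplies the dataset with consistent labels", {
  sp <- scene_spec()
  ds <- render_frames(sp, 1, seed = 5, size = 48)
  aug <- augment(ds, factor = 6, seed = 1)
  expect_length(aug$images, 6)
  expect_length(aug$labels, 6)
  # variant order cycles rotate, hflip, vflip, scale, color
  expect_equal(aug$labels[[3]]$cx, 1 - ds$labels[[1]]$cx, tolerance = 1e-12)
  expect_equal(aug$labels[[4]]$cy, 1 - ds$labels[[1]]$cy, tolerance = 1e-12)
  expect_equal(aug$labels[[6]], ds$labels[[1]])   # colour keeps geometry
  # every augmented label stays inside the frame
  for (lab in aug$labels) {
    expect_true(all(lab$cx - lab$w / 2 >= -1e-9, lab$cx + lab$w / 2 <= 1 + 1e-9,
                    lab$cy - lab$h / 2 >= -1e-9, lab$cy + lab$h / 2 <= 1 + 1e-9))
  }
  ds10 <- render_frames(sp, 10, seed = 6, size = 48)
  expect_length(augment(ds10, factor = 6, seed = 2)$images, 60)
})

test_that("dataset splitting follows largest-remainder apportionment", {
  s <- split_dataset(8874, c(8, 1, 1), seed = 1)
  expect_equal(lengths(s), c(train = 7099L, test = 888L, val = 887L))
  s10 <- split_dataset(10, c(8, 1, 1), seed = 1)
  expect_equal(lengths(s10), c(train = 8L, test = 1L, val = 1L))
  # disjoint and exhaustive
  all_idx <- sort(c(s10$train, s10$test, s10$val))
  expect_equal(all_idx, 1:10)
  expect_identical(split_dataset(100, seed = 3), split_dataset(100, seed = 3))
  expect_error(split_dataset(0), "empty")
})

test_that("synthetic keypoint scenarios trigger their own posture rules", {
  correct <- synth_keypoints("correct", n_frames = 40, seed = 1)
  rep_c <- assess_posture(correct)
  expect_equal(unname(rep_c$fractions), c(0, 0, 0))
  nv <- synth_keypoints("non_vertical", n_frames = 40, seed = 2)
  per_nv <- assess_posture(nv)$per_frame
  expect_gte(mean(per_nv$non_vertical, na.rm = TRUE), 0.95)
  ok <- synth_keypoints("one_knee", n_frames = 40, seed = 3)
  expect_gte(mean(assess_posture(ok)$per_frame$one_knee, na.rm = TRUE), 0.95)
  da <- synth_keypoints("dark_arms", n_frames = 40, seed = 4)
  expect_gte(mean(assess_posture(da)$per_frame$low_visibility), 0.95)
  # determinism
  expect_identical(synth_keypoints("one_knee", 10, seed = 7),
                   synth_keypoints("one_knee", 10, seed = 7))
})
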