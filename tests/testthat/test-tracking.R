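test_that("frame schedule pairs every stride-th frame with one offset frames later", {
  s <- build_frame_schedule(90, fps = 30)
  expect_equal(s$reference_index, c(0, 30, 60))
  expect_equal(s$comparison_index, c(15, 45, 75))
  expect_equal(s$timestamp_s, c(0, 1, 2))

  s2 <- build_frame_schedule(100, fps = 30)
  expect_equal(nrow(s2), 3L)          # (90, 105) dropped
  expect_equal(max(s2$comparison_index), 75)

  expect_equal(nrow(build_frame_schedule(10, fps = 30)), 0L)
  expect_error(build_frame_schedule(0, 30), ">= 1")
  expect_error(build_frame_schedule(100, 30, ref_stride = 0), ">= 1")
})

test_that("frame difference is pixelwise absolute and rejects size mismatch", {
  f <- matrix(runif(64), 8, 8)
  expect_equal(frame_difference(f, f), matrix(0, 8, 8))
  expect_equal(frame_difference(matrix(0.2, 4, 4), matrix(0.7, 4, 4)),
               matrix(0.5, 4, 4))
  expect_error(frame_difference(matrix(0, 4, 4), matrix(0, 4, 5)),
               "dimensions")

  # blob at A in ref, at B in cmp: difference nonzero exactly on A union B
  ref <- frame_with_square(32, 32, top = 3, left = 3, size = 6)
  cmp <- frame_with_square(32, 32, top = 20, left = 22, size = 6)
  d <- frame_difference(ref, cmp)
  expected <- matrix(FALSE, 32, 32)
  expected[3:8, 3:8] <- TRUE
  expected[20:25, 22:27] <- TRUE
  expect_identical(d != 0, expected)
})

test_that("segmentation thresholds at Otsu's level and opening removes speckle", {
  expect_false(any(segment_motion(matrix(0, 16, 16))))

  # strongly bimodal difference image: threshold recovers exactly the blob
  d <- matrix(0.02, 40, 40)
  d[10:20, 12:22] <- 0.6
  mask <- segment_motion(d, opening_radius = 0)
  expect_identical(unname(which(mask, arr.ind = TRUE)),
                   unname(which(d == 0.6, arr.ind = TRUE)))
  # a radius-2 disc opening only rounds off the four rectangle corners
  mask2 <- segment_motion(d, opening_radius = 2)
  expect_equal(sum(mask) - sum(mask2), 4)

  # isolated pixel dies under a radius-2 opening; the blob survives
  d2 <- matrix(0, 30, 30)
  d2[5, 5] <- 0.9
  d2[15:22, 15:22] <- 0.9
  m2 <- segment_motion(d2, threshold = 0.5, opening_radius = 2)
  expect_false(m2[5, 5])
  expect_true(all(m2[17:20, 17:20]))

  expect_error(segment_motion(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("Otsu level maximizes between-class variance (exhaustive oracle)", {
  set.seed(11)
  for (k in 1:5) {
    x <- c(rnorm(3000, 0.05, 0.03), rnorm(500 * k, 0.55, 0.08))
    x <- matrix(pmin(1, pmax(0, x)), ncol = 50)
    expect_equal(otsu_threshold(x), oracle_otsu(x))
  }
})

test_that("centroid picks the largest 8-connected component, sub-pixel", {
  expect_true(all(is.na(locate_centroid(matrix(FALSE, 5, 5)))))

  m <- matrix(FALSE, 40, 40)
  m[21:23, 11:13] <- TRUE  # rows y = 20..22, cols x = 10..12
  expect_equal(locate_centroid(m), c(x = 11, y = 21))

  # two components, 50 px and 10 px: centroid of the larger one
  m2 <- matrix(FALSE, 40, 40)
  m2[3:12, 4:8] <- TRUE       # 50 px, x = 3..7, y = 2..11
  m2[30:34, 30:31] <- TRUE    # 10 px
  areas <- table(chamberchoice:::label_components8(m2)[m2])
  expect_setequal(as.integer(areas), c(50L, 10L))
  expect_equal(locate_centroid(m2), c(x = 5, y = 6.5))

  # diagonal contact merges into one component (8-connectivity)
  m3 <- matrix(FALSE, 10, 10)
  m3[2, 2] <- TRUE; m3[3, 3] <- TRUE; m3[4, 4] <- TRUE
  m3[8, 8] <- TRUE            # separate single pixel
  expect_equal(locate_centroid(m3), c(x = 2, y = 2))
})

test_that("difference ghost holds both positions and its centroid lies between them", {
  # congruent squares displaced diagonally: the symmetric difference is
  # centrally symmetric about the midpoint and 8-connected at the crossing
  # corners, so the centroid equals the midpoint exactly
  ref <- frame_with_square(40, 40, top = 11, left = 11, size = 10)
  cmp <- frame_with_square(40, 40, top = 17, left = 17, size = 10)
  d <- frame_difference(ref, cmp)
  cen <- locate_centroid(segment_motion(d, opening_radius = 0))
  a <- c(x = 14.5, y = 14.5)  # true blob centers (0-based)
  b <- c(x = 20.5, y = 20.5)
  expect_equal(cen, (a + b) / 2)

  # with the default opening the centroid still lies between the positions
  cen2 <- locate_centroid(segment_motion(d, opening_radius = 2))
  expect_true(all(cen2 >= a - 2.5 & cen2 <= b + 2.5))
})

test_that("tracking a rendered blob recovers its chamber and misses static video", {
  arena <- make_two_chamber_arena()
  # blob confined to the left chamber (p = 0, irritant on the right)
  r <- simulate_round(p = 0, irritant_side = "right", arena = arena,
                      duration = 20, fps = 10, seed = 3, render = TRUE,
                      params = render_params(fps = 10, noise_sd = 0),
                      ref_stride = 10L, offset = 5L)
  traj <- track_video(r$source, arena, ref_stride = 10L, offset = 5L)
  detected <- traj$side[traj$side != "missing"]
  expect_gt(length(detected), 0L)
  expect_true(all(detected == "left"))

  # completely static video: every pair missing
  still <- frame_with_square(60, 60, top = 20, left = 20, size = 10)
  src <- frame_source_list(rep(list(still), 30), fps = 10)
  sq <- make_arena(rbind(c(0, 0), c(59, 0), c(59, 59), c(0, 59)),
                   rbind(c(30, 0), c(30, 59)))
  traj2 <- track_video(src, sq, ref_stride = 10L, offset = 5L)
  expect_true(all(traj2$side == "missing"))
  expect_true(all(is.na(traj2$x)))
})

test_that("a divider crossing flips the reported side at the matching pair", {
  arena <- make_two_chamber_arena()
  n <- 100L
  pos <- cbind(c(rep(150, 50), rep(510, 50)),
               rep(150, n))  # jump left -> right between frames 49 and 50
  pos <- pos + cbind(rep(c(0, 3), n / 2), rep(c(0, 3), n / 2))  # motion
  src <- render_video(pos, render_params(fps = 10, noise_sd = 0), seed = 1)
  traj <- track_video(src, arena, ref_stride = 10L, offset = 5L)
  ok <- traj$side != "missing"
  expect_identical(traj$side[ok & traj$reference_index < 40],
                   rep("left", sum(ok & traj$reference_index < 40)))
  expect_identical(traj$side[ok & traj$reference_index >= 50],
                   rep("right", sum(ok & traj$reference_index >= 50)))
})

test_that("tracking is deterministic for identical inputs", {
  r <- simulate_round(p = 0.4, irritant_side = "left", duration = 15,
                      fps = 10, seed = 9, render = TRUE,
                      params = render_params(fps = 10),
                      ref_stride = 10L, offset = 5L)
  first <- track_video(r$source, r$arena, ref_stride = 10L, offset = 5L)
  second <- track_video(r$source, r$arena, ref_stride = 10L, offset = 5L)
  expect_identical(as.data.frame(first), as.data.frame(second))
})

test_that("trajectory CSV and overlay plot are written", {
  r <- simulate_round(p = 0.5, irritant_side = "left", duration = 10,
                      fps = 10, seed = 2, render = FALSE,
                      ref_stride = 10L, offset = 5L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(r$trajectory, csv)
  back <- read.csv(csv)
  expect_equal(names(back),
               c("reference_index", "timestamp_s", "x", "y", "side"))
  expect_equal(nrow(back), nrow(r$trajectory))

  fig <- withr::local_tempfile(fileext = ".png")
  counts <- plot_track(r$trajectory, r$arena, file = fig)
  expect_true(file.exists(fig))
  expect_equal(sum(counts), nrow(r$trajectory))
})
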