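test_that("degenerate preferences pin the animal to one chamber", {
  m1 <- occupancy_model(1, duration = 10, fps = 10, seed = 1)
  s1 <- simulate_occupancy(m1)
  expect_true(all(s1 == "irritant"))
  expect_identical(attr(s1, "fraction_irritant"), 1)

  m0 <- occupancy_model(0, duration = 10, fps = 10, seed = 1)
  expect_true(all(simulate_occupancy(m0) == "saline"))

  expect_error(occupancy_model(1.2), "\\[0, 1\\]")
  expect_error(occupancy_model(0.5, mean_dwell = -1), "positive")
})

test_that("occupancy fraction concentrates at the stationary probability", {
  # time-average variance of the stationary two-state chain:
  # 2 p (1-p) / (theta T), theta = 1/m_I + 1/m_S
  for (p in c(0.3, 0.5)) {
    sd_an <- occupancy_sd(p, mean_dwell = 20, duration = 3000)
    fr <- vapply(1:100, function(s) {
      m <- occupancy_model(p, mean_dwell = 20, duration = 3000, fps = 2,
                           seed = s)
      attr(simulate_occupancy(m), "fraction_irritant")
    }, numeric(1))
    expect_lt(abs(mean(fr) - p), 3 * sd_an / sqrt(100) * 4)
    expect_gte(mean(abs(fr - p) <= 2.5 * sd_an), 0.95)
    # empirical spread consistent with the analytic sd
    expect_gt(sd(fr), sd_an / 2)
    expect_lt(sd(fr), sd_an * 2)
  }
})

test_that("long-run occupancy approaches the closed-form stationary probability", {
  m <- occupancy_model(0.3, mean_dwell = 20, duration = 1e4, fps = 2,
                       seed = 1)
  fr <- attr(simulate_occupancy(m), "fraction_irritant")
  expect_lt(abs(fr - 0.3), 0.03)
})

test_that("simulated paths stay inside the arena and respect the chamber state", {
  arena <- make_two_chamber_arena()
  m <- occupancy_model(0.5, mean_dwell = 10, duration = 60, fps = 10,
                       seed = 4)
  states <- simulate_occupancy(m)
  sides <- ifelse(states == "irritant", "right", "left")
  pos <- simulate_path(sides, arena, fps = 10, seed = 4)
  lab <- classify_side(pos, arena)
  expect_true(all(lab != "outside"))

  # mismatches only within a bounded transit window per switch
  n_switch <- sum(sides[-1] != sides[-length(sides)])
  mismatch <- sum(lab != sides)
  expect_lte(mismatch, n_switch * 2 * 10)  # 2 s x fps frames per switch

  # zero speed: position constant within each dwell segment
  pos0 <- simulate_path(rep("left", 50), arena, speed = 0, fps = 10,
                        seed = 1)
  expect_equal(max(dist(pos0)), 0)

  expect_error(simulate_path(sides, arena, blob_radius = 200, fps = 10),
               "blob radius")
})

test_that("rendering is seeded, exact and correctly sized", {
  pos <- cbind(rep(150, 5), rep(150, 5))
  pr0 <- render_params(noise_sd = 0)
  src <- render_video(pos, pr0, seed = 1)
  f <- src$get_frame(0)
  expect_equal(dim(f), c(300, 660))

  # noiseless frame differs from background exactly on the ellipse support
  a <- pr0$blob_axes[1]; b <- pr0$blob_axes[2]
  xs <- matrix((0:659 - 150), 300, 660, byrow = TRUE)
  ys <- matrix((0:299 - 150), 300, 660)
  support <- xs^2 / a^2 + ys^2 / b^2 <= 1
  expect_identical(f != pr0$background, support)
  expect_true(all(f[support] == pr0$blob_level))

  # frame count = round(duration * fps)
  m <- occupancy_model(0.5, duration = 60, fps = 30, seed = 2)
  sides <- ifelse(simulate_occupancy(m) == "irritant", "right", "left")
  expect_length(sides, 1800L)

  # seeded reproducibility of the noise field
  prn <- render_params(noise_sd = 0.02)
  s1 <- render_video(pos, prn, seed = 7)
  s2 <- render_video(pos, prn, seed = 7)
  s3 <- render_video(pos, prn, seed = 8)
  expect_identical(s1$get_frame(3), s2$get_frame(3))
  expect_false(identical(s1$get_frame(3), s3$get_frame(3)))

  expect_error(render_params(background = 0.2, blob_level = 0.5), "darker")
  expect_error(render_video(cbind(5, 5),
                            render_params(width = 20, height = 20,
                                          blob_axes = c(18, 10)),
                            seed = 1)$get_frame(0), "fit")
})

test_that("PNG frame directories round-trip through the tracker input path", {
  pos <- cbind(seq(100, 180, length.out = 12), rep(150, 12))
  dir <- withr::local_tempdir()
  src <- render_video(pos, render_params(noise_sd = 0), seed = 1, dir = dir)
  expect_equal(src$n_frames, 12L)
  expect_length(list.files(dir, pattern = "\\.png$"), 12L)
  f_disk <- src$get_frame(0)
  f_mem <- render_video(pos, render_params(noise_sd = 0), seed = 1)$get_frame(0)
  expect_lt(max(abs(f_disk - f_mem)), 1 / 255)  # 8-bit quantization only
})

test_that("simulator ground truth agrees with arena classification off transit", {
  r <- simulate_round(p = 0.35, irritant_side = "right", duration = 60,
                      fps = 10, seed = 6, render = FALSE)
  fx <- r$truth$frames
  stable_frames <- fx$state == fx$side
  expect_gt(mean(stable_frames), 0.8)
  ref1 <- r$truth$pairs$reference_index + 1L
  # on stable pairs the recorded pair side equals geometric classification
  st <- r$truth$pairs$stable
  expect_identical(r$truth$pairs$side[st], fx$side[ref1][st])
  expect_equal(r$truth$occupancy_fraction,
               mean(r$truth$pairs$side == "right"))
})

test_that("cohorts follow the session design and are pure functions of the seed", {
  groups <- list(list(label = "WT", n = 3, preference = 0.3),
                 list(label = "KO", n = 3, preference = 0.5))
  cohort <- make_cohort(groups, time_points_h = c(0, 1), duration = 30,
                        fps = 10, seed = 11, render = FALSE)
  expect_length(cohort$sessions, 3 * 2 * 2)
  for (s in cohort$sessions) {
    expect_identical(s$rounds$baseline$p, 0.5)
    expect_false(s$rounds$swap$irritant_side ==
                   s$rounds$presentation$irritant_side)
    expect_identical(s$rounds$presentation$irritant_side, s$irritant_side)
    expect_null(s$rounds$presentation$source)
    expect_s3_class(s$rounds$presentation$trajectory, "trajectory")
  }
  # irritant side alternates across consecutive time points for each mouse
  md <- cohort$metadata
  pres <- md[md$round == "presentation", ]
  for (m in unique(pres$mouse_id)) {
    sides <- pres$irritant_side[pres$mouse_id == m]
    expect_identical(sides[1] != sides[2], TRUE)
  }

  scores1 <- score_cohort(cohort)
  cohort2 <- make_cohort(groups, time_points_h = c(0, 1), duration = 30,
                         fps = 10, seed = 11, render = FALSE)
  expect_identical(score_cohort(cohort2), scores1)
  cohort3 <- make_cohort(groups, time_points_h = c(0, 1), duration = 30,
                         fps = 10, seed = 12, render = FALSE)
  expect_false(identical(score_cohort(cohort3), scores1))
})

test_that("ground-truth cohort means track the preference parameters", {
  groups <- list(list(label = "avoider", n = 8, preference = 0.3),
                 list(label = "neutral", n = 8, preference = 0.5))
  cohort <- make_cohort(groups, time_points_h = 0, duration = 300,
                        fps = 5, seed = 3, render = FALSE)
  tab <- cohort_score_table(score_cohort(cohort))
  means <- tapply(tab$score, tab$group, mean)
  # per-mouse sd ~ occupancy_sd/sqrt(2 rounds); group mean of 8 mice
  tol <- 3 * occupancy_sd(0.4, 20, 300) / sqrt(2 * 8)
  expect_lt(abs(means[["avoider"]] - (-0.2)), tol)
  expect_lt(abs(means[["neutral"]] - 0), tol)
})
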