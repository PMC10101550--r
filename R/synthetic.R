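#' Default two-chamber arena geometry
#'
#' Builds the simulator's arena: two square chambers joined by a short
#' central passage, in top view. Defaults are 300 x 300 px chambers and a
#' 60 x 60 px passage, with the divider drawn vertically through the
#' passage center. The chamber and passage rectangles are attached as
#' attribute `geometry` for the path simulator.
#'
#' @param chamber_size side length of each square chamber, px.
#' @param passage_length gap between the chambers (passage length), px.
#' @param passage_width passage opening height, px.
#' @return an `arena_definition` with a `geometry` attribute.
#' @export
make_two_chamber_arena <- function(chamber_size = 300, passage_length = 60,
                                   passage_width = 60) {
  cs <- chamber_size; pl <- passage_length; pw <- passage_width
  if (pw >= cs) stop("passage wider than the chambers", call. = FALSE)
  y0 <- (cs - pw) / 2; y1 <- (cs + pw) / 2
  poly <- rbind(
    c(0, 0), c(cs, 0), c(cs, y0), c(cs + pl, y0), c(cs + pl, 0),
    c(2 * cs + pl, 0), c(2 * cs + pl, cs), c(cs + pl, cs),
    c(cs + pl, y1), c(cs, y1), c(cs, cs), c(0, cs))
  div <- rbind(c(cs + pl / 2, 0), c(cs + pl / 2, cs))
  arena <- make_arena(poly, div)
  attr(arena, "geometry") <- list(
    left = c(xmin = 0, xmax = cs, ymin = 0, ymax = cs),
    right = c(xmin = cs + pl, xmax = 2 * cs + pl, ymin = 0, ymax = cs),
    passage = c(xmin = cs, xmax = cs + pl, ymin = y0, ymax = y1),
    width = 2 * cs + pl, height = cs)
  arena
}

#' Two-state chamber-occupancy model
#'
#' The simulated animal alternates between the irritant and saline
#' chambers as a two-state continuous-time Markov chain. The preference
#' parameter `p` is the stationary probability of the irritant chamber;
#' `mean_dwell` is the mean of the two chambers' expected dwell times, so
#' the irritant and saline sojourn means are `2 p mean_dwell` and
#' `2 (1 - p) mean_dwell` and the stationary irritant fraction is exactly
#' `p`. `p` of 0 or 1 degenerates to a single-chamber chain.
#'
#' @param p stationary probability of the irritant chamber, in `[0, 1]`.
#' @param mean_dwell mean chamber dwell time, seconds.
#' @param duration session length, seconds (default 300: one 5-min round).
#' @param fps frames per second of the emulated recording.
#' @param seed integer seed.
#' @return an `occupancy_model` parameter list.
#' @export
occupancy_model <- function(p, mean_dwell = 20, duration = 300, fps = 30,
                            seed = 1L) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (mean_dwell <= 0 || duration <= 0 || fps <= 0)
    stop("mean_dwell, duration and fps must be positive", call. = FALSE)
  structure(list(p = p, mean_dwell = mean_dwell, duration = duration,
                 fps = fps, seed = as.integer(seed)),
            class = "occupancy_model")
}

#' Simulate the per-frame chamber state sequence
#'
#' Draws exponential sojourns from the two-state chain and samples the
#' state at every frame time `i / fps`. Reproducible: the sequence is a
#' pure function of the model (including its seed).
#'
#' @param model an [occupancy_model()].
#' @return character vector of length `round(duration * fps)` with values
#'   `"irritant"` / `"saline"`, with the exact per-frame bookkeeping
#'   attached as attribute `fraction_irritant`.
#' @export
simulate_occupancy <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  n <- round(model$duration * model$fps)
  p <- model$p
  set.seed(model$seed)
  if (p == 0 || p == 1) {
    states <- rep(if (p == 1) "irritant" else "saline", n)
  } else {
    m_irr <- 2 * p * model$mean_dwell
    m_sal <- 2 * (1 - p) * model$mean_dwell
    state <- if (stats::runif(1) < p) "irritant" else "saline"
    states <- character(n)
    t_now <- 0; i <- 1L
    total <- model$duration
    while (i <= n) {
      dwell <- stats::rexp(1, rate = 1 / if (state == "irritant") m_irr else m_sal)
      t_end <- min(t_now + dwell, total)
      # frames with time in [t_now, t_end)
      last <- min(n, ceiling(t_end * model$fps))
      if (last >= i) {
        states[i:last] <- state
        i <- last + 1L
      }
      t_now <- t_now + dwell
      state <- if (state == "irritant") "saline" else "irritant"
    }
  }
  attr(states, "fraction_irritant") <- mean(states == "irritant")
  states
}

#' Simulate a continuous path consistent with a chamber sequence
#'
#' Generates per-frame positions as a persistent (correlated) random walk
#' inside the current chamber's rectangle (inset by the blob radius): the
#' animal moves at `speed` with its heading diffusing at `turn_rate`, and
#' reflects off chamber walls. Directional persistence matches how mice
#' actually locomote and is what the frame-differencing tracker assumes —
#' over the 0.5-s pairing interval a moving animal typically displaces by
#' more than its own body length, so the two difference-image ghosts
#' separate. When the chamber state switches, the path is routed
#' deterministically through the passage at `max(speed, 220)` px/s along
#' the passage midline, so a switch completes — and the geometric side
#' matches the chamber state again — within 2 s.
#'
#' @param sides character vector, `"left"`/`"right"` chamber state per
#'   frame.
#' @param arena an arena from [make_two_chamber_arena()].
#' @param speed locomotion speed, px/s (0 = stationary within dwells).
#' @param turn_rate heading diffusion, rad per sqrt(second).
#' @param blob_radius inset from chamber walls (the blob's semi-major
#'   axis), px.
#' @param fps frames per second.
#' @param seed integer seed.
#' @return numeric matrix `n x 2` of `(x, y)` positions, one row per
#'   frame.
#' @export
simulate_path <- function(sides, arena, speed = 150, turn_rate = 2,
                          blob_radius = 18, fps = 30, seed = 1L) {
  geom <- attr(arena, "geometry")
  if (is.null(geom))
    stop("arena lacks simulator geometry; use make_two_chamber_arena()",
         call. = FALSE)
  rects <- list(left = geom$left, right = geom$right)
  m <- blob_radius + 2
  for (s in names(rects)) {
    r <- rects[[s]]
    if (r[["xmax"]] - r[["xmin"]] <= 2 * m || r[["ymax"]] - r[["ymin"]] <= 2 * m)
      stop("blob radius too large for the chamber", call. = FALSE)
    rects[[s]] <- c(xmin = r[["xmin"]] + m, xmax = r[["xmax"]] - m,
                    ymin = r[["ymin"]] + m, ymax = r[["ymax"]] - m)
  }
  ymid <- (geom$passage[["ymin"]] + geom$passage[["ymax"]]) / 2
  entry <- list(left = c(rects$left[["xmax"]], ymid),
                right = c(rects$right[["xmin"]], ymid))
  n <- length(sides)
  set.seed(seed)
  pos <- matrix(NA_real_, n, 2L)
  cur <- c(mean(rects[[sides[1L]]][c("xmin", "xmax")]),
           mean(rects[[sides[1L]]][c("ymin", "ymax")]))
  heading <- stats::runif(1, 0, 2 * pi)
  step <- speed / fps
  turn_sd <- turn_rate / sqrt(fps)
  transit_step <- max(speed, 220) / fps
  in_rect <- function(pt, r)
    pt[1L] >= r[["xmin"]] && pt[1L] <= r[["xmax"]] &&
    pt[2L] >= r[["ymin"]] && pt[2L] <= r[["ymax"]]
  for (i in seq_len(n)) {
    target <- rects[[sides[i]]]
    if (in_rect(cur, target)) {
      if (step > 0) {
        heading <- heading + stats::rnorm(1, 0, turn_sd)
        nxt <- cur + step * c(cos(heading), sin(heading))
        # reflect off chamber walls, folding the heading with the wall
        if (nxt[1L] < target[["xmin"]] || nxt[1L] > target[["xmax"]]) {
          heading <- pi - heading
          nxt[1L] <- if (nxt[1L] < target[["xmin"]])
            2 * target[["xmin"]] - nxt[1L] else 2 * target[["xmax"]] - nxt[1L]
        }
        if (nxt[2L] < target[["ymin"]] || nxt[2L] > target[["ymax"]]) {
          heading <- -heading
          nxt[2L] <- if (nxt[2L] < target[["ymin"]])
            2 * target[["ymin"]] - nxt[2L] else 2 * target[["ymax"]] - nxt[2L]
        }
        nxt[1L] <- min(max(nxt[1L], target[["xmin"]]), target[["xmax"]])
        nxt[2L] <- min(max(nxt[2L], target[["ymin"]]), target[["ymax"]])
        cur <- nxt
      }
    } else {
      # transit: leave via own entry point, cross on the passage midline,
      # then enter the target chamber at its entry point
      budget <- transit_step
      while (budget > 0) {
        waypoint <- if (in_rect(cur, rects$left)) {
          entry$left                      # head to the left-side opening
        } else if (in_rect(cur, rects$right)) {
          entry$right
        } else if (sides[i] == "right") {
          entry$right                     # inside the passage, keep going
        } else {
          entry$left
        }
        # once at the opening midline, the waypoint beyond is the far entry
        if (sqrt(sum((cur - waypoint)^2)) < 1e-9)
          waypoint <- if (sides[i] == "right") entry$right else entry$left
        delta <- waypoint - cur
        dist <- sqrt(sum(delta^2))
        if (dist <= budget) {
          cur <- waypoint
          budget <- budget - dist
          if (in_rect(cur, target)) break
        } else {
          cur <- cur + delta / dist * budget
          budget <- 0
        }
      }
    }
    pos[i, ] <- cur
  }
  colnames(pos) <- c("x", "y")
  pos
}

#' Rendering parameters for the synthetic video
#'
#' The renderer emulates the assay's recording conditions: a lightly
#' illuminated (light) background with a single dark elliptical blob for
#' the animal, plus optional per-pixel Gaussian noise.
#'
#' @param width,height frame size, px (defaults match
#'   [make_two_chamber_arena()]).
#' @param fps frames per second.
#' @param background background intensity in `(0, 1]`.
#' @param blob_level blob intensity; must be darker than the background.
#' @param blob_axes ellipse semi-axes `(a, b)` in px (x and y).
#' @param noise_sd per-pixel Gaussian noise standard deviation (0 = none).
#' @return a `render_params` list.
#' @export
render_params <- function(width = 660, height = 300, fps = 30,
                          background = 0.8, blob_level = 0.15,
                          blob_axes = c(18, 10), noise_sd = 0.02) {
  if (blob_level >= background)
    stop("blob must be darker than the background", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, background = background,
                 blob_level = blob_level, blob_axes = blob_axes,
                 noise_sd = noise_sd),
            class = "render_params")
}

# per-frame seed derivation: distinct, reproducible, independent of the
# order frames are rendered in; kept below 2^31
derive_seed <- function(seed, counter) {
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 +
                as.numeric(counter) * 104729) %% 2147483647)
}

render_frame <- function(pos, params, frame_index, seed) {
  f <- matrix(params$background, params$height, params$width)
  a <- params$blob_axes[1L]; b <- params$blob_axes[2L]
  if (a >= params$width / 2 || b >= params$height / 2)
    stop("blob does not fit in the frame", call. = FALSE)
  cx <- pos[1L]; cy <- pos[2L]
  colr <- max(1L, floor(cx - a) + 1L):min(params$width, ceiling(cx + a) + 1L)
  rowr <- max(1L, floor(cy - b) + 1L):min(params$height, ceiling(cy + b) + 1L)
  xs <- (colr - 1) - cx
  ys <- (rowr - 1) - cy
  ell <- outer(ys^2 / b^2, xs^2 / a^2, "+") <= 1
  sub <- f[rowr, colr, drop = FALSE]
  sub[ell] <- params$blob_level
  f[rowr, colr] <- sub
  if (params$noise_sd > 0) {
    set.seed(derive_seed(seed, frame_index))
    f <- f + matrix(stats::rnorm(length(f), 0, params$noise_sd),
                    nrow(f), ncol(f))
    rng <- range(f)
    if (rng[1L] < 0 || rng[2L] > 1) f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Render a synthetic session video
#'
#' Draws a dark filled ellipse at each true position on a light
#' background, with optional per-pixel Gaussian noise. The same seed gives
#' bit-identical frames. Frames are exposed lazily as a `frame_source`
#' (each frame is a pure function of `(positions, params, seed)`), or
#' written as a numbered-PNG directory when `dir` is given.
#'
#' @param positions `n x 2` matrix of per-frame `(x, y)` blob centers.
#' @param params a [render_params()] object.
#' @param seed integer seed for the noise field.
#' @param dir optional output directory for `frame_%06d.png` files.
#' @return a `frame_source` (lazy when `dir` is `NULL`, directory-backed
#'   otherwise).
#' @export
render_video <- function(positions, params = render_params(), seed = 1L,
                         dir = NULL) {
  n <- nrow(positions)
  src <- new_frame_source(
    n_frames = n, fps = params$fps, width = params$width,
    height = params$height,
    get_frame = function(i) render_frame(positions[i + 1L, ], params, i, seed))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n) - 1L) {
      png::writePNG(src$get_frame(i),
                    file.path(dir, sprintf("frame_%06d.png", i)))
    }
    return(frame_source_dir(dir, fps = params$fps))
  }
  src
}

#' Simulate one exposure round with ground truth
#'
#' Chains the occupancy model, path simulator and (optionally) the
#' renderer into one ground-truthed round. In ground-truth-only mode no
#' frames are produced; instead a `trajectory` of track-point-equivalent
#' records (true position and geometric side at each reference frame) is
#' emitted, which feeds the scoring module directly.
#'
#' @param p preference for the irritant chamber (stationary probability).
#' @param irritant_side `"left"` or `"right"`.
#' @param arena an arena from [make_two_chamber_arena()].
#' @param duration seconds (default 300).
#' @param fps frames per second.
#' @param mean_dwell mean chamber dwell, seconds.
#' @param speed locomotion speed, px/s.
#' @param turn_rate heading diffusion, rad per sqrt(second).
#' @param seed integer seed (fanned out to occupancy / path / noise).
#' @param render logical: render frames (lazily) or ground-truth-only.
#' @param params a [render_params()] object (when rendering).
#' @param ref_stride,offset schedule parameters used for the pair-level
#'   ground truth.
#' @return a `synthetic_round` list: `source` (`frame_source` or `NULL`),
#'   `trajectory` (ground-truth-only mode), `truth` (see below),
#'   `irritant_side`, `p`, and the arena. `truth` holds per-frame `x`,
#'   `y`, chamber `state` and geometric `side`, the pair table with
#'   per-pair true sides and a `stable` flag (state equal at both frames
#'   of the pair), and `occupancy_fraction`: the exact fraction of
#'   pair-times in the irritant chamber.
#' @export
simulate_round <- function(p, irritant_side = "right", arena = NULL,
                           duration = 300, fps = 30, mean_dwell = 20,
                           speed = 150, turn_rate = 2, seed = 1L,
                           render = TRUE,
                           params = NULL, ref_stride = 30L, offset = 15L) {
  if (is.null(arena)) arena <- make_two_chamber_arena()
  geom <- attr(arena, "geometry")
  if (is.null(params))
    params <- render_params(width = geom$width, height = geom$height,
                            fps = fps)
  model <- occupancy_model(p, mean_dwell = mean_dwell, duration = duration,
                           fps = fps, seed = derive_seed(seed, 1L))
  states <- simulate_occupancy(model)
  other <- if (irritant_side == "left") "right" else "left"
  sides <- ifelse(states == "irritant", irritant_side, other)
  pos <- simulate_path(sides, arena, speed = speed, turn_rate = turn_rate,
                       blob_radius = params$blob_axes[1L], fps = fps,
                       seed = derive_seed(seed, 2L))
  geo_side <- classify_side(pos, arena)
  sched <- build_frame_schedule(length(sides), fps, ref_stride, offset)
  ref1 <- sched$reference_index + 1L
  cmp1 <- sched$comparison_index + 1L
  pair_side <- sides[ref1]
  pairs <- data.frame(reference_index = sched$reference_index,
                      comparison_index = sched$comparison_index,
                      side = pair_side,
                      stable = sides[ref1] == sides[cmp1] &
                        geo_side[ref1] == sides[ref1] &
                        geo_side[cmp1] == sides[cmp1],
                      stringsAsFactors = FALSE)
  truth <- list(
    frames = data.frame(frame = seq_along(sides) - 1L,
                        x = pos[, 1L], y = pos[, 2L],
                        state = sides, side = geo_side,
                        stringsAsFactors = FALSE),
    pairs = pairs,
    occupancy_fraction = mean(pair_side == irritant_side))
  out <- list(arena = arena, irritant_side = irritant_side, p = p,
              truth = truth, params = params, source = NULL,
              trajectory = NULL, seed = seed)
  if (render) {
    out$source <- render_video(pos, params, seed = derive_seed(seed, 3L))
  } else {
    out$trajectory <- trajectory(sched$reference_index,
                                 x = pos[ref1, 1L], y = pos[ref1, 2L],
                                 side = geo_side[ref1], fps = fps)
  }
  class(out) <- "synthetic_round"
  out
}

#' Write a simulated round's ground truth to CSV
#'
#' Columns `frame, x, y, chamber` (the model's chamber state mapped to its
#' geometric side).
#'
#' @param round a `synthetic_round`.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(round, path) {
  df <- round$truth$frames
  utils::write.csv(data.frame(frame = df$frame, x = df$x, y = df$y,
                              chamber = df$state),
                   path, row.names = FALSE)
  invisible(path)
}

#' Simulate a full cohort study
#'
#' Generates a complete synthetic study: for each group, each mouse and
#' each time point, a session of three rounds — a saline/saline baseline
#' (preference 0.5), an irritant presentation, and a side-swapped round
#' with the irritant in the opposite chamber. The presentation side is
#' chosen (seeded) at the first time point and alternates across
#' subsequent time points. A single global seed fans out to per-round
#' sub-seeds by a fixed counter scheme, so the whole cohort is a pure
#' function of its specification and seed.
#'
#' @param groups list of group specs: `list(label =, n =, preference =)`
#'   where `preference` is a single value or one per time point.
#' @param time_points_h time-point labels, hours.
#' @param duration round length, seconds.
#' @param fps frames per second.
#' @param seed global integer seed.
#' @param render logical; `FALSE` (ground-truth-only, the fast test
#'   profile) emits trajectories instead of frames.
#' @param dir optional directory: writes per-round PNG frame directories
#'   (when rendering), ground-truth CSVs and a `metadata.yaml`.
#' @param ... further arguments to [simulate_round()].
#' @return a `synthetic_cohort`: list with `sessions` (each carrying
#'   group, mouse_id, time_point_h, irritant_side and the three
#'   `synthetic_round`s) and `metadata` (one data-frame row per round).
#' @export
make_cohort <- function(groups, time_points_h = c(0, 1, 6), duration = 300,
                        fps = 30, seed = 1L, render = FALSE, dir = NULL,
                        ...) {
  stopifnot(length(groups) >= 1L)
  sessions <- list()
  meta <- list()
  counter <- 0L
  for (g in groups) {
    stopifnot(g$n >= 1L)
    prefs <- rep_len(g$preference, length(time_points_h))
    for (mi in seq_len(g$n)) {
      mouse_id <- sprintf("%s_m%02d", g$label, mi)
      counter <- counter + 1L
      set.seed(derive_seed(seed, 100000L + counter))
      side0 <- sample(c("left", "right"), 1L)
      for (ti in seq_along(time_points_h)) {
        # irritant chamber alternates between consecutive sessions
        pres_side <- if ((ti %% 2L) == 1L) side0 else
          setdiff(c("left", "right"), side0)
        rounds <- list()
        specs <- list(
          baseline = list(p = 0.5, side = pres_side),
          presentation = list(p = prefs[ti], side = pres_side),
          swap = list(p = prefs[ti],
                      side = setdiff(c("left", "right"), pres_side)))
        for (rn in names(specs)) {
          counter <- counter + 1L
          rounds[[rn]] <- simulate_round(
            p = specs[[rn]]$p, irritant_side = specs[[rn]]$side,
            duration = duration, fps = fps,
            seed = derive_seed(seed, counter), render = render, ...)
          meta[[length(meta) + 1L]] <- data.frame(
            group = g$label, mouse_id = mouse_id,
            time_point_h = time_points_h[ti], round = rn,
            irritant_side = specs[[rn]]$side, p = specs[[rn]]$p,
            stringsAsFactors = FALSE)
        }
        sessions[[length(sessions) + 1L]] <- list(
          group = g$label, mouse_id = mouse_id,
          time_point_h = time_points_h[ti], irritant_side = pres_side,
          rounds = rounds)
      }
    }
  }
  cohort <- structure(list(sessions = sessions,
                           metadata = do.call(rbind, meta)),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, render = render)
  cohort
}

write_cohort <- function(cohort, dir, render = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(sessions = list())
  for (s in cohort$sessions) {
    sdir <- file.path(dir, s$mouse_id,
                      sprintf("t%gh", s$time_point_h))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    entry <- list(mouse_id = s$mouse_id, group = s$group,
                  time_point_h = s$time_point_h, rounds = list())
    for (rn in names(s$rounds)) {
      r <- s$rounds[[rn]]
      gt_path <- file.path(sdir, paste0(rn, "_ground_truth.csv"))
      write_ground_truth(r, gt_path)
      video_path <- NA_character_
      if (render && !is.null(r$source)) {
        video_path <- file.path(sdir, paste0(rn, "_frames"))
        render_video(r$truth$frames[, c("x", "y")] |> as.matrix(),
                     r$params, seed = derive_seed(r$seed, 3L),
                     dir = video_path)
      }
      entry$rounds[[rn]] <- list(round = rn, irritant_side = r$irritant_side,
                                 p = r$p, video = video_path,
                                 ground_truth = gt_path)
    }
    meta$sessions[[length(meta$sessions) + 1L]] <- entry
  }
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Score every session of a synthetic cohort
#'
#' In ground-truth-only mode the simulator's track-point records are scored
#' directly; with `track = TRUE` each rendered round is first run through
#' [track_video()], exercising the full pipeline.
#'
#' @param cohort a `synthetic_cohort`.
#' @param track run the frame-differencing tracker on rendered rounds.
#' @param ... tracker arguments (threshold, opening_radius, ...).
#' @return a score table: `rbind` of per-session [score_session()] rows.
#' @export
score_cohort <- function(cohort, track = FALSE, ...) {
  rows <- lapply(cohort$sessions, function(s) {
    trajs <- lapply(s$rounds, function(r) {
      if (track) {
        if (is.null(r$source)) stop("cohort was not rendered", call. = FALSE)
        track_video(r$source, r$arena, ...)
      } else {
        if (is.null(r$trajectory))
          stop("no ground-truth trajectories; use track = TRUE", call. = FALSE)
        r$trajectory
      }
    })
    score_session(trajs, irritant_side = s$irritant_side,
                  mouse_id = s$mouse_id, group = s$group,
                  time_point_h = s$time_point_h)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Per-mouse time-point score table for group statistics
#'
#' Aggregates a cohort score table to one centered score per mouse and
#' time point (mean of the presentation and swap rounds) in the layout
#' [compare_groups()] expects.
#'
#' @param scores score table from [score_cohort()].
#' @return data frame with columns `mouse`, `group`, `time`, `score`.
#' @export
cohort_score_table <- function(scores) {
  df <- as.data.frame(scores)
  df <- df[df$round %in% c("presentation", "swap"), , drop = FALSE]
  agg <- stats::aggregate(centered_score ~ mouse_id + group + time_point_h,
                          data = df, FUN = mean)
  data.frame(mouse = agg$mouse_id, group = agg$group,
             time = factor(agg$time_point_h), score = agg$centered_score,
             stringsAsFactors = FALSE)
}
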