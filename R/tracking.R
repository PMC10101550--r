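#' Build the paired reference/comparison frame schedule
#'
#' The tracker designates every `ref_stride`-th frame as a reference frame
#' (0-based indices 0, `ref_stride`, 2 `ref_stride`, ...) and pairs each
#' with a comparison frame `offset` frames later. At the defaults
#' (`ref_stride = 30`, `offset = 15`) on a 30 fps recording, one frame per
#' second is compared with the frame 0.5 s later. Pairs whose comparison
#' index would fall past the end of the video are dropped.
#'
#' @param n_frames total number of frames in the video (>= 1).
#' @param fps frames per second.
#' @param ref_stride spacing between reference frames, in frames.
#' @param offset reference-to-comparison gap, in frames.
#' @return a `frame_schedule` object: data frame with columns
#'   `reference_index`, `comparison_index`, `timestamp_s`
#'   (= reference_index / fps), plus `fps`, `ref_stride`, `offset`
#'   attributes. May have zero rows for very short videos.
#' @examples
#' build_frame_schedule(90, fps = 30)  # pairs (0,15), (30,45), (60,75)
#' @export
build_frame_schedule <- function(n_frames, fps = 30, ref_stride = 30L,
                                 offset = 15L) {
  if (n_frames < 1 || ref_stride < 1 || offset < 1 || fps <= 0)
    stop("n_frames, ref_stride, offset must be >= 1 and fps > 0", call. = FALSE)
  refs <- seq.int(0L, n_frames - 1L, by = as.integer(ref_stride))
  cmps <- refs + as.integer(offset)
  keep <- cmps <= n_frames - 1L
  sched <- data.frame(reference_index = refs[keep],
                      comparison_index = cmps[keep],
                      timestamp_s = refs[keep] / fps)
  structure(sched, fps = fps, ref_stride = as.integer(ref_stride),
            offset = as.integer(offset),
            class = c("frame_schedule", "data.frame"))
}

#' Absolute intensity difference between two frames
#'
#' Pixelwise `|comparison - reference|` on `[0, 1]` grayscale frames. For a
#' moving dark animal the brightest regions of the result mark the areas of
#' most change: the animal's position in *both* frames (the "old + new"
#' ghost), so a centroid of the difference lies between the two true
#' positions.
#'
#' @param reference,comparison numeric matrices of equal dimension in
#'   `[0, 1]`.
#' @return numeric matrix of the same dimension.
#' @export
frame_difference <- function(reference, comparison) {
  if (!identical(dim(reference), dim(comparison)))
    stop("frame dimensions differ", call. = FALSE)
  abs(comparison - reference)
}

#' Segment the moving animal from a difference image
#'
#' Thresholds the difference image into a binary mask, then removes
#' segmentation speckle with a morphological opening (disc structuring
#' element). The default threshold is Otsu's between-class-variance
#' criterion computed on the difference image; a fixed level in `(0, 1)`
#' may be supplied instead. A flat (e.g. all-zero) difference image yields
#' an empty mask.
#'
#' @param diff difference image in `[0, 1]`.
#' @param threshold `"otsu"` or a fixed numeric level.
#' @param opening_radius disc radius in pixels for the opening (0 disables).
#' @return logical matrix mask, with the threshold actually used attached as
#'   attribute `threshold`.
#' @export
segment_motion <- function(diff, threshold = "otsu", opening_radius = 2L) {
  rng <- range(diff)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("difference image must lie in [0, 1]", call. = FALSE)
  if (identical(threshold, "otsu")) {
    if (rng[2L] == rng[1L]) {
      thr <- rng[2L]  # flat image: nothing exceeds it
    } else {
      thr <- otsu_threshold(diff, levels = 256L)
    }
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- diff > thr
  if (opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    # opening is local: run it on the foreground bounding box (padded by
    # the brush radius) and paste back, identical to opening the full frame
    ij <- which(mask, arr.ind = TRUE)
    pad <- as.integer(opening_radius) + 1L
    r0 <- max(1L, min(ij[, 1L]) - pad); r1 <- min(nrow(mask), max(ij[, 1L]) + pad)
    c0 <- max(1L, min(ij[, 2L]) - pad); c1 <- min(ncol(mask), max(ij[, 2L]) + pad)
    sub <- EBImage::opening(mask[r0:r1, c0:c1, drop = FALSE] + 0, brush) > 0.5
    mask[] <- FALSE
    mask[r0:r1, c0:c1] <- sub
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Otsu's threshold on a difference image
#'
#' Histogram-based maximization of the between-class variance over
#' `levels` equal-width bins on `[0, 1]`: the returned level `t` maximizes
#' `w0 w1 (mu0 - mu1)^2` for the split `x <= t` vs `x > t`, with ties
#' broken toward the lowest level. Intended for binarizing the
#' frame-difference image, where the histogram is strongly bimodal
#' (near-zero background change vs the moving animal).
#'
#' @param x numeric matrix or vector with values in `[0, 1]`.
#' @param levels number of histogram bins.
#' @return the threshold level (scalar in `[0, 1]`).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  L <- as.integer(levels)
  counts <- tabulate(pmin(L, floor(as.numeric(x) * L) + 1L), nbins = L)
  n <- sum(counts)
  mids <- (seq_len(L) - 0.5) / L
  w0 <- cumsum(counts)[-L]
  m0 <- cumsum(counts * mids)[-L]
  w1 <- n - w0
  mu_t <- sum(counts * mids)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, L - 1L)
  bcv[valid] <- (mu_t * w0[valid] / n - m0[valid])^2 /
    ((w0[valid] / n) * (w1[valid] / n))
  t_best <- which.max(bcv)
  t_best / L
}

#' Label connected components with 8-connectivity
#'
#' `EBImage::bwlabel()` labels 4-connected components; diagonal-only
#' contacts split a blob. This wrapper merges labels that touch diagonally
#' so components are 8-connected, matching the single-blob assumption of
#' the tracker.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # down-right
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # up-right
  )
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1L))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Centroid of the segmented animal
#'
#' Returns the sub-pixel centroid (mean pixel coordinate, 0-based, `x` =
#' column, `y` = row) of the largest 8-connected component of a binary
#' mask, or missing (`c(NA, NA)`) for an empty mask. Area ties are broken
#' by the smallest top-left bounding-box corner (lexicographic on x, then
#' y).
#'
#' @param mask logical matrix.
#' @return numeric `c(x, y)` or `c(NA, NA)`.
#' @export
locate_centroid <- function(mask) {
  if (!any(mask)) return(c(x = NA_real_, y = NA_real_))
  # labelling is local: restrict to the foreground bounding box
  fg <- which(mask, arr.ind = TRUE)
  r0 <- min(fg[, 1L]); c0 <- min(fg[, 2L])
  sub <- mask[r0:max(fg[, 1L]), c0:max(fg[, 2L]), drop = FALSE]
  lab <- label_components8(sub)
  ij <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[ij]
  x <- (ij[, 2L] + c0 - 1L) - 1; y <- (ij[, 1L] + r0 - 1L) - 1
  areas <- tabulate(labs)
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    xmin <- vapply(best, function(l) min(x[labs == l]), numeric(1L))
    ymin <- vapply(best, function(l) min(y[labs == l]), numeric(1L))
    best <- best[order(xmin, ymin)][1L]
  }
  sel <- labs == best
  c(x = mean(x[sel]), y = mean(y[sel]))
}

#' Track the animal through a recording
#'
#' Runs the full frame-differencing tracker over a frame source: for each
#' reference/comparison pair in the schedule, compute the absolute
#' difference, binarize it, clean the mask with a morphological opening,
#' take the centroid of the largest component and classify it into the
#' left or right chamber of the arena. Pairs with no detectable motion
#' (e.g. a stationary animal) yield a missing centroid; missing points are
#' recorded as such, never carried forward.
#'
#' @param source a `frame_source` (see [frame_source_dir()]), or a path to
#'   a PNG frame directory.
#' @param arena an [make_arena()] object.
#' @param ref_stride,offset schedule parameters in frames.
#' @param threshold `"otsu"` (default) or a fixed level in `(0, 1)`.
#' @param opening_radius disc radius in pixels for the morphological
#'   opening.
#' @param verbose log per-video side counts and the mean Otsu threshold.
#' @return a `trajectory`: data frame with one row per schedule pair and
#'   columns `reference_index`, `timestamp_s`, `x`, `y`, `side`
#'   (`"left"`, `"right"`, `"outside"` or `"missing"`), with video
#'   metadata and the parameters used attached as attributes.
#' @export
track_video <- function(source, arena, ref_stride = 30L, offset = 15L,
                        threshold = "otsu", opening_radius = 2L,
                        verbose = FALSE) {
  if (is.character(source)) source <- frame_source_dir(source)
  stopifnot(inherits(source, "frame_source"), inherits(arena, "arena_definition"))
  if (source$n_frames < 1L) stop("video has zero frames", call. = FALSE)
  sched <- build_frame_schedule(source$n_frames, source$fps, ref_stride, offset)
  n <- nrow(sched)
  x <- y <- rep(NA_real_, n)
  side <- rep("missing", n)
  thr_used <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ref <- to_grayscale(source$get_frame(sched$reference_index[k]))
    cmp <- to_grayscale(source$get_frame(sched$comparison_index[k]))
    d <- frame_difference(ref, cmp)
    mask <- segment_motion(d, threshold = threshold,
                           opening_radius = opening_radius)
    thr_used[k] <- attr(mask, "threshold")
    cen <- locate_centroid(mask)
    if (!is.na(cen[1L])) {
      x[k] <- cen[1L]; y[k] <- cen[2L]
      side[k] <- classify_side(c(cen[1L], cen[2L]), arena)
    }
  }
  traj <- new_trajectory(
    data.frame(reference_index = sched$reference_index,
               timestamp_s = sched$timestamp_s, x = x, y = y,
               side = side, stringsAsFactors = FALSE),
    n_frames = source$n_frames, fps = source$fps,
    width = source$width, height = source$height,
    params = list(ref_stride = as.integer(ref_stride),
                  offset = as.integer(offset), threshold = threshold,
                  opening_radius = as.integer(opening_radius)),
    mean_threshold = if (n) mean(thr_used) else NA_real_)
  if (verbose) {
    counts <- side_point_counts(traj)
    message(sprintf(
      "tracked %d pairs | left %d right %d outside %d missing %d | mean threshold %.4f",
      n, counts[["left"]], counts[["right"]], counts[["outside"]],
      counts[["missing"]], attr(traj, "mean_threshold")))
  }
  traj
}

new_trajectory <- function(df, n_frames, fps, width, height, params,
                           mean_threshold = NA_real_) {
  structure(df, n_frames = as.integer(n_frames), fps = fps,
            width = width, height = height, params = params,
            mean_threshold = mean_threshold,
            class = c("trajectory", "data.frame"))
}

#' Construct a trajectory from track-point records
#'
#' Builds a `trajectory` object directly from per-pair records — the form
#' the tracker emits — for ground-truth-only simulations or hand-built
#' fixtures. `side` must be `"missing"` exactly where the centroid is
#' missing.
#'
#' @param reference_index integer frame indices (0-based, increasing).
#' @param timestamp_s timestamps in seconds (defaults to index / `fps`).
#' @param x,y centroid coordinates (NA for missed detections).
#' @param side one of `"left"`, `"right"`, `"outside"`, `"missing"` per
#'   point.
#' @param fps frames per second of the nominal recording.
#' @return a `trajectory` object.
#' @export
trajectory <- function(reference_index, x, y, side, fps = 30,
                       timestamp_s = reference_index / fps) {
  side <- as.character(side)
  stopifnot(all(side %in% c("left", "right", "outside", "missing")),
            length(x) == length(reference_index),
            length(side) == length(reference_index))
  if (!all((side == "missing") == is.na(x)))
    stop("side must be 'missing' exactly where the centroid is missing",
         call. = FALSE)
  if (is.unsorted(reference_index, strictly = TRUE))
    stop("reference_index must be strictly increasing", call. = FALSE)
  n_frames <- if (length(reference_index)) max(reference_index) + 1L else 0L
  new_trajectory(
    data.frame(reference_index = as.integer(reference_index),
               timestamp_s = timestamp_s, x = x, y = y, side = side,
               stringsAsFactors = FALSE),
    n_frames = n_frames, fps = fps, width = NA, height = NA,
    params = list())
}

#' @export
print.trajectory <- function(x, ...) {
  counts <- side_point_counts(x)
  cat(sprintf("trajectory: %d track points (left %d, right %d, outside %d, missing %d)\n",
              nrow(x), counts[["left"]], counts[["right"]],
              counts[["outside"]], counts[["missing"]]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns `reference_index, timestamp_s, x, y, side`, one row per schedule
#' pair.
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("reference_index", "timestamp_s",
                                           "x", "y", "side")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Overlay tracked centroids on the arena
#'
#' Draws the arena outline and divider with each detected centroid colored
#' by chamber (cyan = left, magenta = right, gray = outside), the standard
#' visual check that side counts reflect where the animal actually was.
#'
#' @param traj a `trajectory`.
#' @param arena the `arena_definition` it was tracked against.
#' @param file optional PNG path; if `NULL`, draws on the current device.
#' @param ... passed to [graphics::points()].
#' @return invisibly, the per-side point counts shown.
#' @export
plot_track <- function(traj, arena, file = NULL, ...) {
  stopifnot(inherits(arena, "arena_definition"))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  poly <- arena$polygon
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  graphics::plot(NA, xlim = xr + c(-10, 10), ylim = rev(yr + c(-10, 10)),
                 asp = 1, xlab = "x (px)", ylab = "y (px)",
                 main = "tracked centroids by chamber")
  graphics::polygon(poly[, 1L], poly[, 2L], border = "black", lwd = 2)
  graphics::lines(arena$divider[, 1L], arena$divider[, 2L],
                  col = "gray40", lty = 2, lwd = 2)
  cols <- c(left = "cyan3", right = "magenta3", outside = "gray60")
  ok <- !is.na(traj$x)
  if (any(ok))
    graphics::points(traj$x[ok], traj$y[ok], pch = 19, cex = 0.6,
                     col = cols[traj$side[ok]], ...)
  counts <- side_point_counts(traj)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("%s (%d)", names(cols),
                                    counts[names(cols)]),
                   col = cols, pch = 19)
  invisible(counts)
}
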