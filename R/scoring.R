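#' Per-side track-point counts
#'
#' Tallies a trajectory's points into left / right / outside / missing.
#' Counts always sum to the number of track points. With the default
#' schedule (one pair per second) a count is directly a number of seconds.
#'
#' @param traj a `trajectory`.
#' @return named integer vector `c(left, right, outside, missing)`.
#' @export
side_point_counts <- function(traj) {
  lv <- c("left", "right", "outside", "missing")
  out <- table(factor(traj$side, levels = lv))
  stats::setNames(as.integer(out), lv)
}

#' Behavior score of one exposure round
#'
#' The behavior score of a round is the fraction of assigned track points
#' the animal spent in the irritant chamber, re-centered by subtracting 0.5
#' so that 0 is indifference, negative values are avoidance and positive
#' values preference. Only points assigned to a chamber enter the ratio:
#' the denominator is `left + right` (irritant chamber + saline chamber);
#' outside/missing points carry no side information and are excluded from
#' numerator and denominator alike.
#'
#' @param traj a `trajectory`.
#' @param irritant_side `"left"` or `"right"`: the chamber whose nebulizer
#'   holds the irritant for this round (for a saline/saline baseline round,
#'   the nominal side the next round will use).
#' @return a `behavior_score` object: list with `raw_fraction` in `[0, 1]`,
#'   `centered` in `[-0.5, 0.5]`, `n_assigned`, `n_missing`,
#'   `irritant_side`.
#' @examples
#' tr <- trajectory(0:3, x = c(1, 1, 9, 9), y = rep(1, 4),
#'                  side = c("left", "left", "right", "right"))
#' behavior_score(tr, "right")  # raw 0.5, centered 0: indifference
#' @export
behavior_score <- function(traj, irritant_side = c("left", "right")) {
  irritant_side <- match.arg(irritant_side)
  counts <- side_point_counts(traj)
  n_assigned <- counts[["left"]] + counts[["right"]]
  if (n_assigned == 0L)
    stop("unscorable round: no track points assigned to either chamber",
         call. = FALSE)
  raw <- counts[[irritant_side]] / n_assigned
  # integer numerator over a common denominator keeps irritant-side
  # relabelling exactly antisymmetric in floating point
  centered <- (2 * counts[[irritant_side]] - n_assigned) / (2 * n_assigned)
  structure(list(raw_fraction = raw, centered = centered,
                 n_assigned = n_assigned,
                 n_missing = counts[["missing"]],
                 irritant_side = irritant_side),
            class = "behavior_score")
}

#' @export
print.behavior_score <- function(x, ...) {
  verdict <- if (x$centered < 0) "avoidance" else if (x$centered > 0)
    "preference" else "indifference"
  cat(sprintf(
    "behavior score: raw %.3f, centered %+.3f (%s of %s chamber; %d assigned, %d missing)\n",
    x$raw_fraction, x$centered, verdict, x$irritant_side, x$n_assigned,
    x$n_missing))
  invisible(x)
}

#' Aggregate the two irritant rounds of a time point
#'
#' Each time point comprises a presentation round and a side-swapped round
#' (the irritant nebulizer moved to the opposite chamber to cancel
#' chamber-specific bias). The per-mouse score at the time point is the
#' mean of the two rounds' centered scores, each computed against its own
#' irritant side. Both rounds must be scorable; there is no silent
#' single-round fallback.
#'
#' @param presentation,swap `behavior_score` objects for the two rounds.
#' @return the aggregated centered score (numeric scalar).
#' @export
aggregate_time_point <- function(presentation, swap) {
  if (!inherits(presentation, "behavior_score") ||
      !inherits(swap, "behavior_score"))
    stop("both rounds must be scorable behavior_score objects", call. = FALSE)
  if (presentation$irritant_side == swap$irritant_side)
    stop("swap round must use the opposite irritant side", call. = FALSE)
  mean(c(presentation$centered, swap$centered))
}

#' Score a full session (baseline + presentation + swap)
#'
#' A session is one mouse at one time point: a saline/saline baseline
#' round, an irritant presentation round, and a side-swapped round. The
#' baseline is scored against the presentation round's irritant side as a
#' nominal label and reported separately — it is never pooled with
#' irritant scores.
#'
#' @param trajectories named list with elements `baseline`, `presentation`,
#'   `swap`, each a `trajectory`.
#' @param irritant_side `"left"` or `"right"`: the presentation round's
#'   irritant chamber (the swap round uses the opposite side).
#' @param mouse_id,group,time_point_h metadata carried into the score rows.
#' @return a `session_record`: data frame with one row per round and
#'   columns `mouse_id, group, time_point_h, round, irritant_side,
#'   n_assigned, n_missing, raw_fraction, centered_score`, with the
#'   aggregated time-point score as attribute `time_point_score`.
#' @export
score_session <- function(trajectories, irritant_side,
                          mouse_id = "m1", group = "group",
                          time_point_h = 0) {
  stopifnot(all(c("baseline", "presentation", "swap") %in% names(trajectories)))
  other <- if (irritant_side == "left") "right" else "left"
  sides <- c(baseline = irritant_side, presentation = irritant_side,
             swap = other)
  rounds <- c("baseline", "presentation", "swap")
  scores <- lapply(rounds, function(r)
    behavior_score(trajectories[[r]], sides[[r]]))
  names(scores) <- rounds
  df <- data.frame(
    mouse_id = mouse_id, group = group, time_point_h = time_point_h,
    round = rounds, irritant_side = unname(sides[rounds]),
    n_assigned = vapply(scores, function(s) s$n_assigned, numeric(1L)),
    n_missing = vapply(scores, function(s) s$n_missing, numeric(1L)),
    raw_fraction = vapply(scores, function(s) s$raw_fraction, numeric(1L)),
    centered_score = vapply(scores, function(s) s$centered, numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(df,
            time_point_score = aggregate_time_point(scores$presentation,
                                                    scores$swap),
            class = c("session_record", "data.frame"))
}

#' Cohort heat-map matrix of centered scores
#'
#' Builds the mice-by-rounds matrix of centered behavior scores shown as a
#' heat map: one row per mouse, columns the irritant rounds (presentation
#' and swap, per time point when several are present). Rendered with a
#' diverging palette — gray at 0 (indifference), blue negative
#' (avoidance), red positive (preference) — saturating at -0.5 / +0.5.
#'
#' @param scores a score table as produced by [score_session()] /
#'   [score_cohort()] (rows for baseline rounds are dropped).
#' @param file optional PNG path for the rendered figure.
#' @return the numeric score matrix (mice x rounds), invisibly carrying
#'   the color limits as attribute `limits`.
#' @export
build_heatmap <- function(scores, file = NULL) {
  df <- as.data.frame(scores)
  df <- df[df$round != "baseline", , drop = FALSE]
  if (nrow(df) == 0L) stop("no irritant rounds to plot", call. = FALSE)
  df$col_key <- paste(format(df$time_point_h, trim = TRUE), df$round,
                      sep = "h/")
  mice <- unique(df$mouse_id)
  cols <- unique(df$col_key)
  m <- matrix(NA_real_, length(mice), length(cols),
              dimnames = list(mice, cols))
  m[cbind(match(df$mouse_id, mice), match(df$col_key, cols))] <-
    df$centered_score
  if (!is.null(file)) {
    grDevices::png(file, width = 160 + 60 * ncol(m),
                   height = 120 + 24 * nrow(m))
    on.exit(grDevices::dev.off())
    render_heatmap(m)
  }
  attr(m, "limits") <- c(-0.5, 0.5)
  invisible(m)
}

#' @rdname build_heatmap
#' @param m a centered-score matrix from [build_heatmap()].
#' @export
render_heatmap <- function(m) {
  pal <- heatmap_palette(255L)
  op <- graphics::par(mar = c(6, 6, 3, 2))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-0.5, 0.5), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = "centered behavior score per mouse and round")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1)
  graphics::box()
  invisible(m)
}

#' Diverging score palette: blue (avoidance) - gray (0) - red (preference)
#' @param n number of colors.
#' @return character vector of colors.
#' @export
heatmap_palette <- function(n = 255L) {
  grDevices::colorRampPalette(c("#2166AC", "#808080", "#B2182B"))(n)
}

#' Map a centered score to its heat-map color
#'
#' @param score centered scores in `[-0.5, 0.5]`.
#' @param n palette resolution.
#' @return character vector of colors; exactly the palette midpoint (gray)
#'   at score 0 when `n` is odd.
#' @export
score_color <- function(score, n = 255L) {
  pal <- heatmap_palette(n)
  idx <- pmin(n, pmax(1L, 1L + floor((score + 0.5) / 1 * (n - 1L) + 0.5)))
  pal[idx]
}

#' Write a score table to CSV
#'
#' @param scores score table (`session_record` rows or their rbind).
#' @param path output CSV path.
#' @export
write_scores <- function(scores, path) {
  cols <- c("mouse_id", "group", "time_point_h", "round", "irritant_side",
            "n_assigned", "n_missing", "raw_fraction", "centered_score")
  utils::write.csv(as.data.frame(scores)[, cols], path, row.names = FALSE)
  invisible(path)
}
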