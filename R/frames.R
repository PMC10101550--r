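#' Frame sources
#'
#' The tracker reads video through a small frame-source abstraction: an
#' object that knows the frame count, frame rate and size, and returns any
#' frame by 0-based index as a numeric matrix (rows = image rows / y,
#' columns = x) with intensities normalized to `[0, 1]`. Two constructors
#' are provided: a directory of numbered PNG frames (the exact-test path and
#' the simulator's on-disk format) and an in-memory list of matrices.
#' Color frames are converted to grayscale with standard luma weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path directory containing PNG frames; files are ordered by the
#'   first integer in their file names (e.g. `frame_000017.png`).
#' @param fps frames per second (nominal 30 for the assay recordings).
#' @return a `frame_source` object with fields `n_frames`, `fps`, `width`,
#'   `height`, and `get_frame(i)` taking a 0-based index.
#' @export
frame_source_dir <- function(path, fps = 30) {
  files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) stop("no PNG frames found in ", path, call. = FALSE)
  idx <- as.integer(sub(".*?([0-9]+)[^0-9]*\\.png$", "\\1", basename(files)))
  files <- files[order(idx)]
  first <- read_frame_png(files[[1L]])
  new_frame_source(
    n_frames = length(files), fps = fps,
    width = ncol(first), height = nrow(first),
    get_frame = function(i) read_frame_png(files[[i + 1L]])
  )
}

#' @rdname frame_source_dir
#' @param frames list of numeric matrices (equal dimensions) in `[0, 1]`.
#' @export
frame_source_list <- function(frames, fps = 30) {
  stopifnot(length(frames) >= 1L)
  d <- dim(frames[[1L]])
  new_frame_source(
    n_frames = length(frames), fps = fps, width = d[2L], height = d[1L],
    get_frame = function(i) frames[[i + 1L]]
  )
}

new_frame_source <- function(n_frames, fps, width, height, get_frame) {
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 width = as.integer(width), height = as.integer(height),
                 get_frame = get_frame),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("frame source: %d frames, %g fps, %d x %d px\n",
              x$n_frames, x$fps, x$width, x$height))
  invisible(x)
}

read_frame_png <- function(file) {
  img <- png::readPNG(file)
  to_grayscale(img)
}

# luma conversion for 3/4-channel arrays; pass-through for matrices
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    k <- dim(img)[3L]
    if (k >= 3L)
      return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
    return(img[, , 1L])
  }
  stop("unsupported image array", call. = FALSE)
}

#' Mirror a frame source or arena horizontally
#'
#' Utilities for symmetry checks: a horizontally flipped recording analysed
#' against the correspondingly flipped arena must give mirrored centroids
#' (`x -> width - 1 - x`) and swapped left/right sides, hence a negated
#' centered behavior score for a fixed irritant-side label.
#'
#' @param src a `frame_source`.
#' @param width frame width in pixels (for the arena flip).
#' @return a flipped `frame_source` / `arena_definition`.
#' @export
flip_frame_source <- function(src) {
  new_frame_source(src$n_frames, src$fps, src$width, src$height,
                   function(i) src$get_frame(i)[, src$width:1L, drop = FALSE])
}

#' @rdname flip_frame_source
#' @param arena an `arena_definition`.
#' @export
flip_arena <- function(arena, width) {
  poly <- arena$polygon; div <- arena$divider
  poly[, 1L] <- (width - 1) - poly[, 1L]
  div[, 1L] <- (width - 1) - div[, 1L]
  make_arena(poly, div)
}
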