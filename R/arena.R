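#' Arena definition for a two-chamber forced-choice device
#'
#' An arena is the region of the video frame where the animal can move,
#' described by a traced polygon plus a dividing line that splits it into a
#' left and a right chamber. Coordinates are continuous pixel positions with
#' the image convention: origin at the top-left corner, x increasing to the
#' right, y increasing downward.
#'
#' The divider is stored as a segment but classification uses its infinite
#' supporting line, so a hand-drawn divider need not span the full polygon.
#' With the divider oriented from its first to its second endpoint, the
#' half-plane on the negative-x side of the oriented line (in image
#' coordinates) is labelled `"left"`. Points with signed distance exactly
#' zero are assigned to the left chamber, so every interior point gets
#' exactly one label.
#'
#' @param polygon numeric matrix (or 2-column data frame) of at least 3
#'   polygon vertices, one `(x, y)` row per vertex, in tracing order. The
#'   polygon must be simple (non-self-intersecting) with nonzero area.
#' @param divider numeric 2x2 matrix: the two `(x, y)` endpoints of the
#'   dividing segment. Its supporting line must pass through the polygon
#'   interior.
#' @return An object of class `arena_definition` with elements `polygon`,
#'   `divider` and `side_labels`.
#' @examples
#' sq <- make_arena(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
#'                  rbind(c(50, 0), c(50, 100)))
#' classify_side(c(25, 50), sq)   # "left"
#' classify_side(c(150, 150), sq) # "outside"
#' @export
make_arena <- function(polygon, divider) {
  polygon <- as_coord_matrix(polygon, "polygon")
  divider <- as_coord_matrix(divider, "divider")
  if (nrow(polygon) < 3L)
    stop("geometry error: polygon needs at least 3 vertices", call. = FALSE)
  if (nrow(divider) != 2L)
    stop("geometry error: divider must be two endpoints", call. = FALSE)
  if (all(divider[1L, ] == divider[2L, ]))
    stop("geometry error: divider endpoints must be distinct", call. = FALSE)
  if (abs(polygon_area(polygon)) <= 0)
    stop("geometry error: polygon has zero area", call. = FALSE)
  if (polygon_self_intersects(polygon))
    stop("geometry error: polygon is self-intersecting", call. = FALSE)
  # the supporting line meets the interior iff vertices fall on both strict sides
  s <- divider_signed_distance(polygon[, 1L], polygon[, 2L], divider)
  if (!(any(s < 0) && any(s > 0)))
    stop("geometry error: divider line does not intersect the polygon interior",
         call. = FALSE)
  structure(list(polygon = polygon, divider = divider,
                 side_labels = c(negative = "left", positive = "right")),
            class = "arena_definition")
}

as_coord_matrix <- function(x, what) {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2L || anyNA(m))
    stop(sprintf("geometry error: %s must be a numeric n x 2 matrix", what),
         call. = FALSE)
  dimnames(m) <- NULL
  m
}

# shoelace formula; sign encodes orientation
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# proper-crossing test on all non-adjacent edge pairs
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_properly_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

segments_properly_cross <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Signed distance proxy to the oriented divider line: for divider A -> B,
# s = dy*(x - Ax) - dx*(y - Ay). s < 0 is the negative-x side of the oriented
# line in image coordinates, i.e. "left"; s = 0 ties go left.
divider_signed_distance <- function(x, y, divider) {
  dx <- divider[2L, 1L] - divider[1L, 1L]
  dy <- divider[2L, 2L] - divider[1L, 2L]
  dy * (x - divider[1L, 1L]) - dx * (y - divider[1L, 2L])
}

#' Classify points into arena sides
#'
#' Assigns each point to `"left"`, `"right"` or `"outside"`. A point outside
#' the polygon (even-odd rule, boundary points counted inside) is
#' `"outside"`; otherwise the side is given by the sign of its distance to
#' the divider's supporting line, with exact ties assigned to `"left"`.
#' This is a total function: every finite point receives exactly one label.
#'
#' @param point a length-2 `(x, y)` vector, or an n x 2 matrix of points.
#' @param arena an [make_arena()] object.
#' @return character vector of `"left"`, `"right"`, `"outside"`.
#' @export
classify_side <- function(point, arena) {
  stopifnot(inherits(arena, "arena_definition"))
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2L) else as_coord_matrix(point, "point")
  inside <- points_in_polygon(pts[, 1L], pts[, 2L], arena$polygon)
  s <- divider_signed_distance(pts[, 1L], pts[, 2L], arena$divider)
  out <- ifelse(!inside, "outside", ifelse(s <= 0, "left", "right"))
  as.character(out)
}

#' Even-odd point-in-polygon with boundary points counted inside
#'
#' Vectorized crossing-number test. A ray is cast toward +x from each query
#' point using half-open edge intervals so each crossing is counted once;
#' points lying exactly on a polygon edge are reported inside.
#'
#' @param x,y numeric coordinate vectors.
#' @param polygon vertex matrix as in [make_arena()].
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(x, y, polygon) {
  n <- nrow(polygon)
  px <- polygon[, 1L]; py <- polygon[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- rep(FALSE, length(x))
  onedge <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # boundary check: collinear and within the edge's bounding box
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on <- cr == 0 &
      x >= pmin(x1, x2) & x <= pmax(x1, x2) &
      y >= pmin(y1, y2) & y <= pmax(y1, y2)
    onedge <- onedge | on
    # half-open rule in y avoids double-counting vertex crossings
    crosses <- ((y1 <= y) != (y2 <= y))
    if (any(crosses)) {
      xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      flip <- crosses & (x < xi)
      inside <- xor(inside, flip)
    }
  }
  inside | onedge
}

#' Read or write an arena file
#'
#' Arenas are stored as YAML (or JSON) documents with two keys:
#' `polygon: [[x, y], ...]` and `divider: [[x1, y1], [x2, y2]]`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return [read_arena()] returns a validated `arena_definition`;
#'   [write_arena()] returns `path` invisibly.
#' @export
read_arena <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  coords <- function(x) {
    if (is.matrix(x)) return(apply(x, 2L, as.numeric))
    do.call(rbind, lapply(x, function(v) as.numeric(unlist(v))))
  }
  make_arena(coords(doc$polygon), coords(doc$divider))
}

#' @rdname read_arena
#' @param arena an `arena_definition`.
#' @export
write_arena <- function(arena, path) {
  stopifnot(inherits(arena, "arena_definition"))
  doc <- list(polygon = unname(apply(arena$polygon, 1L, as.numeric, simplify = FALSE)),
              divider = unname(apply(arena$divider, 1L, as.numeric, simplify = FALSE)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @export
print.arena_definition <- function(x, ...) {
  cat("Two-chamber arena definition\n")
  cat(sprintf("  polygon: %d vertices, area %.1f px^2\n",
              nrow(x$polygon), abs(polygon_area(x$polygon))))
  cat(sprintf("  divider: (%.1f, %.1f) -> (%.1f, %.1f)\n",
              x$divider[1L, 1L], x$divider[1L, 2L],
              x$divider[2L, 1L], x$divider[2L, 2L]))
  invisible(x)
}

#' Area of the arena polygon on each side of the divider
#'
#' Monte-Carlo-free helper used for sanity checks: clips the polygon against
#' the divider's supporting line (Sutherland-Hodgman) and returns the area of
#' the left and right pieces.
#'
#' @param arena an `arena_definition`.
#' @return named numeric vector `c(left =, right =)` in px^2.
#' @export
arena_side_areas <- function(arena) {
  clip_half <- function(keep_negative) {
    p <- arena$polygon
    n <- nrow(p)
    out <- list()
    s <- divider_signed_distance(p[, 1L], p[, 2L], arena$divider)
    keep <- if (keep_negative) s <= 0 else s >= 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- p[i, ]; b <- p[j, ]
      if (keep[i]) out[[length(out) + 1L]] <- a
      if (keep[i] != keep[j]) {
        t <- s[i] / (s[i] - s[j])
        out[[length(out) + 1L]] <- a + t * (b - a)
      }
    }
    if (length(out) < 3L) return(0)
    abs(polygon_area(do.call(rbind, out)))
  }
  c(left = clip_half(TRUE), right = clip_half(FALSE))
}
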