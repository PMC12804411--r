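#' Construct a vessel centerline
#'
#' A centerline is an ordered 3D polyline (mm) with its cumulative arc length.
#' It is the object on which segment length, the tortuosity index and the
#' planar tortuosity decomposition are computed.
#'
#' @param points numeric matrix, one row per point, 3 columns (x, y, z in mm).
#' @param frame_id label of the coordinate frame the points live in
#'   (e.g. "pre_straight_reference").
#' @return object of class `centerline` with elements `points`, `arc_length`
#'   (cumulative chord length, `arc_length[1] == 0`) and `frame_id`.
#' @export
centerline <- function(points, frame_id = "unspecified") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("centerline points must be an N x 3 matrix")
  if (nrow(points) < 2) stop("a centerline needs at least 2 points")
  storage.mode(points) <- "double"
  d <- row_norms(points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])
  if (any(d == 0)) {
    keep <- c(TRUE, d > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2) stop("centerline degenerate: all points coincide")
    d <- row_norms(points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])
  }
  structure(list(points = unname(points),
                 arc_length = c(0, cumsum(d)),
                 frame_id = frame_id),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %d points, length %.3f mm, frame '%s'>\n",
              nrow(x$points), curve_length(x), x$frame_id))
  invisible(x)
}

#' Centerline length
#'
#' Sum of consecutive Euclidean inter-point distances; equal by construction
#' to the last entry of the cumulative arc length.
#'
#' @param line a [centerline()].
#' @return length in mm.
#' @export
curve_length <- function(line) {
  stopifnot(inherits(line, "centerline"))
  line$arc_length[length(line$arc_length)]
}

#' Resample a centerline at uniform arc-length spacing
#'
#' Points are placed at equal arc-length steps along the polyline (linear
#' interpolation between original vertices); the first and last points are
#' preserved exactly, so the last interval may be shorter than `spacing`.
#'
#' @param line a [centerline()].
#' @param spacing target arc-length step in mm; must be positive and smaller
#'   than the total length.
#' @return resampled `centerline`.
#' @export
resample_uniform <- function(line, spacing) {
  stopifnot(inherits(line, "centerline"))
  total <- curve_length(line)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  if (spacing >= total) stop("spacing must be smaller than the curve length")
  # fast path: a polyline already uniform at the requested spacing (up to
  # the chordal-shortening scale, (spacing * curvature)^2 / 24 relative) is
  # returned unchanged, making resampling an exact fixed point
  gaps <- diff(line$arc_length)
  if (length(gaps) > 1 &&
      max(abs(gaps[-length(gaps)] - spacing)) < 1e-3 * spacing &&
      gaps[length(gaps)] <= spacing * (1 + 1e-3))
    return(line)
  s_new <- seq(0, total, by = spacing)
  if (s_new[length(s_new)] < total) s_new <- c(s_new, total)
  pts <- apply(line$points, 2, function(coord)
    stats::approx(line$arc_length, coord, xout = s_new, ties = "ordered")$y)
  pts[1, ] <- line$points[1, ]
  pts[nrow(pts), ] <- line$points[nrow(line$points), ]
  centerline(pts, frame_id = line$frame_id)
}

#' Moving-average smoothing of a centerline
#'
#' Each interior point is replaced by the mean of the window centred on it.
#' Endpoints are pinned and the window shrinks symmetrically near the
#' boundaries, so segment endpoints (and therefore segment cut points) do not
#' drift under smoothing.
#'
#' @param line a [centerline()].
#' @param window odd integer window size, `>= 3` and `<` number of points.
#' @return smoothed `centerline`.
#' @export
smooth_moving_average <- function(line, window = 5L) {
  stopifnot(inherits(line, "centerline"))
  window <- as.integer(window)
  n <- nrow(line$points)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (window < 3L) stop("smoothing window must be >= 3")
  if (window >= n) stop("smoothing window must be smaller than the number of points")
  half <- window %/% 2L
  out <- line$points
  for (i in seq(2L, n - 1L)) {
    h <- min(half, i - 1L, n - i)   # symmetric shrink near boundaries
    idx <- (i - h):(i + h)
    out[i, ] <- colMeans(line$points[idx, , drop = FALSE])
  }
  centerline(out, frame_id = line$frame_id)
}

# Sum of squared turning angles, used to verify smoothing reduces the
# discrete curvature energy.
curvature_energy <- function(line) {
  p <- line$points
  n <- nrow(p)
  if (n < 3) return(0)
  v <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  v <- v / row_norms(v)
  dots <- pmin(1, pmax(-1, rowSums(v[-nrow(v), , drop = FALSE] * v[-1, , drop = FALSE])))
  sum(acos(dots)^2)
}

#' Write a centerline as CSV
#'
#' Columns `x`, `y`, `z`, `arc_length` (all mm).
#'
#' @param line a [centerline()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(line, path) {
  stopifnot(inherits(line, "centerline"))
  df <- data.frame(x = line$points[, 1], y = line$points[, 2],
                   z = line$points[, 3], arc_length = line$arc_length)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline from CSV
#'
#' @param path CSV with columns `x`, `y`, `z` (mm).
#' @param frame_id coordinate frame label.
#' @return a [centerline()].
#' @export
read_centerline_csv <- function(path, frame_id = "unspecified") {
  df <- read.csv(path)
  centerline(as.matrix(df[, c("x", "y", "z")]), frame_id = frame_id)
}
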