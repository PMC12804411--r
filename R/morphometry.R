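#' Tortuosity index of a centerline
#'
#' The tortuosity index is the centerline arc length L divided by the
#' straight-line (chord) distance between its endpoints, minus one:
#' `T = L / chord - 1`. A perfectly straight vessel has T = 0; values grow
#' without bound as the vessel winds. The index is dimensionless and
#' invariant under rigid motions and uniform scaling.
#'
#' @param line a [centerline()] (2D polylines are accepted as N x 2 matrices
#'   via `tortuosity_of_points()` internally).
#' @return tortuosity index (>= 0).
#' @export
tortuosity_index <- function(line) {
  stopifnot(inherits(line, "centerline"))
  tortuosity_of_points(line$points)
}

# Works for N x d point matrices (d = 2 or 3); shared by the 3D index and
# the planar decomposition.
tortuosity_of_points <- function(points) {
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  d <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  L <- sum(d)
  chord <- sqrt(sum((points[n, ] - points[1, ])^2))
  if (chord < 1e-9)
    stop("coincident endpoints: chord undefined for the tortuosity index")
  L / chord - 1
}

#' Equivalent diameter of a cross-sectional area
#'
#' The vessel section is treated as perfectly circular, so the diameter is
#' derived from the area A as `D = 2 * sqrt(A / pi)`.
#'
#' @param area cross-sectional area in mm^2 (positive; vectorized).
#' @return equivalent diameter in mm.
#' @export
equivalent_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Mean vessel diameter over a set of cross-sections
#'
#' Simple arithmetic mean of the per-section equivalent diameters.
#'
#' @param sections list of `cross_section` objects (from [cross_sections()]).
#' @return mean diameter in mm.
#' @export
mean_diameter <- function(sections) {
  if (length(sections) == 0) stop("no cross-sections supplied")
  mean(vapply(sections, function(s) s$equivalent_diameter, numeric(1)))
}

# Intersect a plane (origin o, unit normal nrm) with a triangle mesh; returns
# loops of ordered 2D vertices in the plane basis (u, v), plus that basis.
plane_mesh_loops <- function(mesh, o, nrm) {
  u <- perpendicular_any(nrm)
  v <- cross3(nrm, u)
  vert <- mesh$vertices
  sd <- as.vector((vert - matrix(o, nrow(vert), 3, byrow = TRUE)) %*% nrm)
  # vertices exactly on the plane (plane through a mesh ring) are nudged to
  # one side so every intersection loop stays closed
  sd[sd == 0] <- 1e-9
  f <- mesh$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(list(loops = list(), u = u, v = v))
  fidx <- which(crossing)
  seg_a <- matrix(0, length(fidx), 2)
  seg_b <- matrix(0, length(fidx), 2)
  edge_point <- function(i, j, si, sj) {
    t <- si / (si - sj)
    p <- vert[i, ] + t * (vert[j, ] - vert[i, ])
    c(sum((p - o) * u), sum((p - o) * v))
  }
  for (k in seq_along(fidx)) {
    tf <- f[fidx[k], ]
    ss <- sd[tf]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      si <- ss[e[1]]; sj <- ss[e[2]]
      if ((si < 0) != (sj < 0))
        pts[[length(pts) + 1L]] <- edge_point(tf[e[1]], tf[e[2]], si, sj)
    }
    if (length(pts) >= 2) { seg_a[k, ] <- pts[[1]]; seg_b[k, ] <- pts[[2]] }
  }
  # chain segments into loops by matching endpoints on a rounded key
  key <- function(p) paste(round(p[1], 6), round(p[2], 6))
  ka <- apply(seg_a, 1, key); kb <- apply(seg_b, 1, key)
  nseg <- length(ka)
  used <- logical(nseg)
  nexts <- split(seq_len(nseg), ka)
  nexts_b <- split(seq_len(nseg), kb)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    loop <- list(seg_a[start, ])
    used[start] <- TRUE
    cur_key <- kb[start]; cur_pt <- seg_b[start, ]
    start_key <- ka[start]
    repeat {
      if (identical(cur_key, start_key)) break
      loop[[length(loop) + 1L]] <- cur_pt
      cand <- c(nexts[[cur_key]], nexts_b[[cur_key]])
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break        # open chain (tangent plane); drop
      nxt <- cand[1]
      used[nxt] <- TRUE
      if (identical(ka[nxt], cur_key)) {
        cur_key <- kb[nxt]; cur_pt <- seg_b[nxt, ]
      } else {
        cur_key <- ka[nxt]; cur_pt <- seg_a[nxt, ]
      }
    }
    if (length(loop) >= 3 && identical(cur_key, start_key))
      loops[[length(loops) + 1L]] <- do.call(rbind, loop)
  }
  list(loops = loops, u = u, v = v)
}

#' Cross-sections of a vessel surface perpendicular to its centerline
#'
#' Places planes at equal arc-length intervals along the centerline, each
#' perpendicular to the local tangent, and intersects them with the lumen
#' surface. Of all intersection loops only the one enclosing the centerline
#' point is kept (side branches/far wall re-entries are discarded). Polygon
#' vertices are ordered counter-clockwise about the plane normal and the
#' area is computed by the shoelace formula; the equivalent diameter follows
#' from the circular assumption.
#'
#' @param line a [centerline()] inside the surface.
#' @param mesh the lumen surface (`trimesh`).
#' @param step arc-length spacing of the planes, mm (default 5). If `step`
#'   exceeds the centerline length only the two end sections are produced.
#' @param end_offset sections are kept `end_offset` mm clear of the
#'   centerline ends so that end-cap tangency cannot produce degenerate
#'   polygons (default 0.5).
#' @return list of `cross_section` objects: `origin`, `normal`, `polygon`
#'   (2D vertices), `area`, `equivalent_diameter`, `arc_position`. Skipped
#'   (ambiguous/missed) planes are reported via attribute `n_skipped`.
#' @export
cross_sections <- function(line, mesh, step = 5, end_offset = 0.5) {
  stopifnot(inherits(line, "centerline"), inherits(mesh, "trimesh"))
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  total <- curve_length(line)
  s_planes <- seq(0, total, by = step)
  if (s_planes[length(s_planes)] < total) s_planes <- c(s_planes, total)
  off <- min(end_offset, total / 4)
  s_planes <- pmin(pmax(s_planes, off), total - off)
  pts <- line$points
  sarc <- line$arc_length
  interp_pt <- function(s) {
    vapply(1:3, function(j) stats::approx(sarc, pts[, j], xout = s,
                                          ties = "ordered")$y, numeric(1))
  }
  tangent_at <- function(s) {
    ds <- min(1, total / 10)
    unit_vector(interp_pt(min(s + ds, total)) - interp_pt(max(s - ds, 0)))
  }
  out <- list()
  n_skipped <- 0L
  for (s in s_planes) {
    o <- interp_pt(s)
    nrm <- tangent_at(s)
    pm <- plane_mesh_loops(mesh, o, nrm)
    containing <- Filter(function(lp) point_in_polygon(c(0, 0), lp), pm$loops)
    if (length(containing) != 1L) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("section at s = %.2f mm skipped (%d containing loops)",
                      s, length(containing)))
      next
    }
    poly <- containing[[1]]
    a_signed <- polygon_signed_area(poly)
    if (a_signed < 0) {                 # enforce counter-clockwise about normal
      poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
      a_signed <- -a_signed
    }
    out[[length(out) + 1L]] <- structure(
      list(origin = o, normal = nrm, polygon = poly, area = a_signed,
           equivalent_diameter = equivalent_diameter(a_signed),
           arc_position = s),
      class = "cross_section")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Split a centerline at an anatomical landmark
#'
#' Splits at the centerline point closest to the landmark (typically the
#' adductor hiatus, the anatomical boundary between the superficial femoral
#' and popliteal segments). The split vertex belongs to both halves, so the
#' two segment lengths add up to the full length exactly.
#'
#' @param line a [centerline()]; its first point is taken as the proximal end.
#' @param landmark 3D point in mm.
#' @param max_distance reject landmarks farther than this from the line (mm).
#' @return list with `sfa` (proximal part) and `pa` (distal part), both
#'   [centerline()]s, plus `split_index` and `split_distance`.
#' @export
split_at_landmark <- function(line, landmark, max_distance = 20) {
  stopifnot(inherits(line, "centerline"))
  d <- row_norms(line$points - matrix(landmark, nrow(line$points), 3, byrow = TRUE))
  i <- which(d == min(d))
  if (length(i) > 1) {
    warning("landmark equidistant from several centerline points; using the most proximal")
    i <- i[1]
  }
  if (d[i] > max_distance)
    stop(sprintf("landmark is %.1f mm from the centerline (> %g mm gate)", d[i], max_distance))
  n <- nrow(line$points)
  if (i <= 1 || i >= n)
    stop("landmark projects onto a centerline endpoint; nothing to split")
  list(sfa = centerline(line$points[1:i, , drop = FALSE], frame_id = line$frame_id),
       pa = centerline(line$points[i:n, , drop = FALSE], frame_id = line$frame_id),
       split_index = i, split_distance = d[i])
}
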