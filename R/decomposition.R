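#' Anatomical frame from the tibia axis
#'
#' Builds the orthonormal anatomical frame used for the tortuosity
#' decomposition. The tibia is an elongated rigid structure: its first
#' principal direction defines the superior-inferior axis, an anterior hint
#' vector (orthogonalized against it) defines the antero-posterior axis, and
#' the medio-lateral axis completes the right-handed triad.
#'
#' @param tibia_points N x 3 matrix (mm), e.g. tibia mesh vertices.
#' @param anterior_hint approximate anterior direction; must not be parallel
#'   to the tibia axis.
#' @param proximal_point optional 3D point towards the knee; when given, the
#'   tibia axis sign is chosen to point towards it (superior). Otherwise a
#'   deterministic sign convention (largest-magnitude component positive) is
#'   used; the decomposition itself is sign-invariant.
#' @return object of class `anatomical_frame`: `origin` (tibia centroid),
#'   `axis_tibia`, `axis_ap`, `axis_lat` (orthonormal, right-handed:
#'   `axis_tibia x axis_ap = axis_lat`).
#' @export
anatomical_frame <- function(tibia_points, anterior_hint, proximal_point = NULL) {
  tibia_points <- as.matrix(tibia_points)
  stopifnot(ncol(tibia_points) == 3, nrow(tibia_points) >= 3)
  pc <- stats::prcomp(tibia_points, center = TRUE, scale. = FALSE)
  var_expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  if (var_expl <= 0.6)
    stop(sprintf("tibia point cloud not elongated (first axis explains %.0f%% < 60%% of variance)",
                 100 * var_expl))
  ax <- pc$rotation[, 1]
  origin <- colMeans(tibia_points)
  if (!is.null(proximal_point)) {
    if (sum((proximal_point - origin) * ax) < 0) ax <- -ax
  } else if (ax[which.max(abs(ax))] < 0) ax <- -ax
  hint <- as.numeric(anterior_hint)
  hint_perp <- hint - sum(hint * ax) * ax
  if (vec_norm(hint_perp) < 1e-6 * vec_norm(hint))
    stop("anterior hint is parallel to the tibia axis")
  ap <- unit_vector(hint_perp)
  lat <- cross3(ax, ap)
  structure(list(origin = origin, axis_tibia = as.numeric(ax),
                 axis_ap = ap, axis_lat = lat),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n")
  cat(sprintf("  origin     %s\n", paste(sprintf("%.2f", x$origin), collapse = " ")))
  cat(sprintf("  axis_tibia %s\n", paste(sprintf("%.4f", x$axis_tibia), collapse = " ")))
  cat(sprintf("  axis_ap    %s\n", paste(sprintf("%.4f", x$axis_ap), collapse = " ")))
  cat(sprintf("  axis_lat   %s\n", paste(sprintf("%.4f", x$axis_lat), collapse = " ")))
  invisible(x)
}

#' Project a centerline onto an anatomical plane
#'
#' Orthogonal projection of every centerline point onto one of the two
#' decomposition planes. Under the adopted convention the `"front"`
#' (antero-posterior, T_Front) plane is spanned by the tibia axis and the
#' antero-posterior axis, so it retains the antero-posterior bowing that
#' knee flexion produces; the `"lateral"` (T_Lat) plane is spanned by the
#' tibia axis and the medio-lateral axis and retains medio-lateral
#' excursion. `plane_convention = "swapped"` exchanges the two readings.
#'
#' @param line a [centerline()] in the same coordinate frame as `frame`.
#' @param frame an [anatomical_frame()].
#' @param plane `"front"` or `"lateral"`.
#' @param plane_convention `"ap_in_front"` (default, see above) or
#'   `"swapped"`.
#' @return N x 2 matrix of in-plane coordinates (first column along
#'   `axis_tibia`); consecutive duplicate projected points are collapsed.
#' @export
project_centerline <- function(line, frame, plane = c("front", "lateral"),
                               plane_convention = c("ap_in_front", "swapped")) {
  stopifnot(inherits(line, "centerline"), inherits(frame, "anatomical_frame"))
  plane <- match.arg(plane)
  plane_convention <- match.arg(plane_convention)
  use_ap <- (plane == "front") == (plane_convention == "ap_in_front")
  second <- if (use_ap) frame$axis_ap else frame$axis_lat
  rel <- sweep(line$points, 2, frame$origin)
  xy <- cbind(rel %*% frame$axis_tibia, rel %*% second)
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  keep <- c(TRUE, d > 1e-12)
  xy[keep, , drop = FALSE]
}

#' Planar (decomposed) tortuosity
#'
#' Tortuosity index of the centerline's orthogonal projection onto an
#' anatomical plane: projected length over projected chord, minus one. With
#' the default convention, `plane = "front"` yields T_Front (antero-posterior
#' component) and `plane = "lateral"` yields T_Lat.
#'
#' @inheritParams project_centerline
#' @return projected tortuosity (>= 0).
#' @export
projected_tortuosity <- function(line, frame, plane = c("front", "lateral"),
                                 plane_convention = c("ap_in_front", "swapped")) {
  xy <- project_centerline(line, frame, plane, plane_convention)
  if (nrow(xy) < 2 || vec_norm(xy[nrow(xy), ] - xy[1, ]) < 1e-9)
    stop("projected endpoints coincide: curve is orthogonal to the plane")
  tortuosity_of_points(xy)
}

#' Write an anatomical frame as JSON
#'
#' @param frame an [anatomical_frame()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(lapply(unclass(frame), as.numeric), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}
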