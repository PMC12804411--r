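# Triangulated surface meshes. A mesh is a list(vertices = N x 3 matrix [mm],
# faces = M x 3 integer matrix, 1-based, consistently oriented outward).

new_trimesh <- function(vertices, faces, metadata = list()) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  structure(list(vertices = unname(vertices), faces = unname(faces),
                 metadata = metadata),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a surface mesh is watertight
#'
#' A closed 2-manifold triangle mesh has every undirected edge shared by
#' exactly two triangles.
#'
#' @param mesh a `trimesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Rotation-minimizing (parallel transport) frames along a polyline.
# Returns list(tangents, normals, binormals), each N x 3.
parallel_transport_frames <- function(points) {
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- unit_vector(points[2, ] - points[1, ])
  tang[n, ] <- unit_vector(points[n, ] - points[n - 1, ])
  if (n > 2)
    for (i in 2:(n - 1))
      tang[i, ] <- unit_vector(points[i + 1, ] - points[i - 1, ])
  nor <- matrix(0, n, 3)
  nor[1, ] <- perpendicular_any(tang[1, ])
  for (i in 2:n) {
    # rotate the previous normal by the rotation taking t[i-1] to t[i]
    v <- cross3(tang[i - 1, ], tang[i, ])
    s <- vec_norm(v); c_ <- sum(tang[i - 1, ] * tang[i, ])
    if (s < 1e-12) {
      nor[i, ] <- nor[i - 1, ]
    } else {
      R <- rotation_about_axis(v / s, atan2(s, c_))
      nor[i, ] <- as.vector(R %*% nor[i - 1, ])
    }
    # re-orthogonalize against accumulated drift
    nor[i, ] <- unit_vector(nor[i, ] - sum(nor[i, ] * tang[i, ]) * tang[i, ])
  }
  bin <- t(vapply(seq_len(n), function(i) cross3(tang[i, ], nor[i, ]), numeric(3)))
  list(tangents = tang, normals = nor, binormals = bin)
}

# Discrete curvature (1/mm) at interior vertices from circumscribed circles.
discrete_curvature <- function(points) {
  n <- nrow(points)
  if (n < 3) return(numeric(0))
  a <- points[1:(n - 2), , drop = FALSE]
  b <- points[2:(n - 1), , drop = FALSE]
  cc <- points[3:n, , drop = FALSE]
  ab <- row_norms(b - a); bc <- row_norms(cc - b); ca <- row_norms(a - cc)
  cr <- t(vapply(seq_len(n - 2),
                 function(i) cross3(b[i, ] - a[i, ], cc[i, ] - a[i, ]),
                 numeric(3)))
  area2 <- row_norms(cr)                  # twice the triangle area
  ifelse(area2 < 1e-14, 0, 2 * area2 / (ab * bc * ca))
}

#' Sweep a circular-profile tube along a centerline
#'
#' Builds a watertight triangulated tube by sweeping a circle of radius
#' `radius(s)` (s = arc length, mm) along the centerline using
#' rotation-minimizing frames, with triangle-fan caps at both ends. The true
#' arc-length mean diameter of the profile is stored in the mesh metadata as
#' the ground truth for diameter measurements.
#'
#' The sweep is rejected when the profile radius exceeds half the local
#' radius of curvature anywhere (the tube would self-intersect on the inner
#' side of the bend).
#'
#' @param line a [centerline()].
#' @param radius either a single positive number (constant radius, mm) or a
#'   function of arc length s (mm) returning the radius at s.
#' @param n_theta vertices per cross-sectional ring (default 64, keeping the
#'   polygonal area within 0.2\% of the circle).
#' @param ring_spacing target axial distance between rings in mm (default 1).
#' @return a `trimesh` whose `metadata` holds `centerline`, `radius_fun`,
#'   `true_mean_diameter`, `true_length` and `true_tortuosity`.
#' @export
sweep_tube <- function(line, radius, n_theta = 64L, ring_spacing = 1) {
  stopifnot(inherits(line, "centerline"))
  r_fun <- if (is.function(radius)) radius else {
    r0 <- radius
    function(s) rep.int(r0, length(s))
  }
  total <- curve_length(line)
  if (total <= 0) stop("degenerate centerline")
  dense <- if (total / nrow(line$points) > ring_spacing)
    resample_uniform(line, ring_spacing) else line
  pts <- dense$points
  s <- dense$arc_length
  rr <- r_fun(s)
  if (any(!is.finite(rr)) || min(rr) <= 0) stop("radius profile must be positive everywhere")
  kappa <- discrete_curvature(pts)
  if (length(kappa) && any(kappa > 0)) {
    rad_curv <- 1 / pmax(kappa, 1e-12)
    if (any(rr[2:(length(s) - 1)] > 0.5 * rad_curv))
      stop("self-intersecting sweep: radius exceeds half the local curvature radius")
  }
  fr <- parallel_transport_frames(pts)
  n <- nrow(pts)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ct <- cos(theta); st <- sin(theta)
  verts <- matrix(0, n * n_theta + 2L, 3)
  for (i in seq_len(n)) {
    ring <- pts[rep(i, n_theta), ] +
      rr[i] * (outer(ct, fr$normals[i, ]) + outer(st, fr$binormals[i, ]))
    verts[((i - 1L) * n_theta + 1L):(i * n_theta), ] <- ring
  }
  apex0 <- n * n_theta + 1L   # start cap centre
  apex1 <- n * n_theta + 2L   # end cap centre
  verts[apex0, ] <- pts[1, ]
  verts[apex1, ] <- pts[n, ]
  faces <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)
    b <- i * n_theta + seq_len(n_theta)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, an, b), cbind(an, bn, b))
  }
  ring1 <- seq_len(n_theta)
  ringN <- (n - 1L) * n_theta + seq_len(n_theta)
  faces[[n]] <- rbind(
    cbind(c(ring1[-1], ring1[1]), ring1, apex0),
    cbind(ringN, c(ringN[-1], ringN[1]), apex1))
  s_mid <- (s[-1] + s[-n]) / 2
  true_mean_d <- sum(2 * r_fun(s_mid) * diff(s)) / total
  chord <- vec_norm(pts[n, ] - pts[1, ])
  new_trimesh(verts, do.call(rbind, faces),
              metadata = list(centerline = dense, radius_fun = r_fun,
                              true_mean_diameter = true_mean_d,
                              true_length = total,
                              true_tortuosity = total / chord - 1))
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `trimesh`.
#' @param path output path.
#' @param name solid name in the STL header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "fpmorph_mesh") {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- t(vapply(seq_len(nrow(f)),
                  function(i) {
                    cr <- cross3(p2[i, ] - p1[i, ], p3[i, ] - p1[i, ])
                    nn <- vec_norm(cr)
                    if (nn < 1e-14) c(0, 0, 1) else cr / nn
                  }, numeric(3)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  tri_txt <- sprintf(
    "facet normal %g %g %g\nouter loop\nvertex %g %g %g\nvertex %g %g %g\nvertex %g %g %g\nendloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(tri_txt, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices are de-duplicated exactly so the result can be checked for
#' watertightness.
#'
#' @param path STL file path.
#' @return a `trimesh`.
#' @export
read_stl <- function(path) {
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- paste(m[, 1], m[, 2], m[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  new_trimesh(m[uk, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}
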