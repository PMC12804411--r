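#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: rotation angle %.3f deg, |t| = %.3f mm>\n",
              rotation_angle_deg(x), vec_norm(x$translation)))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param x a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$rotation), -as.vector(t(x$rotation) %*% x$translation))
}

#' Rotation angle of a rigid transform in degrees
#'
#' @param x a `rigid_transform`.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(x) {
  ca <- (sum(diag(x$rotation)) - 1) / 2
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' Apply a rigid transform to geometry
#'
#' Maps every coordinate x to `R x + t`. Lengths, areas and tortuosities are
#' invariant. Works on centerlines, meshes, voxel volumes (affine update
#' only) and raw point matrices/vectors.
#'
#' @param geometry a [centerline()], `trimesh`, `voxel_volume`, N x 3 matrix
#'   or length-3 point.
#' @param transform a `rigid_transform`.
#' @return the transformed object, same type as the input.
#' @export
apply_transform <- function(geometry, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  tp <- function(m) {
    m %*% t(transform$rotation) +
      matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  }
  if (inherits(geometry, "centerline")) {
    out <- centerline(tp(geometry$points), frame_id = geometry$frame_id)
    attr(out, "closed_form") <- attr(geometry, "closed_form")
    return(out)
  }
  if (inherits(geometry, "trimesh"))
    return(new_trimesh(tp(geometry$vertices), geometry$faces, geometry$metadata))
  if (inherits(geometry, "voxel_volume")) {
    hom <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
    return(new_voxel_volume(geometry$data, hom %*% geometry$affine))
  }
  if (is.matrix(geometry)) return(tp(geometry))
  if (is.numeric(geometry) && length(geometry) == 3)
    return(as.vector(transform$rotation %*% geometry) + transform$translation)
  stop("unsupported geometry type")
}

# Closed-form optimal rigid alignment (Kabsch/SVD) of matched point rows.
kabsch <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

# Principal-axes initial alignment candidates: centroid + principal axes,
# the 4 proper-rotation sign flips, each combined with a sweep of azimuthal
# rotations about the first principal axis. Near-cylindrical bones leave the
# azimuth only weakly determined by PCA (the surface bosses are the only
# azimuthal signal), so several starts are scored by RMS and the best ones
# refined by ICP.
pca_candidates <- function(source, target, n_azimuth = 24L) {
  axes <- function(m) {
    e <- eigen(stats::cov(m), symmetric = TRUE)
    v <- e$vectors
    if (det(v) < 0) v[, 3] <- -v[, 3]
    v
  }
  vs <- axes(source); vt <- axes(target)
  cs <- colMeans(source); ct <- colMeans(target)
  out <- list()
  angles <- seq(0, 2 * pi, length.out = n_azimuth + 1L)[-(n_azimuth + 1L)]
  for (flip in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    base <- vt %*% diag(flip) %*% t(vs)
    for (a in angles) {
      R <- rotation_about_axis(vt[, 1], a) %*% base
      out[[length(out) + 1L]] <-
        rigid_transform(R, ct - as.vector(R %*% cs))
    }
  }
  out
}

# RMS of nearest-neighbour distances from each source row to the target set.
icp_rms <- function(source, target) {
  sqrt(mean(nn_dist2(source, target)$d2))
}

# exact nearest neighbours (index + squared distance) via the C++ uniform
# grid locator
nn_dist2 <- function(source, target) {
  out <- nn_grid(source, target)
  list(index = out$index, d2 = pmax(out$d2, 0))
}

#' Rigid iterative-closest-point registration
#'
#' Aligns a source point set onto a target by alternating nearest-neighbour
#' correspondence with the closed-form (SVD-based) optimal rigid fit. Used
#' to bring every acquisition of a patient into the pre-operative
#' straight-knee reference frame via the femur, which is rigid across limb
#' configurations. Initialization aligns centroids and principal axes (sign
#' ambiguity resolved by trying the four proper-rotation flips); the RMS of
#' matched distances is non-increasing across iterations.
#'
#' @param source N x 3 point matrix (mm), e.g. femur mesh vertices of the
#'   acquisition to be moved.
#' @param target M x 3 point matrix in the reference frame.
#' @param max_iter maximum iterations (default 200).
#' @param tol stop when the RMS improves by less than this (mm, default 1e-4).
#' @param trim fraction of best-matching points kept in the fit (default 1 =
#'   no trimming).
#' @param init `"pca"` (centroid + principal axes) or `"identity"`.
#' @param refine `"plane"` (default) finishes with a point-to-plane
#'   refinement against locally estimated target normals, removing the
#'   small pose bias that discrete vertex sampling imposes on point-to-point
#'   matching; `"none"` skips it.
#' @return list with `transform` (`rigid_transform` mapping source into the
#'   target frame), `rms` (final RMS of matched point distances, mm),
#'   `n_iter`, and `rms_history` (per-iteration RMS of the point-to-point
#'   stage, non-increasing).
#' @export
icp_rigid <- function(source, target, max_iter = 200L, tol = 1e-4,
                      trim = 1.0, init = c("pca", "identity"),
                      refine = c("plane", "none")) {
  source <- as.matrix(source); target <- as.matrix(target)
  init <- match.arg(init)
  refine <- match.arg(refine)
  if (nrow(source) < 4 || nrow(target) < 4)
    stop("each point set needs at least 4 points")
  for (m in list(source, target)) {
    e <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    if (e[3] / e[1] < 1e-10)
      stop("degenerate (coplanar or collinear) point set")
  }
  if (init == "pca") {
    cands <- pca_candidates(source, target)
    # score candidates on a deterministic subsample for speed
    sub <- source[seq(1L, nrow(source),
                      length.out = min(400L, nrow(source))), , drop = FALSE]
    scores <- vapply(cands, function(tr)
      icp_rms(apply_transform(sub, tr), target), numeric(1))
    # probe a diverse set of starts: best-scoring candidates that differ by
    # at least 15 degrees of rotation from every already-picked start, so
    # neighbouring basins of a rippled RMS landscape each get one probe
    ord <- order(scores)
    top <- integer(0)
    for (i in ord) {
      distinct <- all(vapply(top, function(j) {
        rel <- crossprod(cands[[i]]$rotation, cands[[j]]$rotation)
        ca <- (sum(diag(rel)) - 1) / 2
        acos(pmin(1, pmax(-1, ca))) > 15 * pi / 180
      }, logical(1)))
      if (distinct) top <- c(top, i)
      if (length(top) >= 6L) break
    }
    sub2 <- source[seq(1L, nrow(source),
                       length.out = min(800L, nrow(source))), , drop = FALSE]
    probes <- lapply(top, function(i)
      icp_iterate(sub2, target, cands[[i]], max_iter = 20L,
                  tol = tol, trim = trim))
    finals <- vapply(probes, function(p) p$rms_history[length(p$rms_history)],
                     numeric(1))
    best <- probes[[which.min(finals)]]
    run <- icp_iterate(source, target, best$transform, max_iter = max_iter,
                       tol = tol, trim = trim)
    rms_history <- run$rms_history   # history of the final full-source run
    transform <- run$transform
  } else {
    run <- icp_iterate(source, target, rigid_transform(), max_iter = max_iter,
                       tol = tol, trim = trim)
    rms_history <- run$rms_history
    transform <- run$transform
  }
  rms <- rms_history[length(rms_history)]
  if (refine == "plane") {
    pol <- icp_plane_polish(source, target, transform,
                            local_normals(target))
    transform <- pol$transform
    rms <- icp_rms(apply_transform(source, transform), target)
  }
  list(transform = transform, rms = rms,
       n_iter = length(rms_history) - 1L, rms_history = rms_history)
}

# Local surface normals of a point cloud by PCA over the k nearest
# neighbours (smallest-variance direction). Signs are arbitrary, which is
# fine for unsigned point-to-plane distances.
local_normals <- function(points, k = 10L) {
  n <- nrow(points)
  k <- min(k, n - 1L)
  nrm <- matrix(0, n, 3)
  block <- 1024L
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    idx <- start:end
    dd <- outer(rowSums(points[idx, , drop = FALSE]^2), rowSums(points^2), "+") -
      2 * points[idx, , drop = FALSE] %*% t(points)
    for (r in seq_along(idx)) {
      nb <- points[order(dd[r, ])[seq_len(k + 1L)], , drop = FALSE]
      ev <- eigen(stats::cov(nb), symmetric = TRUE)
      nrm[idx[r], ] <- ev$vectors[, 3]
    }
  }
  nrm
}

# Point-to-plane refinement: correspondences are the feet of perpendiculars
# from each moved source point onto its nearest neighbour's tangent plane,
# which removes the bias a discrete vertex sampling imposes on
# point-to-point matching. Steps are kept only while the plane RMS drops.
icp_plane_polish <- function(source, target, transform, normals,
                             max_iter = 30L, tol = 1e-6) {
  plane_rms <- function(moved, nn) {
    off <- moved - target[nn$index, , drop = FALSE]
    sqrt(mean(rowSums(off * normals[nn$index, , drop = FALSE])^2))
  }
  moved <- apply_transform(source, transform)
  nn <- nn_dist2(moved, target)
  best <- plane_rms(moved, nn)
  for (iter in seq_len(max_iter)) {
    nrm <- normals[nn$index, , drop = FALSE]
    off <- rowSums((moved - target[nn$index, , drop = FALSE]) * nrm)
    foot <- moved - off * nrm
    step <- kabsch(moved, foot)
    cand <- compose_transforms(step, transform)
    cand_moved <- apply_transform(source, cand)
    cand_nn <- nn_dist2(cand_moved, target)
    rms <- plane_rms(cand_moved, cand_nn)
    if (rms >= best - tol) break
    transform <- cand
    moved <- cand_moved
    nn <- cand_nn
    best <- rms
  }
  list(transform = transform, plane_rms = best)
}

# Core ICP loop from a given starting transform; RMS is non-increasing by
# construction (non-improving steps are rejected).
icp_iterate <- function(source, target, transform, max_iter, tol, trim) {
  moved <- apply_transform(source, transform)
  rms_history <- icp_rms(moved, target)
  for (iter in seq_len(max_iter)) {
    nn <- nn_dist2(moved, target)
    keep <- seq_len(nrow(moved))
    if (trim < 1) {
      k <- max(4L, floor(trim * length(keep)))
      keep <- order(nn$d2)[seq_len(k)]
    }
    step <- kabsch(moved[keep, , drop = FALSE],
                   target[nn$index[keep], , drop = FALSE])
    cand <- compose_transforms(step, transform)
    cand_moved <- apply_transform(source, cand)
    rms <- icp_rms(cand_moved, target)
    if (rms <= rms_history[length(rms_history)] + 1e-12) {
      transform <- cand
      moved <- cand_moved
    } else {
      rms <- rms_history[length(rms_history)]   # reject non-improving step
    }
    improvement <- rms_history[length(rms_history)] - rms
    rms_history <- c(rms_history, min(rms, rms_history[length(rms_history)]))
    if (improvement < tol) break
  }
  list(transform = transform, rms_history = rms_history)
}

#' Write a rigid transform as a JSON sidecar
#'
#' Stored as a 4x4 homogeneous matrix (row-major list of rows).
#'
#' @param transform a `rigid_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  hom <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(homogeneous_matrix = apply(hom, 1, as.numeric, simplify = FALSE)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a rigid transform from its JSON sidecar
#'
#' @param path JSON path written by [write_transform_json()].
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  hom <- jsonlite::read_json(path, simplifyVector = TRUE)$homogeneous_matrix
  if (is.list(hom)) hom <- do.call(rbind, hom)
  rigid_transform(hom[1:3, 1:3], hom[1:3, 4])
}
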