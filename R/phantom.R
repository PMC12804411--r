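# Synthetic limb phantoms: a femoropopliteal vessel swept along a gently
# wavy axis, rigid bone proxies (femur proximal and tibia distal to the
# knee hinge), an adductor-hiatus landmark splitting SFA from PA, and a
# bending operation that rotates everything distal to the hinge while
# keeping the vessel C1-smooth through the knee. All ground-truth values
# (segment lengths, tortuosities, mean diameters, the bent-acquisition
# rigid transform) are carried in the phantom so the measurement pipeline
# can be validated end to end.

#' Bone proxy mesh: a capped cylinder with asymmetric surface bosses
#'
#' Three Gaussian surface bosses at distinct angular/axial positions break
#' the rotational symmetry of the cylinder so that rigid ICP registration on
#' the bone has a unique optimum.
#'
#' @param radius cylinder radius, mm.
#' @param z0,z1 axial extent along +z, mm.
#' @param bosses data.frame with columns `theta` (rad), `z` (mm), `amplitude`
#'   (mm), `sigma` (mm); default three asymmetric bosses.
#' @param n_theta,ring_spacing mesh resolution.
#' @return a watertight `trimesh`.
#' @export
make_bone_mesh <- function(radius = 14, z0 = 0, z1 = 200,
                           bosses = NULL, n_theta = 48L, ring_spacing = 2.5) {
  if (is.null(bosses)) {
    span <- z1 - z0
    bosses <- data.frame(theta = c(0.4, 2.5, 4.4),
                         z = z0 + span * c(0.18, 0.55, 0.85),
                         amplitude = c(9, 11, 8),
                         sigma = c(7, 9, 6))
  }
  zs <- seq(z0, z1, length.out = max(2L, ceiling((z1 - z0) / ring_spacing) + 1L))
  theta0 <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  golden <- pi * (3 - sqrt(5))
  n <- length(zs)
  verts <- matrix(0, n * n_theta + 2L, 3)
  for (i in seq_len(n)) {
    # successive rings are staggered by the golden angle and every vertex
    # carries a deterministic angular jitter: a regular vertex lattice makes
    # point-to-point ICP lock onto spurious minima at multiples of the
    # angular step (any rotation by k steps maps rings onto themselves)
    jitter <- 0.35 * (2 * pi / n_theta) *
      sin(12.9898 * i + 78.233 * seq_len(n_theta))
    theta <- theta0 + (i - 1L) * golden + jitter
    r <- rep(radius, n_theta)
    for (b in seq_len(nrow(bosses))) {
      dth <- abs((theta - bosses$theta[b]) %% (2 * pi))
      dth <- pmin(dth, 2 * pi - dth) * radius       # arc distance on surface
      dz <- zs[i] - bosses$z[b]
      r <- r + bosses$amplitude[b] * exp(-(dth^2 + dz^2) / (2 * bosses$sigma[b]^2))
    }
    verts[((i - 1L) * n_theta + 1L):(i * n_theta), ] <-
      cbind(r * cos(theta), r * sin(theta), zs[i])
  }
  apex0 <- n * n_theta + 1L; apex1 <- n * n_theta + 2L
  verts[apex0, ] <- c(0, 0, z0)
  verts[apex1, ] <- c(0, 0, z1)
  faces <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)
    b <- i * n_theta + seq_len(n_theta)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, an, b), cbind(an, bn, b))
  }
  ring1 <- seq_len(n_theta); ringN <- (n - 1L) * n_theta + seq_len(n_theta)
  faces[[n]] <- rbind(cbind(c(ring1[-1], ring1[1]), ring1, apex0),
                      cbind(ringN, c(ringN[-1], ringN[1]), apex1))
  new_trimesh(verts, do.call(rbind, faces))
}

# Dense vessel axis of the straight limb: gentle antero-posterior (x) and
# medio-lateral (y) sinusoidal excursions along the limb axis (+z).
straight_vessel_axis <- function(p) {
  z <- seq(0, p$vessel_end_z, by = p$axis_step)
  x <- p$ap_amplitude * sin(2 * pi * z / p$ap_wavelength + p$ap_phase)
  y <- p$lat_amplitude * sin(2 * pi * z / p$lat_wavelength + p$lat_phase)
  cbind(x, y, z)
}

# Radius profile (mm) as a function of arc length for one timepoint.
# PRE carries a fusiform aneurysm sac in the popliteal segment; FU1 models
# the stented artery: sac excluded, constant stent radius distal to the
# hiatus.
vessel_radius_profile <- function(p, timepoint) {
  force(p); force(timepoint)
  function(s) {
    r <- p$sfa_radius + (p$pa_radius - p$sfa_radius) *
      pmin(1, pmax(0, s / p$hiatus_z))
    if (timepoint == "PRE") {
      r + p$sac_amplitude * exp(-(s - p$sac_center_s)^2 / (2 * p$sac_sigma^2))
    } else {
      ifelse(s > p$hiatus_z, p$stent_radius, r)
    }
  }
}

default_phantom_params <- function() {
  list(vessel_end_z = 510, hiatus_z = 290, hinge_z = 360,
       axis_step = 0.25,
       ap_amplitude = 3.0, ap_wavelength = 210, ap_phase = 0.7,
       lat_amplitude = 7.0, lat_wavelength = 150, lat_phase = 2.1,
       sfa_radius = 4.0, pa_radius = 3.5,
       sac_amplitude = 3.5, sac_center_s = 320, sac_sigma = 8,
       stent_radius = 3.25,
       blend_half_width = 20,
       femur_z = c(165, 350), tibia_z = c(370, 490), bone_radius = 13,
       tube_n_theta = 64L, tube_ring_spacing = 1.5)
}

#' Straight-limb phantom
#'
#' Builds the straight-knee (180 degree) acquisition of one synthetic limb:
#' vessel surface swept along a gently curved axis, femur and tibia bone
#' proxies, the adductor-hiatus landmark and the knee hinge. Per-patient
#' anatomical variability is drawn reproducibly from `seed`.
#'
#' @param seed integer; drives the per-patient variation of axis amplitudes,
#'   wavelengths, radii and sac size.
#' @param timepoint `"PRE"` (aneurysmal popliteal artery) or `"FU1"`
#'   (post-stenting: sac excluded, constant stent radius).
#' @param params optional list overriding entries of the default phantom
#'   parameter set (see `fpmorph:::default_phantom_params`).
#' @return object of class `limb_phantom` (straight configuration only;
#'   see [bend_limb()]).
#' @export
make_straight_limb <- function(seed = 1L, timepoint = c("PRE", "FU1"),
                               params = list()) {
  timepoint <- match.arg(timepoint)
  p <- utils::modifyList(default_phantom_params(), params)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  jit <- function(x, frac) x * (1 + runif(length(x), -frac, frac))
  p$ap_amplitude <- jit(p$ap_amplitude, 0.3)
  p$lat_amplitude <- jit(p$lat_amplitude, 0.3)
  p$ap_wavelength <- jit(p$ap_wavelength, 0.15)
  p$lat_wavelength <- jit(p$lat_wavelength, 0.15)
  p$ap_phase <- runif(1, 0, 2 * pi)
  p$lat_phase <- runif(1, 0, 2 * pi)
  p$sfa_radius <- jit(p$sfa_radius, 0.1)
  p$pa_radius <- jit(p$pa_radius, 0.1)
  p$sac_amplitude <- jit(p$sac_amplitude, 0.2)
  axis_pts <- straight_vessel_axis(p)
  axis_line <- centerline(axis_pts, frame_id = "pre_straight_reference")
  if (p$hinge_z <= 0 || p$hinge_z >= p$vessel_end_z)
    stop("hinge does not intersect the limb axis")
  r_fun <- vessel_radius_profile(p, timepoint)
  hinge_point <- c(0, 0, p$hinge_z)
  li <- which.min(abs(axis_pts[, 3] - p$hiatus_z))
  structure(list(
    patient_seed = as.integer(seed),
    timepoint = timepoint,
    params = p,
    knee_angle = 180,
    axis = axis_line,
    radius_fun = r_fun,
    vessel = NULL,                     # swept lazily by finalize_phantom_meshes
    femur = make_bone_mesh(p$bone_radius, p$femur_z[1], p$femur_z[2]),
    tibia = make_bone_mesh(p$bone_radius * 0.85, p$tibia_z[1], p$tibia_z[2]),
    hinge = list(point = hinge_point, axis = c(0, 1, 0)),
    landmark_adductor_hiatus = axis_pts[li, ],
    anterior_hint = c(1, 0, 0),
    frame_id = "pre_straight_reference"),
    class = "limb_phantom")
}

# Sweep the vessel tube for a phantom configuration and attach truth values.
finalize_phantom_meshes <- function(ph) {
  ph$vessel <- sweep_tube(ph$axis, ph$radius_fun,
                          n_theta = ph$params$tube_n_theta,
                          ring_spacing = ph$params$tube_ring_spacing)
  ph$truth <- phantom_truth(ph)
  ph
}

# Ground-truth segment metrics from the dense axis and the radius profile.
phantom_truth <- function(ph) {
  sp <- split_at_landmark(ph$axis, ph$landmark_adductor_hiatus, max_distance = 25)
  seg_mean_d <- function(s0, s1) {
    s <- seq(s0, s1, length.out = 2001L)
    mean(2 * ph$radius_fun(s))
  }
  s_split <- ph$axis$arc_length[sp$split_index]
  total <- curve_length(ph$axis)
  list(
    sfa = list(length = curve_length(sp$sfa),
               tortuosity = tortuosity_index(sp$sfa),
               mean_diameter = seg_mean_d(0, s_split)),
    pa = list(length = curve_length(sp$pa),
              tortuosity = tortuosity_index(sp$pa),
              mean_diameter = seg_mean_d(s_split, total)),
    full_length = total)
}

# Cubic Hermite blend between (p0, t0) and (p1, t1), excluding endpoints.
hermite_blend <- function(p0, t0, p1, t1, n) {
  u <- seq(0, 1, length.out = n + 2L)[-c(1L, n + 2L)]
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  outer(h00, p0) + outer(h10, t0) + outer(h01, p1) + outer(h11, t1)
}

#' Bend a straight limb phantom at the knee
#'
#' Rotates all geometry distal to the hinge rigidly about the hinge axis by
#' `180 - knee_angle` degrees (flexion towards posterior). The vessel axis
#' within one blend half-width (default 20 mm) of the hinge is replaced by a
#' cubic Hermite blend that
#' matches position and tangent at both ends, so the bent vessel is
#' C1-smooth and its tortuosity finite and stable; the blended curve is then
#' re-swept and the ground-truth bent metrics recomputed from it. The femur
#' (proximal to the hinge) is untouched.
#'
#' @param ph a `limb_phantom` in the straight configuration.
#' @param knee_angle included knee angle in degrees; 180 returns the input
#'   unchanged, 90 is the standard flexed acquisition.
#' @return a `limb_phantom` in the bent configuration (same frame as the
#'   input; acquisition-frame changes are applied separately, see
#'   [make_limb_phantom()]).
#' @export
bend_limb <- function(ph, knee_angle = 90) {
  stopifnot(inherits(ph, "limb_phantom"))
  if (knee_angle <= 0 || knee_angle > 180)
    stop("knee_angle must be in (0, 180]")
  if (knee_angle == 180) {
    ph$knee_angle <- 180
    return(ph)
  }
  ang <- -(180 - knee_angle) * pi / 180       # flexion towards -x (posterior)
  R <- rotation_about_axis(ph$hinge$axis, ang)
  hp <- ph$hinge$point
  rot <- function(m) sweep(sweep(m, 2, hp) %*% t(R), 2, hp, "+")

  axis_pts <- ph$axis$points
  s <- ph$axis$arc_length
  # arc position where the axis crosses the hinge plane z = hinge z
  i_h <- which.min(abs(axis_pts[, 3] - hp[3]))
  s_h <- s[i_h]
  bw <- ph$params$blend_half_width
  prox <- axis_pts[s <= s_h - bw, , drop = FALSE]
  dist_pts <- rot(axis_pts[s >= s_h + bw, , drop = FALSE])
  if (nrow(prox) < 2 || nrow(dist_pts) < 2)
    stop("hinge too close to a vessel end for the blend region")
  # tangent magnitudes scaled to the blend chord (standard Hermite choice):
  # keeps the spline's curvature radius well above the vessel radius
  chord <- vec_norm(dist_pts[1, ] - prox[nrow(prox), ])
  t0 <- unit_vector(prox[nrow(prox), ] - prox[nrow(prox) - 1L, ]) * chord
  t1 <- unit_vector(dist_pts[2, ] - dist_pts[1, ]) * chord
  n_blend <- max(8L, ceiling(2 * bw / ph$params$axis_step))
  blend <- hermite_blend(prox[nrow(prox), ], t0, dist_pts[1, ], t1, n_blend)
  bent_axis <- centerline(rbind(prox, blend, dist_pts), frame_id = ph$frame_id)

  ph$knee_angle <- knee_angle
  ph$axis <- bent_axis
  ph$tibia <- new_trimesh(rot(ph$tibia$vertices), ph$tibia$faces)
  ph$vessel <- NULL                      # re-swept by finalize_phantom_meshes
  # landmark and femur are proximal to the hinge: unchanged
  ph
}

#' Complete straight + bent limb phantom with acquisition frames
#'
#' Generates one patient's paired acquisition: the straight-knee phantom in
#' the reference frame and the bent-knee phantom (after [bend_limb()]) moved
#' by a random rigid "repositioning" transform emulating a different scanner
#' frame between acquisitions. The true transform is stored so registration
#' can be validated.
#'
#' @inheritParams make_straight_limb
#' @param knee_angle_bent included knee angle of the flexed acquisition
#'   (degrees, default 90).
#' @return list of class `limb_phantom_pair`: `straight` and `bent`
#'   `limb_phantom`s (with swept vessel meshes and truth tables), and
#'   `true_transform`, the rigid transform mapping the straight reference
#'   frame into the bent acquisition frame.
#' @export
make_limb_phantom <- function(seed = 1L, timepoint = c("PRE", "FU1"),
                              knee_angle_bent = 90, params = list()) {
  timepoint <- match.arg(timepoint)
  straight <- make_straight_limb(seed, timepoint, params)
  bent <- bend_limb(straight, knee_angle_bent)
  set.seed((as.integer(seed) * 131L + 17L) %% 2147483647L)
  ax <- unit_vector(rnorm(3))
  G <- rigid_transform(rotation_about_axis(ax, runif(1, -15, 15) * pi / 180),
                       runif(3, -20, 20))
  bent$axis <- apply_transform(bent$axis, G)
  bent$femur <- apply_transform(bent$femur, G)
  bent$tibia <- apply_transform(bent$tibia, G)
  bent$hinge$point <- apply_transform(bent$hinge$point, G)
  bent$hinge$axis <- as.vector(G$rotation %*% bent$hinge$axis)
  bent$landmark_adductor_hiatus <- apply_transform(bent$landmark_adductor_hiatus, G)
  bent$anterior_hint <- as.vector(G$rotation %*% bent$anterior_hint)
  bent$frame_id <- "bent_acquisition"
  bent$axis$frame_id <- "bent_acquisition"
  straight <- finalize_phantom_meshes(straight)
  bent <- finalize_phantom_meshes(bent)
  structure(list(straight = straight, bent = bent, true_transform = G,
                 seed = as.integer(seed), timepoint = timepoint),
            class = "limb_phantom_pair")
}

#' Seed points for centerline extraction on a phantom
#'
#' @param ph a `limb_phantom`.
#' @return list with `start` and `end` 3D points (mm) at the vessel axis
#'   extremities.
#' @export
phantom_seeds <- function(ph) {
  list(start = ph$axis$points[1, ],
       end = ph$axis$points[nrow(ph$axis$points), ])
}
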