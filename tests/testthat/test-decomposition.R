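# Anatomical frames from the tibia axis and planar tortuosity decomposition.

# clean elongated point cloud along +z (no bosses) for exact-plane tests
clean_tibia <- function() {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  z <- seq(0, 120, by = 4)
  g <- expand.grid(th = th, z = z)
  cbind(12 * cos(g$th), 12 * sin(g$th), g$z)
}

test_that("frame axes are orthonormal, right-handed and correctly oriented", {
  fr <- anatomical_frame(clean_tibia(), c(1, 0, 0))
  expect_lt(abs(sum(fr$axis_tibia * fr$axis_ap)), 1e-9)
  expect_lt(abs(sum(fr$axis_tibia * fr$axis_lat)), 1e-9)
  expect_lt(abs(sum(fr$axis_ap * fr$axis_lat)), 1e-9)
  expect_equal(fpmorph:::cross3(fr$axis_tibia, fr$axis_ap), fr$axis_lat,
               tolerance = 1e-9)
  expect_equal(abs(fr$axis_tibia[3]), 1, tolerance = 1e-9)
  expect_equal(fr$axis_ap, c(1, 0, 0), tolerance = 1e-9)
  # proximal point orients the tibia axis
  fr2 <- anatomical_frame(clean_tibia(), c(1, 0, 0),
                          proximal_point = c(0, 0, 500))
  expect_gt(fr2$axis_tibia[3], 0)
})

test_that("degenerate clouds and parallel hints are rejected", {
  set.seed(3)
  blob <- matrix(rnorm(300), ncol = 3)
  expect_error(anatomical_frame(blob, c(1, 0, 0)), "elongated")
  expect_error(anatomical_frame(clean_tibia(), c(0, 0, 1)), "parallel")
})

test_that("frame estimation is equivariant under rigid rotation", {
  tib <- clean_tibia()
  fr <- anatomical_frame(tib, c(1, 0, 0))
  set.seed(17)
  for (i in 1:10) {
    R <- rotation_about_axis(fpmorph:::unit_vector(rnorm(3)),
                             runif(1, -pi, pi))
    fr2 <- anatomical_frame(tib %*% t(R), as.vector(R %*% c(1, 0, 0)))
    for (axn in c("axis_tibia", "axis_ap", "axis_lat")) {
      ang <- acos(pmin(1, abs(sum(fr2[[axn]] * as.vector(R %*% fr[[axn]]))))) * 180 / pi
      expect_lt(ang, 0.5)
    }
  }
})

test_that("planar curves decompose exactly", {
  fr <- anatomical_frame(clean_tibia(), c(1, 0, 0))
  t <- seq(0, 1, length.out = 600)
  # curve confined to the front (tibia, ap) plane through the origin
  curve <- cbind(5 * sin(4 * pi * t), 0, 120 * t)
  cl <- centerline(sweep(curve, 2, fr$origin, "+"))
  t3d <- tortuosity_index(cl)
  expect_equal(projected_tortuosity(cl, fr, "front"), t3d, tolerance = 1e-12)
  expect_lt(projected_tortuosity(cl, fr, "lateral"), 1e-9)
  # straight line: both zero
  straight <- centerline(cbind(t * 30, t * 10, t * 120))
  expect_equal(projected_tortuosity(straight, fr, "front"), 0, tolerance = 1e-9)
  expect_equal(projected_tortuosity(straight, fr, "lateral"), 0, tolerance = 1e-9)
  # swapped convention exchanges the two readings
  expect_equal(projected_tortuosity(cl, fr, "lateral", "swapped"), t3d,
               tolerance = 1e-12)
})

test_that("tilted arc projections match a dense quadrature oracle", {
  fr <- anatomical_frame(clean_tibia(), c(1, 0, 0))
  # circular arc tilted 45 degrees between the two planes
  u <- seq(0, pi / 2, length.out = 20000)
  R45 <- rotation_about_axis(c(0, 0, 1), pi / 4)
  pts <- cbind(60 * (1 - cos(u)), 0, 60 * sin(u)) %*% t(R45)
  cl <- centerline(sweep(pts, 2, fr$origin, "+"))
  for (pl in c("front", "lateral")) {
    xy <- project_centerline(cl, fr, pl)
    # oracle: arc length of the projected curve by dense chord summation on
    # the analytic projection (here identical construction, independent path)
    proj <- if (pl == "front") pts[, c(3, 1)] else pts[, c(3, 2)]
    d <- sqrt(rowSums((proj[-1, ] - proj[-nrow(proj), ])^2))
    oracle <- sum(d) / sqrt(sum((proj[nrow(proj), ] - proj[1, ])^2)) - 1
    expect_equal(projected_tortuosity(cl, fr, pl), oracle, tolerance = 1e-6)
  }
})

test_that("projection is 1-Lipschitz and sign-invariant over random curves", {
  fr <- anatomical_frame(clean_tibia(), c(1, 0, 0))
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    pts <- cbind(cumsum(runif(n, 0.2, 2)), rnorm(n, sd = 3), rnorm(n, sd = 3))
    cl <- centerline(pts)
    for (pl in c("front", "lateral")) {
      xy <- project_centerline(cl, fr, pl)
      d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
      expect_lte(sum(d), curve_length(cl) + 1e-9)
    }
  }
  # reflected planar curve keeps its projected tortuosity
  t <- seq(0, 1, length.out = 300)
  curve <- cbind(4 * sin(2 * pi * t), 0, 100 * t)
  cl <- centerline(sweep(curve, 2, fr$origin, "+"))
  refl <- centerline(sweep(curve %*% diag(c(-1, 1, 1)), 2, fr$origin, "+"))
  expect_equal(projected_tortuosity(cl, fr, "front"),
               projected_tortuosity(refl, fr, "front"), tolerance = 1e-12)

  # curve orthogonal to a plane has no defined projected tortuosity
  flatline <- centerline(cbind(seq(0, 10, 0.5), 0, 0) +
                           matrix(fr$origin, 21, 3, byrow = TRUE))
  expect_error(projected_tortuosity(flatline, fr, "lateral"), "coincide")
})
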