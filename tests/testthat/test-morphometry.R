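# Length, tortuosity index, cross-sections, diameters and segment splitting.

test_that("curve length and tortuosity index on reference shapes", {
  two <- centerline(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(curve_length(two), 10)
  expect_equal(tortuosity_index(two), 0)

  semi <- make_centerline(parametric_curve("circular_arc",
                                           list(radius = 50, angle = pi),
                                           n_points = 8000))
  expect_lt(abs(curve_length(semi) / (pi * 50) - 1), 5e-4)
  expect_equal(tortuosity_index(semi), pi / 2 - 1, tolerance = 1e-4)

  # full sine period vs quadrature oracle
  A <- 10; per <- 80; k <- 2 * pi / per
  sn <- make_centerline(parametric_curve("sinusoid",
                                         list(amplitude = A, period = per),
                                         n_points = 8000))
  oracle <- integrate(function(x) sqrt(1 + (A * k * cos(k * x))^2), 0, per,
                      rel.tol = 1e-10)$value / per - 1
  expect_equal(tortuosity_index(sn), oracle, tolerance = 1e-4)

  ring <- centerline(cbind(cos(seq(0, 2 * pi, length.out = 100)),
                           sin(seq(0, 2 * pi, length.out = 100)), 0))
  expect_error(tortuosity_index(ring), "coincident")
})

test_that("tortuosity index is invariant under rigid motion and scaling", {
  set.seed(5)
  pts <- cbind(cumsum(runif(50, 0.2, 1)), rnorm(50, sd = 2), rnorm(50, sd = 2))
  cl <- centerline(pts)
  t0 <- tortuosity_index(cl)
  for (i in 1:5) {
    tr <- random_rigid()
    expect_equal(tortuosity_index(apply_transform(cl, tr)), t0,
                 tolerance = 1e-12)
  }
  expect_equal(tortuosity_index(centerline(pts * 3.7)), t0, tolerance = 1e-12)
})

test_that("equivalent diameter is the exact circular inverse", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(78.5398), 10, tolerance = 1e-5)
  expect_equal(equivalent_diameter(pi * 4.5^2), 9)
  d <- c(1.7, 6.2, 14)
  expect_equal(equivalent_diameter(pi * (d / 2)^2), d)
  expect_error(equivalent_diameter(-1), "positive")
})

test_that("cylinder cross-sections have the analytic area and count", {
  secs <- cross_sections(fx_line100(), fx_cyl_tube(), step = 5)
  expect_length(secs, 21)
  areas <- vapply(secs, function(s) s$area, numeric(1))
  expect_lt(max(abs(areas / (16 * pi) - 1)), 0.005)
  expect_equal(mean_diameter(secs), 8, tolerance = 0.01)
  # polygons are simple, counter-clockwise, and recompute their diameter
  for (s in secs[c(1, 11, 21)]) {
    expect_gt(fpmorph:::polygon_signed_area(s$polygon), 0)
    expect_equal(s$equivalent_diameter, equivalent_diameter(s$area))
  }
  # step beyond the length leaves only the two end sections
  ends <- cross_sections(fx_line100(), fx_cyl_tube(), step = 500)
  expect_length(ends, 2)
})

test_that("arc-tube sections are circles of the profile radius", {
  secs <- cross_sections(fx_arc_line(), fx_arc_tube(), step = 10)
  areas <- vapply(secs, function(s) s$area, numeric(1))
  expect_lt(max(abs(areas / (pi * 3.5^2) - 1)), 0.01)
})

test_that("mean diameter of a tapered tube approaches the integral mean", {
  taper <- function(s) 5 - 2 * s / 100
  tube <- sweep_tube(fx_line100(), taper)
  secs <- cross_sections(fx_line100(), tube, step = 1)
  expect_equal(mean_diameter(secs), 8, tolerance = 0.01)
  expect_error(mean_diameter(list()), "no cross-sections")
})

test_that("splitting at a landmark is exact and length-additive", {
  cl <- resample_uniform(fx_line100(), 1)
  sp <- split_at_landmark(cl, c(50, 0, 0))
  expect_equal(curve_length(sp$sfa), 50)
  expect_equal(curve_length(sp$pa), 50)
  expect_equal(curve_length(sp$sfa) + curve_length(sp$pa), curve_length(cl))
  # shared boundary vertex
  expect_equal(sp$sfa$points[nrow(sp$sfa$points), ], sp$pa$points[1, ])
  # off-axis landmark projects to the nearest arc position
  sp2 <- split_at_landmark(cl, c(60, 5, 0))
  expect_equal(curve_length(sp2$sfa), 60)
  expect_error(split_at_landmark(cl, c(50, 40, 0)), "gate")

  set.seed(9)
  for (i in 1:5) {
    pts <- cbind(cumsum(runif(60, 0.3, 1.5)), rnorm(60), rnorm(60))
    wig <- centerline(pts)
    spw <- split_at_landmark(wig, wig$points[25, ] + c(0, 0.5, -0.5))
    expect_equal(curve_length(spw$sfa) + curve_length(spw$pa),
                 curve_length(wig), tolerance = 1e-9)
  }
})
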