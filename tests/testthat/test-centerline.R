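# Centerline container, resampling and moving-average smoothing.

test_that("centerline invariants hold by construction", {
  pts <- cbind(c(0, 1, 1, 4), c(0, 0, 2, 2), 0)
  cl <- centerline(pts)
  expect_equal(nrow(cl$points), 4)
  expect_true(all(diff(cl$arc_length) > 0))
  expect_equal(cl$arc_length[1], 0)
  expect_equal(curve_length(cl), 1 + 2 + 3)
  # consecutive duplicates collapse
  cl2 <- centerline(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(cl2$points), 2)
  expect_error(centerline(matrix(0, 2, 3)), "degenerate|coincide")
  expect_error(centerline(matrix(1, 1, 3)), "2 points")
})

test_that("uniform resampling spaces points equally and preserves endpoints", {
  cl <- fx_line100()
  rs <- resample_uniform(cl, 1)
  expect_equal(nrow(rs$points), 101)
  gaps <- diff(rs$arc_length)
  expect_lt(max(abs(gaps[-length(gaps)] - 1)), 1e-6)
  expect_equal(rs$points[1, ], cl$points[1, ])
  expect_equal(rs$points[nrow(rs$points), ], cl$points[nrow(cl$points), ])

  semi <- make_centerline(parametric_curve("circular_arc",
                                           list(radius = 50, angle = pi),
                                           n_points = 5000))
  rs2 <- resample_uniform(semi, 0.5)
  expect_lt(abs(curve_length(rs2) / (pi * 50) - 1), 1e-3)
  # idempotence
  rs3 <- resample_uniform(rs2, 0.5)
  expect_lt(max(abs(rs3$points - rs2$points)), 1e-9)
  expect_error(resample_uniform(cl, 0), "positive")
  expect_error(resample_uniform(cl, 1000), "smaller")
})

test_that("moving-average smoothing fixes straight lines and shortens zig-zags", {
  straight <- fx_line100()
  sm <- smooth_moving_average(straight, 5)
  expect_lt(max(abs(sm$points - straight$points)), 1e-12)

  zig <- centerline(cbind(seq(0, 20, by = 1), rep(c(0, 2), length.out = 21), 0))
  smz <- smooth_moving_average(zig, 5)
  expect_lt(curve_length(smz), curve_length(zig))
  expect_lte(fpmorph:::curvature_energy(smz), fpmorph:::curvature_energy(zig))
  # endpoints pinned
  expect_equal(smz$points[1, ], zig$points[1, ])
  expect_equal(smz$points[21, ], zig$points[21, ])

  expect_error(smooth_moving_average(zig, 4), "odd")
  expect_error(smooth_moving_average(zig, 21), "smaller")
  expect_s3_class(smooth_moving_average(zig, 19), "centerline")
})

test_that("smoothing commutes with rigid transforms", {
  set.seed(31)
  pts <- cbind(cumsum(runif(40, 0.5, 2)), rnorm(40), rnorm(40))
  cl <- centerline(pts)
  tr <- random_rigid()
  a <- smooth_moving_average(apply_transform(cl, tr), 7)
  b <- apply_transform(smooth_moving_average(cl, 7), tr)
  expect_lt(max(abs(a$points - b$points)), 1e-9)
})

test_that("centerline CSV round-trips", {
  cl <- fx_line100()
  path <- tempfile(fileext = ".csv")
  write_centerline_csv(cl, path)
  back <- read_centerline_csv(path)
  expect_equal(back$points, cl$points, tolerance = 1e-12)
})
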