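# Parametric ground-truth curves: closed forms and sampling convergence.

test_that("closed-form length and tortuosity match analytic values", {
  line <- parametric_curve("line", list(length = 100))
  expect_equal(line$closed_form$length, 100)
  expect_equal(line$closed_form$tortuosity, 0)

  semi <- parametric_curve("circular_arc", list(radius = 50, angle = pi))
  expect_equal(semi$closed_form$length, pi * 50)
  expect_equal(semi$closed_form$tortuosity, pi / 2 - 1, tolerance = 1e-12)

  hel <- parametric_curve("helix", list(radius = 10, pitch = 20, turns = 2))
  expect_equal(hel$closed_form$length,
               2 * 2 * pi * sqrt(10^2 + (20 / (2 * pi))^2), tolerance = 1e-12)
  # integer turns: chord equals the axial rise
  expect_equal(hel$closed_form$tortuosity, hel$closed_form$length / 40 - 1,
               tolerance = 1e-12)
})

test_that("sinusoid closed form agrees with independent quadrature", {
  A <- 8; per <- 60
  sn <- parametric_curve("sinusoid", list(amplitude = A, period = per))
  k <- 2 * pi / per
  oracle <- integrate(function(x) sqrt(1 + (A * k * cos(k * x))^2), 0, per,
                      rel.tol = 1e-10)$value
  expect_equal(sn$closed_form$length, oracle, tolerance = 1e-8)
  expect_equal(sn$closed_form$tortuosity, oracle / per - 1, tolerance = 1e-8)
})

test_that("chord sums converge to the closed-form length", {
  specs <- list(
    parametric_curve("circular_arc", list(radius = 50, angle = pi), n_points = 2000),
    parametric_curve("helix", list(radius = 10, pitch = 20, turns = 2), n_points = 4000),
    parametric_curve("sinusoid", list(amplitude = 8, period = 60), n_points = 2000))
  for (sp in specs) {
    cl <- make_centerline(sp)
    expect_lt(abs(curve_length(cl) / sp$closed_form$length - 1), 1e-4)
  }
})

test_that("invalid curve parameters are rejected", {
  expect_error(parametric_curve("spiral"), "arg")
  expect_error(parametric_curve("line", list(length = -5)), "positive")
  expect_error(parametric_curve("circular_arc", list(radius = 10, angle = 0)), "positive")
  expect_error(parametric_curve("line", list(length = 10), n_points = 1), "n_points")
})

test_that("sampled centerline carries its closed form", {
  cl <- make_centerline(parametric_curve("circular_arc",
                                         list(radius = 50, angle = pi),
                                         n_points = 3000))
  cf <- attr(cl, "closed_form")
  expect_equal(tortuosity_index(cl), cf$tortuosity, tolerance = 1e-6)
})
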