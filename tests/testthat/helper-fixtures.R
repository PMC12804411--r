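# Shared fixtures, built once per test session. The heavier objects
# (voxelized tubes, extracted centerlines) are cached in this environment
# so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_line100 <- function() fixture("line100", function()
  make_centerline(parametric_curve("line", list(length = 100), n_points = 101)))

fx_cyl_tube <- function() fixture("cyl_tube", function()
  sweep_tube(fx_line100(), 4))

fx_cyl_mask <- function() fixture("cyl_mask", function()
  voxelize(fx_cyl_tube(), 0.5))

fx_cyl_extracted <- function() fixture("cyl_extracted", function() {
  cl <- extract_centerline(fx_cyl_mask(), c(0, 0, 0), c(100, 0, 0))
  smooth_moving_average(resample_uniform(cl, 1), 5)
})

# quarter-circle arc tube (radius 60 mm, r = 3.5 mm)
fx_arc_line <- function() fixture("arc_line", function()
  make_centerline(parametric_curve("circular_arc",
                                   list(radius = 60, angle = pi / 2),
                                   n_points = 400)))

fx_arc_tube <- function() fixture("arc_tube", function()
  sweep_tube(fx_arc_line(), 3.5))

fx_arc_extracted <- function() fixture("arc_extracted", function() {
  al <- fx_arc_line()
  cl <- extract_centerline(voxelize(fx_arc_tube(), 0.5),
                           al$points[1, ], al$points[nrow(al$points), ])
  smooth_moving_average(resample_uniform(cl, 1), 5)
})

fx_phantom_pair <- function() fixture("phantom_pair", function()
  make_limb_phantom(seed = 7, timepoint = "PRE"))

# random rigid transform under the caller's RNG state
random_rigid <- function(max_angle_deg = 180, max_trans = 50) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rigid_transform(rotation_about_axis(ax, runif(1, -1, 1) * max_angle_deg * pi / 180),
                  runif(3, -max_trans, max_trans))
}
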