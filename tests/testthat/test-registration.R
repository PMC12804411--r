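# Rigid transforms and femur-based ICP registration.

test_that("rigid transforms form a group and preserve metrics", {
  set.seed(21)
  a <- random_rigid(); b <- random_rigid()
  ab <- compose_transforms(a, b)
  p <- rnorm(3)
  expect_equal(apply_transform(p, ab),
               apply_transform(apply_transform(p, b), a), tolerance = 1e-12)
  ident <- compose_transforms(a, invert_transform(a))
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
  expect_lt(max(abs(crossprod(ab$rotation) - diag(3))), 1e-9)
  expect_equal(det(ab$rotation), 1, tolerance = 1e-9)
  expect_error(rigid_transform(matrix(2 * diag(3), 3)), "orthonormal")

  cl <- fx_arc_line()
  moved <- apply_transform(cl, a)
  expect_equal(curve_length(moved), curve_length(cl), tolerance = 1e-9)
  expect_equal(tortuosity_index(moved), tortuosity_index(cl),
               tolerance = 1e-12)
  back <- apply_transform(moved, invert_transform(a))
  expect_lt(max(abs(back$points - cl$points)), 1e-9)
})

test_that("transform JSON sidecar round-trips", {
  set.seed(4)
  tr <- random_rigid()
  path <- tempfile(fileext = ".json")
  write_transform_json(tr, path)
  back <- read_transform_json(path)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tr$translation, tolerance = 1e-12)
})

test_that("ICP recovers a known transform exactly on identical sampling", {
  pair <- fx_phantom_pair()
  icp <- icp_rigid(pair$bent$femur$vertices, pair$straight$femur$vertices)
  err <- compose_transforms(icp$transform, pair$true_transform)
  expect_lt(rotation_angle_deg(err), 0.1)
  expect_lt(fpmorph:::vec_norm(err$translation), 0.1)
  expect_lt(icp$rms, 1e-6)
  expect_true(all(diff(icp$rms_history) <= 1e-12))

  # source equal to target: identity
  same <- icp_rigid(pair$straight$femur$vertices,
                    pair$straight$femur$vertices)
  expect_lt(rotation_angle_deg(same$transform), 1e-4)
  expect_lt(same$rms, 1e-9)
})

test_that("ICP tolerates resampling and noise", {
  pair <- fx_phantom_pair()
  p <- pair$straight$params
  src_mesh <- make_bone_mesh(p$bone_radius, p$femur_z[1], p$femur_z[2],
                             n_theta = 64L, ring_spacing = 1.8)
  set.seed(107)
  src <- apply_transform(src_mesh, pair$true_transform)$vertices +
    matrix(rnorm(3 * nrow(src_mesh$vertices), 0, 0.2), ncol = 3)
  icp <- icp_rigid(src, pair$straight$femur$vertices)
  err <- compose_transforms(icp$transform, pair$true_transform)
  expect_lt(rotation_angle_deg(err), 1)
  expect_lt(fpmorph:::vec_norm(err$translation), 0.5)
  expect_true(all(diff(icp$rms_history) <= 1e-12))
})

test_that("degenerate point sets are rejected", {
  flat <- cbind(rnorm(50), rnorm(50), 0)
  good <- matrix(rnorm(150), ncol = 3)
  expect_error(icp_rigid(flat, good), "degenerate")
  expect_error(icp_rigid(good[1:3, ], good), "at least 4")
})

test_that("morphometry is identical before and after registration", {
  pair <- fx_phantom_pair()
  icp <- icp_rigid(pair$bent$femur$vertices, pair$straight$femur$vertices)
  bent_line <- pair$bent$axis
  moved <- apply_transform(bent_line, icp$transform)
  expect_equal(curve_length(moved), curve_length(bent_line), tolerance = 1e-9)
  expect_equal(tortuosity_index(moved), tortuosity_index(bent_line),
               tolerance = 1e-9)
})
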