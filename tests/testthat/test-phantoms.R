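# Limb phantom generation, bending and the cohort sampler.

test_that("bending at 180 degrees is the identity", {
  ph <- make_straight_limb(seed = 2)
  same <- bend_limb(ph, 180)
  expect_identical(same$axis$points, ph$axis$points)
  expect_identical(same$tibia$vertices, ph$tibia$vertices)
})

test_that("bending is deterministic and increases tortuosity across the hinge", {
  ph <- make_straight_limb(seed = 2)
  b1 <- bend_limb(ph, 90)
  b2 <- bend_limb(ph, 90)
  expect_identical(b1$axis$points, b2$axis$points)
  t_straight <- tortuosity_index(ph$axis)
  t_bent <- tortuosity_index(b1$axis)
  expect_gt(t_bent, t_straight)
  expect_error(bend_limb(ph, 0), "knee_angle")
  bad <- ph; bad$hinge$point <- c(0, 0, 1e6)
  expect_error(bend_limb(bad, 90), "hinge")
})

test_that("bones move rigidly: vertex set congruent across configurations", {
  pair <- fx_phantom_pair()
  # femur: bent vertices are exactly the transformed straight vertices
  moved <- apply_transform(pair$straight$femur, pair$true_transform)
  expect_lt(max(abs(moved$vertices - pair$bent$femur$vertices)), 1e-9)
  # tibia is additionally hinge-rotated but stays congruent: all pairwise
  # edge lengths (sampled) are preserved
  vs <- pair$straight$tibia$vertices
  vb <- pair$bent$tibia$vertices
  set.seed(1)
  i <- sample(nrow(vs), 200); j <- sample(nrow(vs), 200)
  ds <- sqrt(rowSums((vs[i, ] - vs[j, ])^2))
  db <- sqrt(rowSums((vb[i, ] - vb[j, ])^2))
  expect_lt(max(abs(ds - db)), 1e-9)
})

test_that("phantom meshes are watertight and truth values sane", {
  pair <- fx_phantom_pair()
  for (ph in list(pair$straight, pair$bent)) {
    expect_true(is_watertight(ph$vessel))
    expect_true(is_watertight(ph$femur))
    expect_true(is_watertight(ph$tibia))
    expect_gt(ph$truth$sfa$length, 0)
    expect_gte(ph$truth$sfa$tortuosity, 0)
    expect_gt(ph$truth$pa$mean_diameter, 0)
  }
  # the paper's qualitative signature holds in ground truth
  expect_lt(pair$bent$truth$pa$length, pair$straight$truth$pa$length)
  expect_gt(pair$bent$truth$pa$tortuosity, pair$straight$truth$pa$tortuosity)
})

test_that("same seed reproduces phantoms bit-identically", {
  a <- make_limb_phantom(seed = 4, timepoint = "FU1")
  b <- make_limb_phantom(seed = 4, timepoint = "FU1")
  expect_identical(a$straight$vessel$vertices, b$straight$vessel$vertices)
  expect_identical(a$bent$vessel$vertices, b$bent$vessel$vertices)
  expect_identical(a$true_transform, b$true_transform)
})

test_that("stented follow-up phantom has no aneurysm sac", {
  pre <- make_straight_limb(seed = 6, timepoint = "PRE")
  fu <- make_straight_limb(seed = 6, timepoint = "FU1")
  s <- seq(300, 340, by = 1)
  expect_gt(max(pre$radius_fun(s)), 5)        # sac bulge
  expect_lt(max(fu$radius_fun(s)), 4.5)       # stent calibre
})

test_that("cohort sampler is reproducible and hits its cells", {
  cells <- reference_cohort_summary()
  spec <- cohort_spec(cells, n_patients = 9, seed = 3)
  t1 <- sample_cohort(spec)
  t2 <- sample_cohort(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 9 * 8)               # 2 timepoints x 2 configs x 2 segments
  # calibrated sampling: cell medians and IQRs are exact
  v <- t1$length[t1$timepoint == "PRE" & t1$segment == "SFA" &
                   t1$configuration == "straight"]
  expect_equal(median(v), 291.14)
  expect_equal(unname(quantile(v, 0.75) - quantile(v, 0.25)), 47.81,
               tolerance = 1e-9)
  # population mode fluctuates but converges
  specp <- cohort_spec(cells, n_patients = 4000, seed = 3,
                       calibrate = "population")
  tp <- sample_cohort(specp)
  vp <- tp$length[tp$timepoint == "PRE" & tp$segment == "SFA" &
                    tp$configuration == "straight"]
  expect_lt(abs(median(vp) / 291.14 - 1), 0.02)
})

test_that("degenerate and infeasible cohort specs are handled", {
  cells <- reference_cohort_summary()
  zero <- cells; zero$iqr <- 0
  tz <- sample_cohort(cohort_spec(zero, n_patients = 5, seed = 1))
  v <- tz$length[tz$timepoint == "PRE" & tz$segment == "SFA" &
                   tz$configuration == "straight"]
  expect_true(all(v == 291.14))
  neg <- cells; neg$iqr[3] <- -1
  expect_error(cohort_spec(neg), "negative IQR")
  badm <- cells; badm$median[1] <- 0
  expect_error(cohort_spec(badm), "positive")
  expect_error(cohort_spec(cells, n_patients = 2), ">= 3")
})

test_that("paired draws within a patient are correlated", {
  cells <- reference_cohort_summary()
  tab <- sample_cohort(cohort_spec(cells, n_patients = 400, seed = 8,
                                   calibrate = "population"))
  a <- tab$length[tab$timepoint == "PRE" & tab$segment == "SFA" &
                    tab$configuration == "straight"]
  b <- tab$length[tab$timepoint == "PRE" & tab$segment == "SFA" &
                    tab$configuration == "bent"]
  expect_gt(cor(a, b), 0.5)
})
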