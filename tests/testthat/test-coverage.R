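test_that("half-space coverage matches the spherical-zone closed form and Monte Carlo", {
  for (gap in c(-11, 0, 11)) {
    fx <- half_space_fixture(gap)
    tucr <- fixture_tucr(fx)
    expect_lt(abs(tucr - fx$gt$uncovered_fraction), 0.01)
    expect_lt(abs(tucr - halfspace_mc_oracle(gap, n = 2e5)), 0.01)
  }
  fx <- half_space_fixture(0, orientation = "axis_containing")
  tucr <- fixture_tucr(fx)
  expect_lt(abs(tucr - 0.5), 0.01)
})

test_that("fully embedded and fully exposed cups give tucr 0 and 1", {
  pose <- cup_pose(c(0, 0, 0), cup_axis_from_angles(45, 20), 45, 20)
  cup <- build_cup_mesh(eggshell_spec(), pose, "outer_shell_only")
  block <- box_mesh(c(-40, -40, -40), c(40, 40, 40))
  expect_equal(classify_coverage(block, cup, eps = 0.1)$tucr, 0)
  far <- box_mesh(c(200, 200, 200), c(240, 240, 240))
  expect_equal(classify_coverage(far, cup, eps = 0.1)$tucr, 1)
  open_mesh <- trimesh(block$vertices, block$faces[-1, ])
  expect_error(classify_coverage(open_mesh, cup), "not watertight")
})

test_that("quadrant planes satisfy their defining contracts", {
  hip <- test_hip()
  lm <- hip$landmarks
  fr <- hip$frame
  cc <- hip$socket_center
  qp <- quadrant_planes(lm, fr, cc)
  # both planes contain the cup centre
  expect_lt(point_plane_distance(qp$sagittal_q, cc), 1e-9)
  expect_lt(point_plane_distance(qp$horizontal_q, cc), 1e-9)
  # sagittal plane contains both ASIS
  expect_lt(point_plane_distance(qp$sagittal_q, lm$asis_left), 1e-9)
  expect_lt(point_plane_distance(qp$sagittal_q, lm$asis_right), 1e-9)
  # mutual perpendicularity
  n1 <- c(qp$sagittal_q$a, qp$sagittal_q$b, qp$sagittal_q$c)
  n2 <- c(qp$horizontal_q$a, qp$horizontal_q$b, qp$horizontal_q$c)
  expect_lt(abs(sum(n1 * n2)), 1e-9)
  # orientation: anterior point on the positive sagittal side; the
  # horizontal normal points inferiorly for a cup lateral-inferior to the
  # ipsilateral ASIS
  expect_gt(point_plane_distance(qp$sagittal_q, cc + 10 * fr$anterior_axis,
                                 signed = TRUE), 0)
  expect_lt(sum(n2 * fr$superior_axis), 0)
  # degenerate: cup centre on the inter-ASIS line
  expect_error(quadrant_planes(lm, fr, c(0, 0, 80)), "collinear")
  # equivariance
  tr <- random_rigid_transform(8)
  qp2 <- quadrant_planes(apply_transform(tr, lm), build_pelvic_frame(
    apply_transform(tr, lm)), apply_transform(tr, cc))
  p_probe <- apply_transform(tr, cc + c(3, 4, 5))
  expect_equal(point_plane_distance(qp2$sagittal_q, p_probe),
               point_plane_distance(qp$sagittal_q, cc + c(3, 4, 5)),
               tolerance = 1e-9)
})

test_that("segmental ratios partition the total exactly", {
  run <- test_hip_run()
  ucrs <- run$details[[1]]$ucrs
  expect_equal(ucrs$asucr + ucrs$aiucr + ucrs$psucr + ucrs$piucr,
               ucrs$tucr, tolerance = 1e-12)
  expect_equal(sum(ucrs$uncovered_area_mm2) / ucrs$total_area_mm2,
               ucrs$tucr, tolerance = 1e-12)
  # a fully uncovered cup split by symmetric planes gives four quarters
  pose <- cup_pose(c(0, 0, 0), c(0, 0, -1))
  cup <- build_cup_mesh(eggshell_spec(subdivision = 4), pose,
                        "outer_shell_only")
  far <- box_mesh(c(200, 200, 200), c(240, 240, 240))
  cov <- classify_coverage(far, cup, eps = 0)
  planes <- list(sagittal_q = plane(1, 0, 0, 0),
                 horizontal_q = plane(0, 1, 0, 0))
  class(planes) <- "cc_qplanes"
  u4 <- segmental_ucrs(cov, planes)
  expect_equal(c(u4$asucr, u4$aiucr, u4$psucr, u4$piucr),
               rep(0.25, 4), tolerance = 0.005)
  # tucr = 0 implies all four segments are 0
  hipf <- test_hip_full_support()
  runf <- run_pipeline(list(hipf))
  expect_equal(runf$records$asucr + runf$records$psucr, 0,
               tolerance = 0.002)
})

test_that("adding bone never increases any segmental ratio", {
  fx <- half_space_fixture(11)
  cup <- build_cup_mesh(eggshell_spec(), fx$pose, "outer_shell_only")
  lmq <- quadrant_planes(fx$landmarks, fx$frame, fx$pose$center)
  cov1 <- classify_coverage(fx$bone, cup, eps = 0.1)
  u1 <- segmental_ucrs(cov1, lmq)
  # union with a big block swallowing half the exposed zone
  extra <- box_mesh(fx$pose$center + c(-60, -60, -10),
                    fx$pose$center + c(60, 60, 60))
  cov2 <- list(covered = cov1$covered | point_in_solid(extra, cov1$centroids,
                                                       eps = 0.1),
               face_areas = cov1$face_areas, centroids = cov1$centroids,
               total_area_mm2 = cov1$total_area_mm2)
  cov2$uncovered_area_mm2 <- sum(cov2$face_areas[!cov2$covered])
  cov2$tucr <- cov2$uncovered_area_mm2 / cov2$total_area_mm2
  class(cov2) <- "cc_coverage"
  u2 <- segmental_ucrs(cov2, lmq)
  expect_lte(u2$asucr, u1$asucr + 1e-12)
  expect_lte(u2$aiucr, u1$aiucr + 1e-12)
  expect_lte(u2$psucr, u1$psucr + 1e-12)
  expect_lte(u2$piucr, u1$piucr + 1e-12)
  expect_lte(u2$tucr, u1$tucr + 1e-12)
})

test_that("coverage is stable under cup-mesh refinement", {
  for (gap in c(0, 11)) {
    fx <- half_space_fixture(gap)
    t3 <- fixture_tucr(fx, subdivision = 3)
    t4 <- fixture_tucr(fx, subdivision = 4)
    expect_lt(abs(t4 - t3), 0.01)
  }
})
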