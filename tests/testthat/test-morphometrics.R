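# Upward-facing hemispherical bowl pocket: inner radius rho, opening at
# z = 0, deepest point at (0, 0, -rho).  Landmarks sit on the bowl rim.
bowl_fixture <- function(rho = 22) {
  b <- cupcoverage:::axis_basis(c(0, 0, -1))
  shell <- cupcoverage:::spherical_shell_mesh(
    c(0, 0, 0), c(0, 0, -1), b$e1, b$e2, rho, rho + 6, res_deg = 2)
  ang <- 2 * pi * (0:23) / 24
  rim <- cbind(rho * cos(ang), rho * sin(ang), 0)
  lm <- pelvic_landmarks(c(-120, 0, 80), c(120, 0, 80), c(-15, 0, 0),
                         c(15, 0, 0), c(0, -rho, 0), c(0, rho, 0),
                         c(0, 0, -rho), rim, side = "right")
  list(bone = shell, landmarks = lm, frame = build_pelvic_frame(lm),
       rho = rho)
}

test_that("acetabular height is the rim-to-lower-edge perpendicular distance", {
  bf <- bowl_fixture()
  h <- acetabular_height(bf$landmarks, bf$frame)
  expect_equal(h, bf$rho, tolerance = 1e-9)
  # axis-aligned trivial case: lower edge at 0, highest rim point at 32
  lm <- pelvic_landmarks(c(-120, 0, 80), c(120, 0, 80), c(-15, 0, 0),
                         c(15, 0, 0), c(88, -20, -10), c(90, 0, 5),
                         c(88, -20, 0),
                         rbind(c(80, -10, 32), c(96, -30, 5)),
                         side = "right")
  fr <- build_pelvic_frame(lm)
  expect_equal(acetabular_height(lm, fr), 32, tolerance = 1e-12)
  # all rim points at the lower-edge level: degenerate, flagged
  lm0 <- pelvic_landmarks(c(-120, 0, 80), c(120, 0, 80), c(-15, 0, 0),
                          c(15, 0, 0), c(88, -20, -10), c(90, 0, 5),
                          c(88, -20, 0),
                          rbind(c(80, -10, 0), c(96, -30, 0)),
                          side = "right")
  expect_warning(h0 <- acetabular_height(lm0, fr), "degenerate")
  expect_equal(h0, 0)
})

test_that("A-P diameter at half height matches the spherical chord", {
  bf <- bowl_fixture()
  h <- acetabular_height(bf$landmarks, bf$frame)
  r <- ap_diameter(bf$bone, bf$landmarks, bf$frame, h)
  chord <- 2 * sqrt(bf$rho^2 - (bf$rho - h / 2)^2)
  expect_equal(r, chord, tolerance = 0.5)
  # slab far above the socket: empty intersection
  expect_error(ap_diameter(bf$bone, bf$landmarks, bf$frame, 200),
               "slab")
})

test_that("synthetic hips recover their height and diameter targets", {
  hip <- test_hip()
  h <- acetabular_height(hip$landmarks, hip$frame)
  r <- ap_diameter(hip$bone, hip$landmarks, hip$frame, h)
  expect_equal(h, hip$ground_truth$height_mm, tolerance = 0.5)
  expect_equal(r, hip$ground_truth$ap_diameter_mm, tolerance = 0.5)
  # rigid invariance of both metrics
  tr <- random_rigid_transform(23)
  lm2 <- apply_transform(tr, hip$landmarks)
  fr2 <- build_pelvic_frame(lm2)
  bone2 <- apply_transform(tr, hip$bone)
  expect_equal(acetabular_height(lm2, fr2), h, tolerance = 1e-6)
  expect_equal(ap_diameter(bone2, lm2, fr2, h), r, tolerance = 1e-6)
})

test_that("the volume proxy is the exact product H * R^2", {
  expect_equal(volume_proxy(31.99, 25.23), 31.99 * 25.23^2)
  expect_equal(volume_proxy(31.99, 25.23), 20363.33, tolerance = 0.01)
  expect_equal(volume_proxy(1, 1), 1)
  expect_equal(volume_proxy(2, 10), 2 * volume_proxy(1, 10))
  expect_equal(volume_proxy(1, 20), 4 * volume_proxy(1, 10))
  expect_error(volume_proxy(-1, 10), "must be > 0")
  expect_error(volume_proxy(10, 0), "must be > 0")
})
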