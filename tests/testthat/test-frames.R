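canonical_landmarks <- function(side = "right") {
  pelvic_landmarks(c(-120, 0, 80), c(120, 0, 80), c(-15, 0, 0), c(15, 0, 0),
                   c(88, -20, -10), c(90, 0, 5), c(88, -20, -12),
                   rbind(c(80, -10, 20), c(96, -30, -10)), side = side)
}

test_that("canonical landmarks give the canonical frame", {
  fr <- build_pelvic_frame(canonical_landmarks("right"))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$lateral_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$anterior_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$superior_axis, c(0, 0, 1), tolerance = 1e-12)
  # left side flips only the lateral axis
  fl <- build_pelvic_frame(canonical_landmarks("left"))
  expect_equal(fl$lateral_axis, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(fl$anterior_axis, fr$anterior_axis, tolerance = 1e-12)
  expect_equal(fl$superior_axis, fr$superior_axis, tolerance = 1e-12)
})

test_that("frame planes pass through their defining landmarks and are orthogonal", {
  lm <- canonical_landmarks()
  fr <- build_pelvic_frame(lm)
  for (pt in list(lm$asis_left, lm$asis_right, fr$origin)) {
    expect_lt(point_plane_distance(fr$coronal_plane, pt), 1e-9)
  }
  n1 <- c(fr$coronal_plane$a, fr$coronal_plane$b, fr$coronal_plane$c)
  n2 <- c(fr$sagittal_plane$a, fr$sagittal_plane$b, fr$sagittal_plane$c)
  n3 <- c(fr$horizontal_plane$a, fr$horizontal_plane$b,
          fr$horizontal_plane$c)
  expect_lt(abs(sum(n1 * n2)), 1e-9)
  expect_lt(abs(sum(n1 * n3)), 1e-9)
  expect_lt(abs(sum(n2 * n3)), 1e-9)
  # ASIS sit superior to the origin; anterior side is the +y side here
  expect_gt(signed_coordinates(fr, lm$asis_left)[3], 0)
  expect_gt(point_plane_distance(fr$coronal_plane, c(0, 10, 0),
                                 signed = TRUE), 0)
})

test_that("frame construction is equivariant under rigid transforms", {
  lm <- canonical_landmarks()
  fr <- build_pelvic_frame(lm)
  set.seed(21)
  for (k in 1:5) {
    tr <- random_rigid_transform()
    fr2 <- build_pelvic_frame(apply_transform(tr, lm))
    expect_equal(fr2$origin, apply_transform(tr, fr$origin),
                 tolerance = 1e-9)
    for (ax in c("lateral_axis", "anterior_axis", "superior_axis")) {
      expect_equal(fr2[[ax]], as.numeric(tr$rotation %*% fr[[ax]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("signed coordinates invert exactly and match direct projection", {
  fr <- build_pelvic_frame(canonical_landmarks())
  expect_equal(signed_coordinates(fr, fr$origin), c(0, 0, 0))
  expect_equal(signed_coordinates(fr, fr$origin + 10 * fr$anterior_axis),
               c(0, 10, 0), tolerance = 1e-12)
  set.seed(22)
  for (k in 1:10) {
    p <- rnorm(3, sd = 50)
    co <- signed_coordinates(fr, p)
    expect_equal(from_frame_coordinates(fr, co), p, tolerance = 1e-9)
    expect_equal(co[1], sum((p - fr$origin) * fr$lateral_axis),
                 tolerance = 1e-12)
  }
})

test_that("degenerate landmark configurations error", {
  expect_error(
    pelvic_landmarks(c(0, 0, 0), c(0.5, 0, 0), c(-15, 0, 0), c(15, 0, 0),
                     c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                     matrix(0, 1, 3)),
    "1 mm")
  # all APP points on one line
  lm <- suppressWarnings(
    pelvic_landmarks(c(-60, 0, 0), c(60, 0, 0), c(-15, 0, 0), c(15, 0, 0),
                     c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), matrix(0, 1, 3)))
  expect_error(build_pelvic_frame(lm), "collinear")
})

test_that("landmark JSON round-trips and validates missing keys", {
  lm <- canonical_landmarks()
  f <- tempfile(fileext = ".json")
  write_landmarks_json(lm, f)
  back <- read_landmarks_json(f)
  expect_equal(back$asis_left, lm$asis_left)
  expect_equal(back$acetabular_rim_points, lm$acetabular_rim_points)
  expect_equal(back$side, lm$side)
  j <- jsonlite::read_json(f)
  j$asis_left <- NULL
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  expect_error(read_landmarks_json(f), "asis_left")
  unlink(f)
})
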