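test_that("generated hips are watertight with consistent ground truth", {
  hip <- test_hip()
  expect_true(hip$bone$watertight)
  expect_gt(mesh_volume(hip$bone), 0)
  g <- hip$ground_truth
  ratios <- c(g$asucr, g$aiucr, g$psucr, g$piucr, g$tucr)
  expect_true(all(ratios >= 0 & ratios <= 1))
  expect_equal(g$asucr + g$aiucr + g$psucr + g$piucr, g$tucr,
               tolerance = 1e-12)
  # requested fractions times quadrant weights approximate the gt ratios
  # (realized windows differ from the continuous target only by cell
  # discretization)
  w <- g$quadrant_weights
  f <- hip$params$deficiency
  expect_lt(abs(g$asucr - f[["AS"]] * w[["AS"]]), 0.01)
  expect_lt(abs(g$psucr - f[["PS"]] * w[["PS"]]), 0.01)
})

test_that("zero deficiency yields a fully supporting socket", {
  hip <- test_hip_full_support()
  expect_equal(hip$ground_truth$tucr, 0)
  run <- run_pipeline(list(hip))
  expect_equal(run$records$tucr, 0, tolerance = 0.002)
})

test_that("total wall loss leaves the cup floating on a tangent plate", {
  hip <- generate_hip(synthetic_hip_params(
    deficiency = c(AS = 1, AI = 1, PS = 1, PI = 1)))
  expect_true(hip$bone$watertight)
  expect_equal(hip$ground_truth$tucr, 1)
  run <- run_pipeline(list(hip))
  expect_equal(run$records$tucr, 1, tolerance = 0.01)
})

test_that("infeasible deficiency fractions raise a constructive error", {
  expect_error(
    generate_hip(synthetic_hip_params(
      deficiency = c(AS = 0.98, AI = 0.1, PS = 0.3, PI = 0.1))),
    "infeasible")
  expect_error(
    generate_hip(synthetic_hip_params(height_mm = 49, ap_diameter_mm = 49)),
    "infeasible")
})

test_that("hip generation is deterministic", {
  p <- synthetic_hip_params(seed = 7)
  h1 <- generate_hip(p)
  h2 <- generate_hip(p)
  expect_identical(h1$bone$vertices, h2$bone$vertices)
  expect_identical(h1$ground_truth, h2$ground_truth)
})

test_that("cohort sampling honors its moments and determinism", {
  # degenerate cohort: zero SDs reproduce the means exactly
  cp0 <- cohort_params(n_hips = 1, height_sd = 0, ap_sd = 0,
                       deficiency_sd = c(AS = 0, AI = 0, PS = 0, PI = 0))
  d0 <- sample_cohort_params(cp0)
  expect_equal(d0$height_mm, 31.99)
  expect_equal(d0$ap_diameter_mm, 25.23)
  expect_equal(d0$f_PS, 0.270)
  # large-sample mean of H within 3 SE of the generating mean
  cp <- cohort_params(n_hips = 500, master_seed = 1234)
  d <- sample_cohort_params(cp)
  expect_lt(abs(mean(d$height_mm) - 31.99), 3 * 4.09 / sqrt(500) + 0.1)
  expect_true(all(d$height_mm >= 15 & d$height_mm <= 50))
  expect_true(all(d$f_AS >= 0 & d$f_AS <= 1))
  # bit-reproducibility
  expect_identical(d, sample_cohort_params(cp))
  # generated cohorts reproduce too
  cps <- cohort_params(n_hips = 2, master_seed = 99)
  c1 <- generate_cohort(cps)
  c2 <- generate_cohort(cps)
  expect_identical(c1[[1]]$bone$vertices, c2[[1]]$bone$vertices)
  expect_identical(c1[[2]]$ground_truth, c2[[2]]$ground_truth)
  expect_error(cohort_params(n_hips = 0), "n_hips")
})

test_that("PS and PI deficiencies are positively correlated across cohorts", {
  hits <- 0
  for (k in 1:100) {
    d <- sample_cohort_params(cohort_params(n_hips = 30, master_seed = k))
    if (cor(d$f_PS, d$f_PI) > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("half-space fixture geometry matches its closed form", {
  fx <- half_space_fixture(11)
  expect_true(fx$bone$watertight)
  expect_equal(fx$gt$uncovered_fraction, 0.5)
  # spherical-zone closed form: uncovered fraction = gap / r
  expect_equal(half_space_fixture(5.5)$gt$uncovered_fraction, 0.25)
  expect_equal(half_space_fixture(-11)$gt$uncovered_fraction, 0)
  expect_error(half_space_fixture(30), "radius")
})
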