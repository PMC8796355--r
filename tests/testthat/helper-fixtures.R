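# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a standard synthetic hip with moderate deficiencies
test_hip <- function() {
  cached("hip_default", function() {
    generate_hip(synthetic_hip_params(
      deficiency = c(AS = 0.2, AI = 0.1, PS = 0.3, PI = 0.1)))
  })
}

# full pipeline result for the standard hip
test_hip_run <- function() {
  cached("hip_default_run", function() {
    run_pipeline(list(test_hip()))
  })
}

# a fully supported (zero-deficiency) hip
test_hip_full_support <- function() {
  cached("hip_full", function() {
    generate_hip(synthetic_hip_params(
      deficiency = c(AS = 0, AI = 0, PS = 0, PI = 0)))
  })
}

# uncovered fraction of the dome against an analytic half-space via the
# facet pipeline at a directly specified pose
fixture_tucr <- function(fx, subdivision = 3, eps = 0.1) {
  cup <- build_cup_mesh(eggshell_spec(subdivision = subdivision), fx$pose,
                        "outer_shell_only")
  classify_coverage(fx$bone, cup, eps = eps)$tucr
}

# Monte-Carlo oracle for the half-space fixtures: uniform points on the
# dome classified against the analytic half-space (never via the mesh).
halfspace_mc_oracle <- function(gap_mm, n = 1e6, r = 22, seed = 99,
                                orientation = "polar") {
  set.seed(seed)
  # uniform on the dome about pole p: cos(theta) ~ U(0,1)
  ct <- runif(n)
  st <- sqrt(1 - ct^2)
  ang <- runif(n, 0, 2 * pi)
  if (orientation == "polar") {
    # uncovered iff depth along the pole is short of the face offset
    mean(r * ct < gap_mm)
  } else {
    # face contains the axis: uncovered on one side of it
    mean(st * cos(ang) < 0)
  }
}
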