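test_that("the canonical profile satisfies its structural invariants", {
  prof <- canonical_profile()
  expect_s3_class(prof, "thickness_profile")
  expect_equal(nrow(prof), 20)
  expect_equal(rowSums(prof[c("X_M", "X_L", "X_T")]), rep(1, 20),
               tolerance = 1e-12)
  expect_equal(prof$s, seq(0, 1, length.out = 20))
})

test_that("generation is deterministic under a fixed seed", {
  expect_identical(canonical_profile(), canonical_profile())
  a <- canonical_profile(profile_spec(seed = 5))
  b <- canonical_profile(profile_spec(seed = 6))
  expect_false(identical(a, b))
  expect_identical(attr(a, "seed"), 5)
})

test_that("the canonical profile reproduces the graded wall architecture", {
  prof <- canonical_profile()
  # longitudinal-fiber monolayer at the split region
  expect_gte(prof$X_L[1], 0.85)
  # longitudinal fibers vanish just before the vascular bundle
  window <- prof$s >= 0.7 & prof$s <= 0.8
  expect_lte(min(prof$X_L[window]), 0.05)
  expect_true(prof$s[which.min(prof$X_L)] >= 0.7 &&
                prof$s[which.min(prof$X_L)] <= 0.8)
  # parenchyma and transverse fibers dominate there
  expect_gt(min((prof$X_M + prof$X_T)[window]), 0.9)
  # mostly longitudinal fibers again at the far side
  expect_gt(prof$X_L[20], 0.6)
})

test_that("generated profiles satisfy consumer invariants across seeds", {
  for (seed in 1:12) {
    prof <- canonical_profile(profile_spec(seed = seed, residual_sd = 0.02))
    expect_silent(thickness_profile(prof))
    st <- anticorrelation_stats(prof)
    expect_equal(st$sign_M_vs_L, -1)
  }
})

test_that("zero-curvature profiles synthesize straight traces", {
  flat <- curvature_profile(tibble::tibble(s = c(0, 1), kappa = c(0, 0)))
  series <- arcs_from_profile(flat, n_segments = 4)
  for (tr in series$traces) {
    expect_true(fit_circle(tr)$straight)
  }
})

test_that("arc geometry is exact: a semicircle spans its diameter", {
  curv <- curvature_profile(tibble::tibble(s = c(0, 1), kappa = c(0.5, 0.5)))
  series <- arcs_from_profile(curv, n_segments = 1, arc_length = 2 * pi,
                              points_per_segment = 101)
  pts <- series$traces[[1]]$points
  chord <- sqrt((pts$x[101] - pts$x[1])^2 + (pts$y[101] - pts$y[1])^2)
  expect_equal(chord, 4, tolerance = 1e-9)
})

test_that("segment widths divide the circumference equally", {
  curv <- curvature_profile(tibble::tibble(s = c(0, 1), kappa = c(0.2, 0.3)))
  series <- arcs_from_profile(curv, n_segments = 8, circumference = 2.4)
  expect_equal(vapply(series$traces, `[[`, numeric(1), "width"),
               rep(0.3, 8))
})

test_that("noiseless azimuth fixtures return the exact truth per cell", {
  fx <- azimuth_fixture(8, noise = noise_spec(mfa_noise_sd_deg = 0, seed = 1))
  vals <- vapply(fx$rois, function(r) estimate_cell_mfa(fx$map, r),
                 numeric(1))
  expect_equal(vals, rep(8, 5), tolerance = 1e-10)
  fx90 <- azimuth_fixture(90, noise = noise_spec(mfa_noise_sd_deg = 0,
                                                 seed = 1))
  vals90 <- vapply(fx90$rois, function(r) estimate_cell_mfa(fx90$map, r),
                   numeric(1))
  expect_equal(vals90, rep(90, 5), tolerance = 1e-10)
})

test_that("noisy azimuth fixtures recover the truth within the cohort sd", {
  fx <- azimuth_fixture(12, noise = noise_spec(mfa_noise_sd_deg = 2,
                                               seed = 7))
  agg <- aggregate_mfa(vapply(fx$rois,
                              function(r) estimate_cell_mfa(fx$map, r),
                              numeric(1)))
  expect_lt(abs(agg$mfa_mean - 12), agg$mfa_sd)
})

test_that("the fixture background is dark like parenchyma", {
  fx <- azimuth_fixture(8, noise = noise_spec(seed = 2))
  inside <- Reduce(`|`, lapply(fx$rois, `[[`, "mask"))
  expect_gt(min(fx$map$retardance[inside]), 50)
  expect_lt(max(fx$map$retardance[!inside]), 5)
})

test_that("shrinkage fixtures hit their nominal ratio", {
  exact <- shrinkage_fixture(ratio = 1, noise_cv = 0)
  expect_equal(shrinkage_ratio(exact)$ratio_percent, 100, tolerance = 1e-12)
  half <- shrinkage_fixture(ratio = 0.5, noise_cv = 0)
  expect_equal(shrinkage_ratio(half)$ratio_percent, 50, tolerance = 1e-12)
  expect_identical(shrinkage_fixture(), shrinkage_fixture())
})

test_that("profile spec validation rejects inconsistent knots", {
  bad <- default_profile_knots()
  bad$X_M[2] <- 0.9
  expect_error(profile_spec(knots = bad), class = "hygrolam_spec_error")
  expect_error(profile_spec(n_stations = 1), class = "hygrolam_spec_error")
  expect_error(noise_spec(arc_point_sd = -1), class = "hygrolam_spec_error")
})
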