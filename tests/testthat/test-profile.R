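make_profile <- function(s, M, L, T) {
  thickness_profile(tibble::tibble(s = s, X_M = M, X_L = L, X_T = T))
}

test_that("profiles with bad station sums or ordering are rejected by name", {
  expect_error(
    thickness_profile(data.frame(s = c(0, 0.5), X_M = c(0.5, 0.3),
                                 X_L = c(0.5, 0.3), X_T = c(0, 0.2))),
    regexp = "station 2.*sums to 0.8", class = "hygrolam_profile_error"
  )
  expect_error(
    thickness_profile(data.frame(s = c(0.5, 0.2), X_M = c(1, 1),
                                 X_L = c(0, 0), X_T = c(0, 0))),
    class = "hygrolam_profile_error"
  )
  expect_error(
    thickness_profile(data.frame(s = 0.1, X_M = 1.2, X_L = -0.2, X_T = 0)),
    class = "hygrolam_profile_error"
  )
})

test_that("station_laminate builds the inner-to-outer capsule stack", {
  prof <- make_profile(c(0, 0.5, 1),
                       M = c(0, 0.5, 0.2),
                       L = c(1, 0, 0.3),
                       T = c(0, 0.5, 0.5))
  # pure longitudinal-fiber monolayer at the split
  lam1 <- station_laminate(prof, 1)
  expect_length(lam1$layers, 1)
  expect_equal(lam1$layers[[1]]$orientation_deg, 0)
  # transverse fibers inside, parenchyma outside near the vascular bundle
  lam2 <- station_laminate(prof, 2)
  expect_length(lam2$layers, 2)
  expect_equal(lam2$layers[[1]]$orientation_deg, 90)
  expect_equal(lam2$layers[[2]]$hygro_strain, -0.7)
  # bookkeeping: thicknesses X_T, X_L, X_M in inner-to-outer order
  lam3 <- station_laminate(prof, 3)
  expect_equal(vapply(lam3$layers, `[[`, numeric(1), "thickness"),
               c(0.5, 0.3, 0.2))
})

test_that("a station with all-zero fractions is rejected", {
  prof <- tibble::tibble(s = 0, X_M = 0, X_L = 0, X_T = 0)
  expect_error(thickness_profile(prof), class = "hygrolam_profile_error")
})

test_that("uniform profiles give a flat normalized curvature of one", {
  prof <- make_profile(seq(0, 1, length.out = 5),
                       M = rep(0.5, 5), L = rep(0.2, 5), T = rep(0.3, 5))
  curv <- predict_curvature_profile(prof)
  expect_equal(curv$kappa_norm, rep(1, 5), tolerance = 1e-12)
})

test_that("stations without parenchyma predict exactly zero curvature", {
  prof <- make_profile(c(0, 1), M = c(0, 0.5), L = c(0.6, 0.2),
                       T = c(0.4, 0.3))
  curv <- predict_curvature_profile(prof)
  expect_identical(curv$kappa[1], 0)
  expect_gt(curv$kappa[2], 0)
})

test_that("peak location picks the maximum, breaking ties toward small s", {
  curv <- curvature_profile(tibble::tibble(
    s = c(0.2, 0.7, 0.9), kappa = c(0.1, 1.0, 0.4)
  ))
  expect_equal(peak_location(curv), 0.7)
  tied <- curvature_profile(tibble::tibble(
    s = c(0.1, 0.4, 0.8), kappa = c(1, 1, 0.2)
  ))
  expect_equal(peak_location(tied), 0.1)
  flat <- curvature_profile(tibble::tibble(s = c(0, 1), kappa = c(0, 0)))
  expect_warning(res <- peak_location(flat), class = "hygrolam_no_movement")
  expect_true(is.na(res))
})

test_that("perfect complementarity gives r2 = 1 with negative sign", {
  s <- seq(0, 1, length.out = 10)
  M <- seq(0.1, 0.8, length.out = 10)
  prof <- make_profile(s, M = M, L = 0.9 - M, T = rep(0.1, 10))
  expect_warning(st <- anticorrelation_stats(prof),
                 class = "hygrolam_degenerate_error") # X_T is constant
  expect_equal(st$r2_M_vs_L, 1, tolerance = 1e-12)
  expect_equal(st$sign_M_vs_L, -1)
  expect_true(is.na(st$r2_M_vs_T))
})

test_that("independent thickness series show near-zero squared correlation", {
  set.seed(11)
  n <- 400
  M <- 0.3 + runif(n, -0.1, 0.1)
  T <- 0.3 + runif(n, -0.1, 0.1)
  prof <- make_profile(seq(0, 1, length.out = n), M, 1 - M - T, T)
  st <- anticorrelation_stats(prof)
  expect_lt(st$r2_M_vs_T, 0.02)
})

test_that("comparing a profile with itself is exact", {
  curv <- predict_curvature_profile(canonical_profile())
  cmp <- compare_profiles(curv, curv)
  expect_equal(cmp$rmse_norm, 0)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$delta_peak_s, 0)
})

test_that("degenerate and disjoint comparisons are flagged", {
  curv <- predict_curvature_profile(canonical_profile())
  const <- curvature_profile(tibble::tibble(
    s = c(0, 0.5, 1), kappa = c(1, 1, 1)
  ))
  expect_warning(cmp <- compare_profiles(curv, const),
                 class = "hygrolam_degenerate_error")
  expect_true(is.na(cmp$pearson_r))
  left <- curvature_profile(tibble::tibble(s = c(0, 0.1), kappa = c(1, 2)))
  right <- curvature_profile(tibble::tibble(s = c(0.8, 0.9), kappa = c(1, 2)))
  expect_error(compare_profiles(left, right),
               class = "hygrolam_profile_error")
})

test_that("prediction is deterministic", {
  prof <- canonical_profile()
  expect_identical(predict_curvature_profile(prof),
                   predict_curvature_profile(prof))
})

test_that("the peak sits where longitudinal fibers vanish but parenchyma remains", {
  # mechanical consequence, not hard-coded: X_L -> 0 on [0.5, 0.7]
  s <- seq(0, 1, length.out = 21)
  L <- ifelse(s >= 0.5 & s <= 0.7, 0, 0.4)
  M <- rep(0.4, 21)
  T <- 1 - M - L
  prof <- make_profile(s, M, L, T)
  pk <- peak_location(predict_curvature_profile(prof))
  expect_gte(pk, 0.5)
  expect_lte(pk, 0.7)
})
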