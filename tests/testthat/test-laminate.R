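test_that("single-layer laminate about its midplane has zero coupling", {
  lam <- laminate(elastic_layer(0.8, 30, 20, 5))
  blocks <- attr(assemble_abd(lam), "blocks")
  expect_equal(blocks$B, matrix(0, 3, 3), tolerance = 1e-15)
})

test_that("single isotropic layer matches the plate closed forms", {
  E <- 2
  nu <- 0.3
  h <- 0.7
  lam <- laminate(elastic_layer(h, 0, E, E, nu12 = nu,
                                G12 = E / (2 * (1 + nu))))
  blocks <- attr(assemble_abd(lam), "blocks")
  expect_equal(blocks$A[1, 1], h * E / (1 - nu^2), tolerance = 1e-12)
  expect_equal(blocks$D[1, 1], blocks$A[1, 1] * h^2 / 12, tolerance = 1e-12)
})

test_that("ABD assembly and hygroscopic resultants match brute-force quadrature", {
  set.seed(7)
  for (i in 1:40) {
    lam <- random_stack()
    abd <- assemble_abd(lam)
    nm <- hygro_resultants(lam)
    orc <- oracle_laminate_integrals(lam)
    abd_orc <- rbind(cbind(orc$A, orc$B), cbind(orc$B, orc$D))
    expect_lt(max(rel_diff(unclass(abd), abd_orc)), 1e-9)
    expect_lt(max(rel_diff(nm, c(orc$N, orc$M))), 1e-9)
  }
})

test_that("zero hygroscopic strain gives zero resultants and zero state", {
  lam <- laminate(
    elastic_layer(0.3, 90, 20, 5),
    elastic_layer(0.5, 0, 20, 5)
  )
  expect_equal(hygro_resultants(lam), rep(0, 6))
  st <- solve_free_hygro(lam)
  expect_equal(st$curvatures, rep(0, 3))
  expect_equal(st$midplane_strains, rep(0, 3))
})

test_that("a single shrinking isotropic layer carries no bending moment", {
  lam <- laminate(elastic_layer(0.4, 0, 0.1, 0.1, hygro_strain = -0.7))
  nm <- hygro_resultants(lam)
  expect_equal(nm[4:6], rep(0, 3), tolerance = 1e-15)
  st <- solve_free_hygro(lam)
  expect_equal(st$curvatures, rep(0, 3), tolerance = 1e-12)
  # free shrinkage: the midplane simply contracts by the hygro strain
  expect_equal(st$midplane_strains[1:2], rep(-0.7, 2), tolerance = 1e-12)
})

test_that("isotropic bilayer reproduces the closed-form bimetal curvature", {
  grid <- expand.grid(m = c(0.1, 0.5, 1, 2, 10), n = c(0.1, 0.5, 1, 2, 10))
  eps <- -0.7
  for (i in seq_len(nrow(grid))) {
    h2 <- 1 / (1 + grid$m[i])
    h1 <- 1 - h2
    E2 <- 1
    E1 <- grid$n[i]
    lam <- laminate(
      elastic_layer(h1, 0, E1, E1, nu12 = 0.3, hygro_strain = eps),
      elastic_layer(h2, 0, E2, E2, nu12 = 0.3)
    )
    k_plate <- solve_free_hygro(lam)$kappa_L
    k_beam <- timoshenko_bilayer_curvature(h1, h2, E1, E2, eps)
    expect_lt(abs(k_plate - k_beam) / abs(k_beam), 1e-6)
  }
})

test_that("the solve is linear in the hygroscopic strain", {
  base <- canonical_profile(profile_spec(residual_sd = 0))
  for (alpha in c(0.25, 0.5, 1.25)) {
    k1 <- solve_free_hygro(station_laminate(base, 12))$kappa_L
    pars <- model_params(eps_parenchyma = -0.7 * alpha)
    k2 <- solve_free_hygro(station_laminate(base, 12, pars))$kappa_L
    expect_equal(k2, alpha * k1, tolerance = 1e-12)
  }
})

test_that("midplane-symmetric stacks do not bend", {
  mk <- function(th, ang, eps) {
    elastic_layer(th, ang, 20, 5, hygro_strain = eps)
  }
  lam <- laminate(mk(0.2, 30, -0.5), mk(0.3, 80, 0.1),
                  mk(0.3, 80, 0.1), mk(0.2, 30, -0.5))
  st <- solve_free_hygro(lam)
  expect_equal(st$curvatures, rep(0, 3), tolerance = 1e-10)
})

test_that("the physical curvature does not depend on the reference plane", {
  layers <- list(
    elastic_layer(0.3, 90, 20, 5),
    elastic_layer(0.2, 0, 20, 5),
    elastic_layer(0.5, 0, 0.1, 0.1, hygro_strain = -0.7)
  )
  k_mid <- solve_free_hygro(laminate(layers))$curvatures
  for (zr in c(0, 0.25, 1)) {
    k_ref <- solve_free_hygro(laminate(layers, z_ref = zr))$curvatures
    expect_equal(k_ref, k_mid, tolerance = 1e-9)
  }
})

test_that("thicker longitudinal fibers monotonically damp longitudinal bending", {
  kappas <- vapply(seq(0.05, 0.6, by = 0.05), function(xl) {
    lam <- laminate(
      elastic_layer(0.3, 90, 20, 5),
      elastic_layer(xl, 0, 20, 5),
      elastic_layer(0.5, 0, 0.1, 0.1, hygro_strain = -0.7)
    )
    solve_free_hygro(lam)$kappa_L
  }, numeric(1))
  expect_true(all(kappas > 0))
  expect_true(all(diff(abs(kappas)) < 0))
})

test_that("drying bends the capsule stack outward (positive kappa_L)", {
  lam <- laminate(
    elastic_layer(0.3, 90, 20, 5),
    elastic_layer(0.2, 0, 20, 5),
    elastic_layer(0.5, 0, 0.1, 0.1, hygro_strain = -0.7)
  )
  expect_gt(solve_free_hygro(lam)$kappa_L, 0)
})

test_that("empty laminates are rejected", {
  expect_error(laminate(), class = "hygrolam_laminate_error")
  expect_error(laminate(list()), class = "hygrolam_laminate_error")
})

test_that("tidy() lays out layers inner to outer with interfaces", {
  lam <- laminate(
    elastic_layer(0.3, 90, 20, 5, name = "transverse fibers"),
    elastic_layer(0.7, 0, 0.1, 0.1, hygro_strain = -0.7, name = "parenchyma")
  )
  tb <- tidy(lam)
  expect_equal(tb$z_lower, c(-0.5, -0.2))
  expect_equal(tb$z_upper, c(-0.2, 0.5))
  expect_equal(tb$name, c("transverse fibers", "parenchyma"))
})
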