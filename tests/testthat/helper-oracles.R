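# Independent oracles used across tests. These deliberately avoid the code
# paths they check: stiffness rotation is done on the 4th-order elasticity
# tensor, and laminate integrals by brute-force midpoint quadrature.

# Plane-stress stiffness rotated via the full 4th-order tensor transform
# C'_ijkl = R_ia R_jb R_kc R_ld C_abcd, then repacked in Voigt notation
# with engineering shear.
oracle_rotated_stiffness <- function(E1, E2, G12, nu12, theta_deg) {
  nu21 <- nu12 * E2 / E1
  d <- 1 - nu12 * nu21
  Q <- matrix(c(E1 / d, nu12 * E2 / d, 0,
                nu12 * E2 / d, E2 / d, 0,
                0, 0, G12), 3, 3, byrow = TRUE)
  # unpack into C_ijkl (tensor shear strain convention)
  idx <- function(i, j) if (i == j) i else 3L
  C <- array(0, c(2, 2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    v1 <- idx(i, j)
    v2 <- idx(k, l)
    val <- Q[v1, v2]
    # engineering -> tensor shear: Q[.,3] and Q[3,.] already relate
    # stress to engineering strain; tensor components need no extra
    # factor when both indices are repacked symmetrically below.
    C[i, j, k, l] <- val
  }
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  Cp <- array(0, c(2, 2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    s <- 0
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (dd in 1:2) {
      s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, dd] * C[a, b, cc, dd]
    }
    Cp[i, j, k, l] <- s
  }
  matrix(c(
    Cp[1, 1, 1, 1], Cp[1, 1, 2, 2], Cp[1, 1, 1, 2],
    Cp[2, 2, 1, 1], Cp[2, 2, 2, 2], Cp[2, 2, 1, 2],
    Cp[1, 2, 1, 1], Cp[1, 2, 2, 2], Cp[1, 2, 1, 2]
  ), 3, 3, byrow = TRUE)
}

# Brute-force through-thickness quadrature of Q(z) * (1, z, z^2) and of the
# hygroscopic resultants: composite Simpson weights on a per-layer grid
# (exact for the piecewise-polynomial integrands, up to rounding).
oracle_laminate_integrals <- function(lam, slices_per_layer = 64) {
  simpson <- function(f, a, b, n = slices_per_layer) {
    z0 <- a + (seq_len(n) - 1) * (b - a) / n
    z1 <- z0 + (b - a) / n
    zm <- (z0 + z1) / 2
    sum((z1 - z0) / 6 * (f(z0) + 4 * f(zm) + f(z1)))
  }
  A <- B <- D <- matrix(0, 3, 3)
  N <- M <- numeric(3)
  for (k in seq_along(lam$layers)) {
    Qb <- reduced_stiffness(lam$layers[[k]])
    zl <- lam$z[k]
    zu <- lam$z[k + 1]
    A <- A + Qb * simpson(function(z) rep(1, length(z)), zl, zu)
    B <- B + Qb * simpson(identity, zl, zu)
    D <- D + Qb * simpson(function(z) z^2, zl, zu)
    eps <- lam$layers[[k]]$hygro_strain
    if (eps != 0) {
      bvec <- as.numeric(Qb %*% c(eps, eps, 0))
      N <- N + bvec * simpson(function(z) rep(1, length(z)), zl, zu)
      M <- M + bvec * simpson(identity, zl, zu)
    }
  }
  list(A = A, B = B, D = D, N = N, M = M)
}

# A random physically valid stack of 1-5 layers.
random_stack <- function(n_layers = sample(1:5, 1)) {
  layers <- lapply(seq_len(n_layers), function(i) {
    E2 <- runif(1, 0.1, 5)
    E1 <- E2 * runif(1, 1, 10)
    nu12 <- runif(1, 0, min(0.45, 0.95 * sqrt(E1 / E2)))
    elastic_layer(
      thickness = runif(1, 0.05, 1),
      orientation_deg = runif(1, 0, 180),
      E_parallel = E1, E_perp = E2, nu12 = nu12,
      G12 = runif(1, 0.2, 3),
      hygro_strain = runif(1, -0.8, 0.3)
    )
  })
  laminate(layers)
}

# Exact points on a circle of radius R (for trace fixtures).
circle_points <- function(R, theta0, theta1, n, cx = 0, cy = 0) {
  th <- seq(theta0, theta1, length.out = n)
  tibble::tibble(x = cx + R * cos(th), y = cy + R * sin(th))
}

capsule_params <- model_params()

# worst entry difference relative to the overall scale of the reference
rel_diff <- function(a, b) {
  max(abs(a - b)) / max(abs(b))
}
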