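#' Define a single tissue lamina
#'
#' An `elastic_layer` is one ply of the capsule-wall laminate: a slab of
#' tissue with a thickness, an in-plane fiber orientation, plane-stress
#' orthotropic elastic constants, and an isotropic in-plane hygroscopic
#' strain (its free shrinkage or swelling on a change of water content).
#'
#' Orientation is measured from the capsule's longitudinal axis, so 0
#' describes longitudinally oriented fiber cells and 90 the transverse
#' (circumferential) fibers. Moduli are accepted in relative units: only
#' stiffness ratios matter for normalized curvature profiles.
#'
#' @param thickness Layer thickness (> 0), any consistent length unit.
#' @param orientation_deg Fiber-axis angle from the longitudinal axis,
#'   degrees.
#' @param E_parallel,E_perp Young's moduli along and across the fiber axis;
#'   `E_parallel >= E_perp > 0`.
#' @param nu12 Major in-plane Poisson ratio; must satisfy
#'   `0 <= nu12 < sqrt(E_parallel / E_perp)` for a positive-definite
#'   plane-stress stiffness.
#' @param G12 In-plane shear modulus. Default `E_perp / (2 * (1 + nu12))`,
#'   the isotropic relation applied to the matrix-dominated direction.
#' @param hygro_strain Free in-plane hygroscopic strain (dimensionless);
#'   negative values describe shrinkage on drying.
#' @param name Optional label used in printing and error messages.
#'
#' @return An object of class `elastic_layer`.
#' @seealso [laminate()], [reduced_stiffness()]
#' @export
#' @examples
#' elastic_layer(0.3, 0, E_parallel = 20, E_perp = 5)
elastic_layer <- function(thickness, orientation_deg, E_parallel, E_perp,
                          nu12 = 0.3, G12 = NULL, hygro_strain = 0,
                          name = NULL) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (!is.finite(thickness) || thickness <= 0) {
    abort("`thickness` must be a positive finite number.",
          class = "hygrolam_layer_error")
  }
  if (!is.finite(E_parallel) || !is.finite(E_perp) ||
      E_perp <= 0 || E_parallel < E_perp) {
    abort("Moduli must satisfy E_parallel >= E_perp > 0.",
          class = "hygrolam_layer_error")
  }
  if (!is.finite(nu12) || nu12 < 0 || nu12 >= sqrt(E_parallel / E_perp)) {
    abort(
      "`nu12` must lie in [0, sqrt(E_parallel/E_perp)) for a positive-definite stiffness.",
      class = "hygrolam_stiffness_error"
    )
  }
  G12 <- G12 %||% (E_perp / (2 * (1 + nu12)))
  if (!is.finite(G12) || G12 <= 0) {
    abort("`G12` must be positive and finite.",
          class = "hygrolam_layer_error")
  }
  if (!is.finite(hygro_strain)) {
    abort("`hygro_strain` must be finite.", class = "hygrolam_layer_error")
  }
  structure(
    list(
      thickness = thickness,
      orientation_deg = orientation_deg,
      E_parallel = E_parallel,
      E_perp = E_perp,
      nu12 = nu12,
      G12 = G12,
      hygro_strain = hygro_strain,
      name = name
    ),
    class = "elastic_layer"
  )
}

#' @export
print.elastic_layer <- function(x, ...) {
  cat(sprintf(
    "<elastic_layer%s> t = %g, theta = %g deg, E = (%g, %g), nu12 = %g, G12 = %g, eps = %g\n",
    if (is.null(x$name)) "" else paste0(" ", x$name),
    x$thickness, x$orientation_deg, x$E_parallel, x$E_perp,
    x$nu12, x$G12, x$hygro_strain
  ))
  invisible(x)
}

#' Default model parameters for the capsule-wall laminate
#'
#' Bundles the relative tissue stiffnesses and the hygroscopic drive used
#' when a thickness profile is turned into per-station laminates. The
#' default stiffness triplet 20 : 5 : 0.1 expresses fibril-dominated
#' stiffness along the fiber cells, matrix-dominated stiffness across them,
#' and a much softer foam-like parenchyma. Only the parenchyma carries a
#' hygroscopic strain; the crystalline-cellulose fiber layers are treated
#' as hygroscopically inert.
#'
#' @param stiffness_triplet Numeric length 3: modulus along the fibers,
#'   across the fibers, and of the parenchyma, in relative units.
#' @param nu Default in-plane Poisson ratio for all layers.
#' @param eps_parenchyma In-plane free drying strain of the parenchyma
#'   (dimensionless, in (-1, Inf)); the default -0.7 corresponds to
#'   isotropic shrinkage to 30 percent of the wet dimension. By linearity
#'   of the plate solve this only scales curvature profiles; normalized
#'   profiles do not depend on it.
#' @param h_total Total wall thickness assigned to each station
#'   (dimensionless by default).
#'
#' @return An object of class `model_params`.
#' @export
model_params <- function(stiffness_triplet = c(20, 5, 0.1), nu = 0.3,
                         eps_parenchyma = -0.7, h_total = 1) {
  stopifnot(length(stiffness_triplet) == 3L)
  if (any(!is.finite(stiffness_triplet)) || any(stiffness_triplet <= 0)) {
    abort("All moduli in `stiffness_triplet` must be positive.",
          class = "hygrolam_params_error")
  }
  if (!is.finite(eps_parenchyma) || eps_parenchyma <= -1) {
    abort("`eps_parenchyma` must lie in (-1, Inf).",
          class = "hygrolam_params_error")
  }
  if (!is.finite(h_total) || h_total <= 0) {
    abort("`h_total` must be positive.", class = "hygrolam_params_error")
  }
  structure(
    list(
      stiffness_triplet = as.numeric(stiffness_triplet),
      nu = nu,
      eps_parenchyma = eps_parenchyma,
      h_total = h_total
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> E = %g:%g:%g (axial:perp:parenchyma), nu = %g, eps_parenchyma = %g, h_total = %g\n",
    x$stiffness_triplet[1], x$stiffness_triplet[2], x$stiffness_triplet[3],
    x$nu, x$eps_parenchyma, x$h_total
  ))
  invisible(x)
}

# Plane-stress stiffness in material axes (engineering shear convention).
q_material <- function(layer) {
  nu21 <- layer$nu12 * layer$E_perp / layer$E_parallel
  d <- 1 - layer$nu12 * nu21
  matrix(c(
    layer$E_parallel / d, layer$nu12 * layer$E_perp / d, 0,
    layer$nu12 * layer$E_perp / d, layer$E_perp / d, 0,
    0, 0, layer$G12
  ), 3, 3, byrow = TRUE)
}

#' Reduced in-plane stiffness of a layer in laminate axes
#'
#' Builds the 3x3 plane-stress orthotropic stiffness from the layer's
#' engineering constants and rotates it by the fiber orientation into the
#' laminate (capsule) axes, using the standard transformation with the
#' Reuter matrix for the engineering shear strain.
#'
#' @param layer An [elastic_layer()].
#' @return A symmetric positive-definite 3x3 matrix (rows/cols: xx, yy, xy).
#' @export
#' @examples
#' reduced_stiffness(elastic_layer(1, 45, 20, 5))
reduced_stiffness <- function(layer) {
  stopifnot(inherits(layer, "elastic_layer"))
  Q <- q_material(layer)
  th <- layer$orientation_deg * pi / 180
  cc <- cos(th)
  ss <- sin(th)
  Tm <- matrix(c(
    cc^2, ss^2, 2 * cc * ss,
    ss^2, cc^2, -2 * cc * ss,
    -cc * ss, cc * ss, cc^2 - ss^2
  ), 3, 3, byrow = TRUE)
  R <- diag(c(1, 1, 2))
  Qbar <- solve(Tm) %*% Q %*% R %*% Tm %*% solve(R)
  # enforce exact symmetry against rounding in the congruence product
  (Qbar + t(Qbar)) / 2
}

#' Effective fiber-layer moduli by rule of mixtures
#'
#' Voigt (arithmetic, iso-strain) average for the modulus along the fiber
#' axis and Reuss (harmonic, iso-stress) average across it, treating a
#' fiber layer as a parallel-fibril composite of crystalline cellulose in a
#' compliant non-cellulosic matrix.
#'
#' @param E_fibril,E_matrix Constituent moduli (> 0).
#' @param volume_fraction Fibril volume fraction in \[0, 1\].
#' @return A one-row tibble with columns `E_parallel` and `E_perp`.
#' @export
#' @examples
#' effective_fiber_moduli(100, 1, 0.5)
effective_fiber_moduli <- function(E_fibril, E_matrix, volume_fraction) {
  if (!is.finite(E_fibril) || !is.finite(E_matrix) ||
      E_fibril <= 0 || E_matrix <= 0) {
    abort("Constituent moduli must be positive.",
          class = "hygrolam_params_error")
  }
  if (!is.numeric(volume_fraction) || any(volume_fraction < 0) ||
      any(volume_fraction > 1)) {
    abort("`volume_fraction` must lie in [0, 1].",
          class = "hygrolam_params_error")
  }
  vf <- volume_fraction
  tibble::tibble(
    E_parallel = vf * E_fibril + (1 - vf) * E_matrix,
    E_perp = 1 / (vf / E_fibril + (1 - vf) / E_matrix)
  )
}

#' Closed-form curvature of an isotropic hygroscopic bilayer
#'
#' Evaluates the classical bimetal-strip formula for a two-layer strip in
#' which layer 1 (listed first, the inner side of a stack) carries a free
#' strain `eps` and layer 2 is passive:
#' \deqn{\kappa = \frac{6\,\varepsilon (1+m)^2}{h\,[3(1+m)^2 + (1+mn)(m^2 + 1/(mn))]}}
#' with `m = h1/h2`, `n = E1/E2`, `h = h1 + h2`. The sign follows `eps`:
#' a shrinking active layer (`eps < 0`) bends the strip concave toward
#' itself, which is negative in the convention of [solve_free_hygro()]
#' (positive = concave toward the outer, last-listed surface).
#'
#' Used as an independent oracle for the plate solve in the bilayer limit;
#' the plate and beam answers coincide when the two layers share one
#' Poisson ratio, because the equibiaxial biaxial moduli then keep the same
#' ratio `n`.
#'
#' @param h1,h2 Layer thicknesses (> 0); layer 1 is the active (inner) one.
#' @param E1,E2 Layer moduli (> 0).
#' @param eps Free strain of layer 1.
#' @return Signed curvature, units 1/length of `h1`, `h2`.
#' @export
#' @examples
#' timoshenko_bilayer_curvature(0.5, 0.5, 1, 1, -0.7) # = 1.5 * -0.7
timoshenko_bilayer_curvature <- function(h1, h2, E1, E2, eps) {
  if (any(c(h1, h2, E1, E2) <= 0)) {
    abort("Thicknesses and moduli must be positive.",
          class = "hygrolam_params_error")
  }
  m <- h1 / h2
  n <- E1 / E2
  h <- h1 + h2
  6 * eps * (1 + m)^2 /
    (h * (3 * (1 + m)^2 + (1 + m * n) * (m^2 + 1 / (m * n))))
}
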