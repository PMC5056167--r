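#' Assemble a laminate from layers
#'
#' A `laminate` is an ordered stack of [elastic_layer()] objects, listed
#' from the inner (endocarp) surface outward, together with the
#' through-thickness interface coordinates. The through-thickness
#' reference plane defaults to the geometric midplane; any other reference
#' changes the bookkeeping split between midplane strain and curvature but
#' not the physical deformation.
#'
#' @param ... Layers, or a single list of layers.
#' @param z_ref Either `"midplane"` or a numeric height of the reference
#'   plane measured from the inner surface.
#' @return An object of class `laminate`.
#' @export
#' @examples
#' lam <- laminate(
#'   elastic_layer(0.3, 90, 20, 5, name = "transverse fibers"),
#'   elastic_layer(0.2, 0, 20, 5, name = "longitudinal fibers"),
#'   elastic_layer(0.5, 0, 0.1, 0.1, hygro_strain = -0.7, name = "parenchyma")
#' )
#' tidy(lam)
laminate <- function(..., z_ref = "midplane") {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "elastic_layer")) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0L) {
    abort("A laminate needs at least one layer.",
          class = "hygrolam_laminate_error")
  }
  ok <- vapply(layers, inherits, logical(1), what = "elastic_layer")
  if (!all(ok)) {
    abort("All elements must be `elastic_layer` objects.",
          class = "hygrolam_laminate_error")
  }
  h <- vapply(layers, `[[`, numeric(1), "thickness")
  total <- sum(h)
  if (identical(z_ref, "midplane")) {
    z0 <- total / 2
  } else if (is.numeric(z_ref) && length(z_ref) == 1L && is.finite(z_ref)) {
    z0 <- z_ref
  } else {
    abort("`z_ref` must be \"midplane\" or a finite number.",
          class = "hygrolam_laminate_error")
  }
  structure(
    list(
      layers = layers,
      z = cumsum(c(0, h)) - z0, # interfaces, inner surface first
      total_thickness = total,
      z_ref = z_ref
    ),
    class = "laminate"
  )
}

#' @export
print.laminate <- function(x, ...) {
  cat(sprintf("<laminate> %d layer(s), total thickness %g (inner -> outer)\n",
              length(x$layers), x$total_thickness))
  for (l in x$layers) print(l)
  invisible(x)
}

#' @describeIn laminate One row per layer, inner to outer, with interface
#'   coordinates.
#' @param x A `laminate`.
#' @method tidy laminate
#' @export
tidy.laminate <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$layers),
    name = vapply(x$layers, function(l) l$name %||% NA_character_,
                  character(1)),
    thickness = vapply(x$layers, `[[`, numeric(1), "thickness"),
    orientation_deg = vapply(x$layers, `[[`, numeric(1), "orientation_deg"),
    E_parallel = vapply(x$layers, `[[`, numeric(1), "E_parallel"),
    E_perp = vapply(x$layers, `[[`, numeric(1), "E_perp"),
    nu12 = vapply(x$layers, `[[`, numeric(1), "nu12"),
    G12 = vapply(x$layers, `[[`, numeric(1), "G12"),
    hygro_strain = vapply(x$layers, `[[`, numeric(1), "hygro_strain"),
    z_lower = x$z[-length(x$z)],
    z_upper = x$z[-1]
  )
}

#' Extensional/coupling/bending stiffness of a laminate
#'
#' Classical lamination theory: with layer stiffnesses \eqn{\bar Q_k}
#' constant between interfaces \eqn{z_{k-1} < z_k},
#' \deqn{A = \sum_k \bar Q_k \Delta z_k,\quad
#'       B = \tfrac12 \sum_k \bar Q_k \Delta(z^2),\quad
#'       D = \tfrac13 \sum_k \bar Q_k \Delta(z^3).}
#'
#' @param lam A [laminate()].
#' @return A 6x6 matrix `rbind(cbind(A, B), cbind(B, D))` with an
#'   `"blocks"` attribute holding `A`, `B`, `D`.
#' @export
assemble_abd <- function(lam) {
  stopifnot(inherits(lam, "laminate"))
  A <- B <- D <- matrix(0, 3, 3)
  for (k in seq_along(lam$layers)) {
    Qb <- reduced_stiffness(lam$layers[[k]])
    zl <- lam$z[k]
    zu <- lam$z[k + 1]
    A <- A + Qb * (zu - zl)
    B <- B + Qb * (zu^2 - zl^2) / 2
    D <- D + Qb * (zu^3 - zl^3) / 3
  }
  out <- rbind(cbind(A, B), cbind(B, D))
  attr(out, "blocks") <- list(A = A, B = B, D = D)
  out
}

#' Hygroscopic force and moment resultants
#'
#' Integrates each layer's stiffness-weighted free hygroscopic strain
#' through the thickness. The free strain is isotropic in the plane,
#' so its vector form (eps, eps, 0) is the same in material and laminate
#' axes.
#'
#' @param lam A [laminate()].
#' @return A length-6 numeric vector `c(Nx, Ny, Nxy, Mx, My, Mxy)`.
#' @export
hygro_resultants <- function(lam) {
  stopifnot(inherits(lam, "laminate"))
  N <- M <- numeric(3)
  for (k in seq_along(lam$layers)) {
    eps <- lam$layers[[k]]$hygro_strain
    if (eps == 0) next
    Qb <- reduced_stiffness(lam$layers[[k]])
    beta <- c(eps, eps, 0)
    zl <- lam$z[k]
    zu <- lam$z[k + 1]
    N <- N + as.numeric(Qb %*% beta) * (zu - zl)
    M <- M + as.numeric(Qb %*% beta) * (zu^2 - zl^2) / 2
  }
  c(N, M)
}

#' Free hygro-elastic deformation of a laminate
#'
#' Solves the classical laminate plate system
#' \deqn{\begin{pmatrix} A & B \\ B & D \end{pmatrix}
#'       \begin{pmatrix} \varepsilon^0 \\ \kappa \end{pmatrix} =
#'       \begin{pmatrix} N^h \\ M^h \end{pmatrix}}
#' for the midplane strains and curvatures a traction-free plate adopts
#' under the layers' hygroscopic strains. Curvatures are reported with
#' positive \eqn{\kappa_x} meaning the stack bends concave toward its
#' outer (last-listed) surface, so a drying capsule wall, whose shrinking
#' parenchyma sits outermost, has \eqn{\kappa_L > 0} (segments bend
#' outward). The solve is linear: scaling every layer's hygroscopic strain
#' scales the whole state.
#'
#' @param lam A [laminate()].
#' @return An object of class `plate_state`: a list with
#'   `midplane_strains` (\eqn{\varepsilon_x, \varepsilon_y, \gamma_{xy}}),
#'   `curvatures` (\eqn{\kappa_x, \kappa_y, \kappa_{xy}}), and the scalar
#'   conveniences `kappa_L` (= \eqn{\kappa_x}, longitudinal) and `kappa_T`
#'   (= \eqn{\kappa_y}, transverse).
#' @export
#' @examples
#' lam <- laminate(
#'   elastic_layer(0.5, 0, 20, 5),
#'   elastic_layer(0.5, 0, 0.1, 0.1, hygro_strain = -0.7)
#' )
#' glance(solve_free_hygro(lam))
solve_free_hygro <- function(lam) {
  stopifnot(inherits(lam, "laminate"))
  ABD <- assemble_abd(lam)
  rhs <- hygro_resultants(lam)
  sol <- tryCatch(
    solve(ABD, rhs),
    error = function(e) {
      abort(
        paste0(
          "ABD matrix is numerically singular for this stack: ",
          paste(
            vapply(lam$layers, function(l) {
              sprintf("[t=%g, theta=%g]", l$thickness, l$orientation_deg)
            }, character(1)),
            collapse = " "
          )
        ),
        class = "hygrolam_conditioning_error",
        parent = e
      )
    }
  )
  structure(
    list(
      midplane_strains = sol[1:3],
      curvatures = -sol[4:6], # positive = concave toward outer surface
      kappa_L = -sol[4],
      kappa_T = -sol[5]
    ),
    class = "plate_state"
  )
}

#' @export
print.plate_state <- function(x, ...) {
  cat(sprintf(
    "<plate_state> kappa_L = %.6g, kappa_T = %.6g, kappa_xy = %.6g\n",
    x$kappa_L, x$kappa_T, x$curvatures[3]
  ))
  invisible(x)
}

#' @describeIn solve_free_hygro One-row summary of a solved plate state.
#' @param x A `plate_state`.
#' @param ... Unused.
#' @method glance plate_state
#' @export
glance.plate_state <- function(x, ...) {
  tibble::tibble(
    kappa_L = x$kappa_L,
    kappa_T = x$kappa_T,
    kappa_xy = x$curvatures[3],
    eps_x0 = x$midplane_strains[1],
    eps_y0 = x$midplane_strains[2],
    gamma_xy0 = x$midplane_strains[3]
  )
}
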