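#' Specification of a synthetic graded thickness profile
#'
#' The generator emulates the graded wall architecture of a capsule
#' locule: a longitudinal-fiber monolayer at the split region, growing
#' parenchyma and transverse-fiber fractions toward the vascular bundle
#' (where the longitudinal fibers vanish), and a return to
#' mostly-longitudinal tissue at the far side. Knot values are fixture
#' calibration, not measured data: they are chosen so the generated
#' profile reproduces the qualitative architecture and the reported
#' strength of the parenchyma/longitudinal-fiber anti-correlation.
#'
#' @param n_stations Number of equally spaced stations (default 20).
#' @param knots A data frame with columns `position`, `s`, `X_M`, `X_L`,
#'   `X_T`; each row's fractions must lie in \[0, 1\] and sum to 1.
#' @param residual_sd Station-level Gaussian jitter applied to the
#'   fractions before renormalization (default 0.005).
#' @param seed RNG seed for the jitter.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(n_stations = 20,
                         knots = default_profile_knots(),
                         residual_sd = 0.005,
                         seed = 1) {
  if (!is.numeric(n_stations) || n_stations < 2) {
    abort("`n_stations` must be at least 2.", class = "hygrolam_spec_error")
  }
  req <- c("s", "X_M", "X_L", "X_T")
  if (!all(req %in% names(knots)) || nrow(knots) < 2) {
    abort("`knots` needs >= 2 rows with columns s, X_M, X_L, X_T.",
          class = "hygrolam_spec_error")
  }
  knots <- tibble::as_tibble(knots)
  X <- as.matrix(knots[c("X_M", "X_L", "X_T")])
  if (any(X < 0) || any(X > 1) || any(abs(rowSums(X) - 1) > 1e-9)) {
    abort("Knot fractions must lie in [0, 1] and sum to 1 per knot.",
          class = "hygrolam_spec_error")
  }
  if (any(diff(knots$s) <= 0)) {
    abort("Knot positions must be strictly increasing.",
          class = "hygrolam_spec_error")
  }
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    abort("`residual_sd` must be >= 0.", class = "hygrolam_spec_error")
  }
  structure(
    list(n_stations = as.integer(n_stations), knots = knots,
         residual_sd = residual_sd, seed = seed),
    class = "profile_spec"
  )
}

#' @describeIn profile_spec The packaged default knots.
#' @export
default_profile_knots <- function() {
  tibble::tibble(
    position = c("split", "mid", "vascular_bundle", "far_side"),
    s = c(0, 0.45, 0.75, 1),
    X_M = c(0.05, 0.34, 0.73, 0.15),
    X_L = c(0.90, 0.36, 0.01, 0.75),
    X_T = c(0.05, 0.30, 0.26, 0.10)
  )
}

#' Noise settings for synthetic fixtures
#'
#' @param arc_point_sd Gaussian sd of coordinate noise on synthetic arc
#'   points (length units of the traces).
#' @param mfa_noise_sd_deg Von Mises angular noise sd for azimuth maps,
#'   degrees.
#' @param seed RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(arc_point_sd = 0, mfa_noise_sd_deg = 2, seed = 1) {
  if (arc_point_sd < 0 || mfa_noise_sd_deg < 0) {
    abort("Noise magnitudes must be >= 0.", class = "hygrolam_spec_error")
  }
  structure(
    list(arc_point_sd = arc_point_sd, mfa_noise_sd_deg = mfa_noise_sd_deg,
         seed = seed),
    class = "noise_spec"
  )
}

#' Generate the canonical graded thickness profile
#'
#' Monotone-shape-preserving interpolation (Fritsch-Carlson) of the knot
#' fractions onto equally spaced stations, clamped at zero and
#' renormalized to sum to 1 per station; seeded station-level jitter is
#' then applied and the rows renormalized again. Deterministic given the
#' spec's seed, which is recorded in the `"seed"` attribute.
#'
#' @param spec A [profile_spec()].
#' @return A [thickness_profile()] tibble.
#' @export
#' @examples
#' canonical_profile()
canonical_profile <- function(spec = profile_spec()) {
  stopifnot(inherits(spec, "profile_spec"))
  s <- seq(0, 1, length.out = spec$n_stations)
  interp <- function(v) {
    pmax(splinefun(spec$knots$s, v, method = "monoH.FC")(s), 0)
  }
  X <- cbind(interp(spec$knots$X_M), interp(spec$knots$X_L),
             interp(spec$knots$X_T))
  X <- X / rowSums(X)
  if (spec$residual_sd > 0) {
    jitter <- withr_seed(
      spec$seed,
      matrix(rnorm(3 * spec$n_stations, 0, spec$residual_sd),
             spec$n_stations, 3)
    )
    X <- pmax(X + jitter, 0)
    X <- X / rowSums(X)
  }
  out <- thickness_profile(tibble::tibble(
    s = s, X_M = X[, 1], X_L = X[, 2], X_T = X[, 3]
  ))
  attr(out, "seed") <- spec$seed
  out
}

#' Synthesize digitized segment arcs from a curvature profile
#'
#' The inverse of the dissection measurement, for round-trip validation:
#' the circumference is divided into `n_segments` equal widths, the
#' profile's curvature is linearly interpolated at each segment midpoint,
#' and each segment is emitted as points along a circular arc of that
#' curvature (a straight line for zero curvature), optionally perturbed
#' by Gaussian coordinate noise. Each trace receives a random rigid
#' motion, which a circle fit is invariant to. Deterministic given the
#' noise seed.
#'
#' @param curv A `curvature_profile` (the `kappa` column is used).
#' @param n_segments Number of segments cut from the circumference.
#' @param arc_length Length of each longitudinal segment trace.
#' @param noise A [noise_spec()]; `arc_point_sd` and `seed` are used.
#' @param circumference Total locule circumference (sets the widths).
#' @param points_per_segment Digitized points per trace.
#' @return A [segment_series()] with a `"seed"` attribute.
#' @export
arcs_from_profile <- function(curv, n_segments = 9, arc_length = 1,
                              noise = noise_spec(), circumference = 1,
                              points_per_segment = 25) {
  curv <- curvature_profile(curv)
  stopifnot(inherits(noise, "noise_spec"))
  if (arc_length <= 0 || circumference <= 0 || n_segments < 1) {
    abort("`arc_length`, `circumference` and `n_segments` must be positive.",
          class = "hygrolam_spec_error")
  }
  if (any(!is.finite(curv$kappa))) {
    abort("Curvatures must be finite.", class = "hygrolam_spec_error")
  }
  mids <- (seq_len(n_segments) - 0.5) / n_segments
  kap <- if (nrow(curv) == 1L) rep(curv$kappa, n_segments) else {
    approx(curv$s, curv$kappa, xout = mids, rule = 2)$y
  }
  d <- circumference / n_segments
  t <- seq(0, arc_length, length.out = points_per_segment)
  traces <- withr_seed(noise$seed, {
    purrr::map(seq_len(n_segments), function(i) {
      k <- kap[i]
      if (abs(k) < 1e-12) {
        x <- t
        y <- rep(0, length(t))
      } else {
        x <- sin(k * t) / k
        y <- (1 - cos(k * t)) / k
      }
      # random rigid motion: digitized photographs have arbitrary frames
      phi <- runif(1, 0, 2 * pi)
      ox <- runif(1, -5, 5)
      oy <- runif(1, -5, 5)
      xr <- cos(phi) * x - sin(phi) * y + ox
      yr <- sin(phi) * x + cos(phi) * y + oy
      if (noise$arc_point_sd > 0) {
        xr <- xr + rnorm(length(t), 0, noise$arc_point_sd)
        yr <- yr + rnorm(length(t), 0, noise$arc_point_sd)
      }
      segment_trace(tibble::tibble(x = xr, y = yr), width = d, id = i)
    })
  })
  out <- segment_series(traces)
  attr(out, "seed") <- noise$seed
  out
}

#' Packaged ground-truth microfibril angles
#'
#' Default true MFA values used by [azimuth_fixture()]: 8 degrees for
#' transverse fiber cells and 12 degrees for longitudinal fiber cells.
#'
#' @return A named numeric vector.
#' @export
default_mfa_truths <- function() {
  c(transverse = 8, longitudinal = 12)
}

#' Synthetic azimuth/retardance map with known microfibril angle
#'
#' Lays `n_cells` rectangular fiber-cell masks on a dark background, each
#' at a different cell-axis angle. Inside each cell the azimuth equals
#' the cell axis plus the true MFA plus von Mises angular noise, and the
#' retardance is high (90-130 nm); the background retardance is near zero,
#' like the weakly birefringent parenchyma. Deterministic given the noise
#' seed.
#'
#' @param true_mfa_deg Ground-truth MFA in \[0, 90\] degrees.
#' @param n_cells Number of cells (default 5).
#' @param noise A [noise_spec()]; `mfa_noise_sd_deg` and `seed` are used.
#' @param cell_px Pixel dimensions of each rectangular cell mask.
#' @return A list with elements `map` ([azimuth_map()]), `rois` (list of
#'   [cell_roi()]), `true_mfa_deg`, and `seed`.
#' @export
azimuth_fixture <- function(true_mfa_deg, n_cells = 5,
                            noise = noise_spec(), cell_px = c(12, 30)) {
  stopifnot(inherits(noise, "noise_spec"))
  if (true_mfa_deg < 0 || true_mfa_deg > 90) {
    abort("`true_mfa_deg` must lie in [0, 90].",
          class = "hygrolam_spec_error")
  }
  if (n_cells < 1) {
    abort("`n_cells` must be >= 1.", class = "hygrolam_spec_error")
  }
  pad <- 3L
  nr <- n_cells * (cell_px[1] + pad) + pad
  nc <- cell_px[2] + 2L * pad
  axes <- (seq_len(n_cells) - 1) * 180 / n_cells
  withr_seed(noise$seed, {
    azimuth <- matrix(runif(nr * nc, 0, 180), nr, nc)
    retardance <- matrix(runif(nr * nc, 0, 2), nr, nc)
    rois <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      r0 <- pad + (i - 1L) * (cell_px[1] + pad)
      mask <- matrix(FALSE, nr, nc)
      mask[(r0 + 1L):(r0 + cell_px[1]), (pad + 1L):(pad + cell_px[2])] <- TRUE
      npx <- sum(mask)
      azimuth[mask] <- (axes[i] + true_mfa_deg +
                          rvonmises_deg(npx, noise$mfa_noise_sd_deg)) %% 180
      retardance[mask] <- runif(npx, 90, 130)
      rois[[i]] <- cell_roi(mask, axes[i], id = i)
    }
    list(
      map = azimuth_map(azimuth, retardance),
      rois = rois,
      true_mfa_deg = true_mfa_deg,
      seed = noise$seed
    )
  })
}

#' Synthetic wet/dry thickness pair with known shrinkage
#'
#' Wet thicknesses are lognormal around a nominal value; dry thicknesses
#' are the wet values scaled by `ratio` with multiplicative Gaussian
#' noise. The packaged default ratio of 0.30 corresponds to a parenchyma
#' layer drying to 30 percent of its wet thickness.
#'
#' @param ratio True dry/wet thickness ratio (> 0).
#' @param n_samples Number of same-locus sample pairs.
#' @param noise_cv Coefficient of variation of the per-sample ratio noise.
#' @param seed RNG seed.
#' @param nominal_wet Nominal wet thickness (length units; default 0.5).
#' @return A tibble with columns `wet` and `dry` and a `"seed"` attribute,
#'   ready for [shrinkage_ratio()].
#' @export
#' @examples
#' shrinkage_ratio(shrinkage_fixture())
shrinkage_fixture <- function(ratio = 0.30, n_samples = 20,
                              noise_cv = 0.02, seed = 3,
                              nominal_wet = 0.5) {
  if (ratio <= 0) {
    abort("`ratio` must be positive.", class = "hygrolam_spec_error")
  }
  if (n_samples < 1 || noise_cv < 0) {
    abort("`n_samples` must be >= 1 and `noise_cv` >= 0.",
          class = "hygrolam_spec_error")
  }
  out <- withr_seed(seed, {
    wet <- rlnorm(n_samples, log(nominal_wet), 0.1)
    dry <- wet * ratio * (1 + rnorm(n_samples, 0, noise_cv))
    tibble::tibble(wet = wet, dry = dry)
  })
  attr(out, "seed") <- seed
  out
}
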