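#' Validate a circumferential thickness profile
#'
#' A thickness profile records, at ordered stations `s` along a locule
#' circumference (fraction in \[0, 1\] measured from the split region), the
#' relative thicknesses of the three wall tissues: `X_M` (mesocarp
#' parenchyma), `X_L` (longitudinal fibers) and `X_T` (transverse fibers).
#' Fractions must be non-negative and sum to 1 at every station.
#'
#' @param data A data frame with columns `s`, `X_M`, `X_L`, `X_T`.
#' @param tol Tolerance on the per-station sum (default 1e-9).
#' @return The data as a tibble of class `thickness_profile`.
#' @export
thickness_profile <- function(data, tol = 1e-9) {
  req <- c("s", "X_M", "X_L", "X_T")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("Profile is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hygrolam_profile_error")
  }
  data <- tibble::as_tibble(data)[req]
  if (nrow(data) < 1L) {
    abort("Profile has no stations.", class = "hygrolam_profile_error")
  }
  if (any(diff(data$s) <= 0) || data$s[1] < 0 ||
      data$s[nrow(data)] > 1) {
    abort("Station positions `s` must be strictly increasing within [0, 1].",
          class = "hygrolam_profile_error")
  }
  X <- as.matrix(data[c("X_M", "X_L", "X_T")])
  if (any(X < 0)) {
    bad <- which(apply(X < 0, 1, any))[1]
    abort(sprintf("Negative thickness fraction at station %d (s = %g).",
                  bad, data$s[bad]),
          class = "hygrolam_profile_error")
  }
  sums <- rowSums(X)
  off <- which(abs(sums - 1) > tol)
  if (length(off)) {
    abort(sprintf(
      "Thickness fractions must sum to 1: station %d (s = %g) sums to %.6g.",
      off[1], data$s[off[1]], sums[off[1]]
    ), class = "hygrolam_profile_error")
  }
  class(data) <- c("thickness_profile", class(data))
  data
}

#' Build the local laminate at one profile station
#'
#' Converts one station's relative thicknesses into a three-layer wall
#' stack, listed inner to outer: transverse fibers (orientation 90), then
#' longitudinal fibers (orientation 0), then the quasi-isotropic mesocarp
#' parenchyma, which is the only layer carrying a hygroscopic strain.
#' Zero-thickness layers are dropped so the ABD system stays
#' well-conditioned.
#'
#' @param profile A [thickness_profile()].
#' @param index Station row index.
#' @param params A [model_params()].
#' @return A [laminate()].
#' @export
station_laminate <- function(profile, index, params = model_params()) {
  profile <- thickness_profile(profile)
  if (!is.numeric(index) || length(index) != 1L ||
      index < 1 || index > nrow(profile)) {
    abort("`index` must be a single valid station row.",
          class = "hygrolam_profile_error")
  }
  row <- profile[index, ]
  if (row$X_M + row$X_L + row$X_T == 0) {
    abort(sprintf("All three fractions are zero at station %d (s = %g).",
                  index, row$s),
          class = "hygrolam_profile_error")
  }
  E <- params$stiffness_triplet
  h <- params$h_total
  layers <- list()
  if (row$X_T > 0) {
    layers <- c(layers, list(elastic_layer(
      row$X_T * h, 90, E[1], E[2], nu12 = params$nu,
      name = "transverse fibers"
    )))
  }
  if (row$X_L > 0) {
    layers <- c(layers, list(elastic_layer(
      row$X_L * h, 0, E[1], E[2], nu12 = params$nu,
      name = "longitudinal fibers"
    )))
  }
  if (row$X_M > 0) {
    layers <- c(layers, list(elastic_layer(
      row$X_M * h, 0, E[3], E[3], nu12 = params$nu,
      hygro_strain = params$eps_parenchyma, name = "parenchyma"
    )))
  }
  laminate(layers)
}

new_curvature_profile <- function(data) {
  data <- tibble::as_tibble(data)
  class(data) <- c("curvature_profile", class(data))
  data
}

#' Validate a curvature profile table
#'
#' @param data A data frame with columns `s`, `kappa` and optionally
#'   `kappa_norm` (recomputed if absent and any curvature is nonzero).
#' @return A tibble of class `curvature_profile`.
#' @export
curvature_profile <- function(data) {
  req <- c("s", "kappa")
  if (!all(req %in% names(data))) {
    abort("A curvature profile needs columns `s` and `kappa`.",
          class = "hygrolam_profile_error")
  }
  data <- tibble::as_tibble(data)
  if (any(diff(data$s) <= 0)) {
    abort("Station positions `s` must be strictly increasing.",
          class = "hygrolam_profile_error")
  }
  if (is.null(data[["kappa_norm"]])) {
    mx <- max(data$kappa)
    data$kappa_norm <- if (mx != 0) data$kappa / mx else data$kappa * 0
  }
  new_curvature_profile(data[c("s", "kappa", "kappa_norm")])
}

#' Predict the longitudinal curvature profile around a locule
#'
#' Runs the hygro-elastic plate solve at every station of a thickness
#' profile and normalizes the resulting longitudinal curvatures by their
#' maximum, reproducing the model side of the measured-versus-predicted
#' curvature comparison. Deterministic: identical inputs give identical
#' output.
#'
#' @param profile A [thickness_profile()].
#' @param params A [model_params()].
#' @return A `curvature_profile` tibble with columns `s`, `kappa`,
#'   `kappa_norm` (and `kappa_T` as a secondary output).
#' @export
#' @examples
#' prof <- canonical_profile()
#' predict_curvature_profile(prof)
predict_curvature_profile <- function(profile, params = model_params()) {
  profile <- thickness_profile(profile)
  states <- purrr::map(seq_len(nrow(profile)), function(i) {
    tryCatch(
      solve_free_hygro(station_laminate(profile, i, params)),
      error = function(e) {
        abort(sprintf("Curvature prediction failed at station %d (s = %g).",
                      i, profile$s[i]),
              class = "hygrolam_profile_error", parent = e)
      }
    )
  })
  kappa <- vapply(states, `[[`, numeric(1), "kappa_L")
  kappa_T <- vapply(states, `[[`, numeric(1), "kappa_T")
  mx <- max(kappa)
  out <- tibble::tibble(
    s = profile$s,
    kappa = kappa,
    kappa_norm = if (mx != 0) kappa / mx else kappa * 0,
    kappa_T = kappa_T
  )
  new_curvature_profile(out)
}

#' Locate the curvature peak
#'
#' Position `s` of the maximum curvature; ties are broken toward the
#' smallest `s`. An all-zero profile carries no movement and returns `NA`
#' with a warning.
#'
#' @param curv A `curvature_profile`.
#' @return The station position of the maximum, or `NA_real_` if nothing
#'   moves.
#' @export
peak_location <- function(curv) {
  curv <- curvature_profile(curv)
  if (all(curv$kappa == 0)) {
    warn("No movement: all curvatures are zero.",
         class = "hygrolam_no_movement")
    return(NA_real_)
  }
  curv$s[which.max(curv$kappa)]
}

#' Anti-correlation statistics between layer thicknesses
#'
#' Squared Pearson correlations of the parenchyma fraction against the
#' two fiber fractions across stations, with the sign of each raw
#' correlation. A strong negative parenchyma/longitudinal-fiber
#' correlation is the morphological fingerprint of the graded capsule
#' wall.
#'
#' @param profile A [thickness_profile()] with at least 3 stations.
#' @return A one-row tibble: `r2_M_vs_L`, `r2_M_vs_T`, `sign_M_vs_L`,
#'   `sign_M_vs_T`.
#' @export
anticorrelation_stats <- function(profile) {
  profile <- thickness_profile(profile)
  if (nrow(profile) < 3L) {
    abort("Need at least 3 stations for correlation statistics.",
          class = "hygrolam_profile_error")
  }
  safe_cor <- function(a, b, label) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warn(paste0("Correlation ", label,
                  " undefined: a series has zero variance."),
           class = "hygrolam_degenerate_error")
      return(NA_real_)
    }
    cor(a, b)
  }
  r_ML <- safe_cor(profile$X_M, profile$X_L, "X_M vs X_L")
  r_MT <- safe_cor(profile$X_M, profile$X_T, "X_M vs X_T")
  tibble::tibble(
    r2_M_vs_L = r_ML^2,
    r2_M_vs_T = r_MT^2,
    sign_M_vs_L = sign(r_ML),
    sign_M_vs_T = sign(r_MT)
  )
}

#' Compare predicted and measured curvature profiles
#'
#' Interpolates the measured profile linearly onto the predicted stations
#' (constant extension beyond its range) and reports the RMSE of the
#' normalized curvature, the Pearson correlation, and the difference in
#' peak position.
#'
#' @param predicted,measured `curvature_profile` tibbles with overlapping
#'   `s` ranges.
#' @return A one-row tibble: `rmse_norm`, `pearson_r`, `delta_peak_s`.
#' @export
compare_profiles <- function(predicted, measured) {
  predicted <- curvature_profile(predicted)
  measured <- curvature_profile(measured)
  if (min(measured$s) > max(predicted$s) ||
      max(measured$s) < min(predicted$s)) {
    abort("Profiles cover disjoint ranges of `s`.",
          class = "hygrolam_profile_error")
  }
  m_on_p <- if (nrow(measured) == 1L) {
    rep(measured$kappa_norm, nrow(predicted))
  } else {
    approx(measured$s, measured$kappa_norm, xout = predicted$s,
           rule = 2)$y
  }
  r <- if (stats::sd(predicted$kappa_norm) == 0 || stats::sd(m_on_p) == 0) {
    warn("Pearson correlation undefined: a profile is constant.",
         class = "hygrolam_degenerate_error")
    NA_real_
  } else {
    cor(predicted$kappa_norm, m_on_p)
  }
  peak_p <- suppressWarnings(peak_location(predicted))
  peak_m <- suppressWarnings(peak_location(measured))
  tibble::tibble(
    rmse_norm = sqrt(mean((predicted$kappa_norm - m_on_p)^2)),
    pearson_r = r,
    delta_peak_s = peak_p - peak_m
  )
}

#' Resample a curvature profile onto new stations
#'
#' Linear interpolation of `kappa` (constant beyond the range), with the
#' normalized column recomputed on the new grid.
#'
#' @param curv A `curvature_profile`.
#' @param s New station positions, strictly increasing.
#' @return A `curvature_profile` at the requested stations.
#' @export
resample_profile <- function(curv, s) {
  curv <- curvature_profile(curv)
  if (any(diff(s) <= 0)) {
    abort("New stations must be strictly increasing.",
          class = "hygrolam_profile_error")
  }
  kap <- if (nrow(curv) == 1L) rep(curv$kappa, length(s)) else {
    approx(curv$s, curv$kappa, xout = s, rule = 2)$y
  }
  curvature_profile(tibble::tibble(s = s, kappa = kap))
}
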