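#' Polarized-light azimuth/retardance map
#'
#' Slow-axis azimuth angles (degrees, 180-degree periodic) and retardance
#' magnitudes (nm) on a shared pixel grid, as produced by an LC-PolScope
#' style imaging system. Strong retardance marks crystalline cellulose;
#' the parenchyma appears dark.
#'
#' @param azimuth Numeric matrix of angles; values are wrapped into
#'   \[0, 180).
#' @param retardance Non-negative numeric matrix, same dimensions.
#' @return An object of class `azimuth_map`.
#' @export
azimuth_map <- function(azimuth, retardance) {
  if (!is.matrix(azimuth) || !is.matrix(retardance) ||
      !all(dim(azimuth) == dim(retardance))) {
    abort("`azimuth` and `retardance` must be matrices of the same shape.",
          class = "hygrolam_mfa_error")
  }
  if (any(!is.finite(azimuth)) || any(!is.finite(retardance)) ||
      any(retardance < 0)) {
    abort("Retardance must be finite and non-negative; azimuth finite.",
          class = "hygrolam_mfa_error")
  }
  structure(list(azimuth = azimuth %% 180, retardance = retardance),
            class = "azimuth_map")
}

#' A fiber-cell region of interest on an azimuth map
#'
#' @param mask Logical matrix marking the cell's pixels (at least one
#'   `TRUE`).
#' @param cell_axis_deg The cell's long-axis angle in image coordinates;
#'   wrapped into \[0, 180).
#' @param id Optional cell identifier.
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(mask, cell_axis_deg, id = NULL) {
  if (!is.matrix(mask) || !is.logical(mask) || !any(mask)) {
    abort("`mask` must be a logical matrix with at least one TRUE pixel.",
          class = "hygrolam_mfa_error")
  }
  if (!is.numeric(cell_axis_deg) || length(cell_axis_deg) != 1L ||
      !is.finite(cell_axis_deg)) {
    abort("`cell_axis_deg` must be a single finite angle.",
          class = "hygrolam_mfa_error")
  }
  structure(list(mask = mask, cell_axis_deg = cell_axis_deg %% 180, id = id),
            class = "cell_roi")
}

# fold an angular difference (degrees) into [-90, 90)
fold_180 <- function(a) ((a + 90) %% 180) - 90

# circular mean of 180-degree-periodic angles (degrees) via angle doubling
circ_mean_180 <- function(a_deg) {
  z <- exp(2i * a_deg * pi / 180)
  fold_180(Arg(mean(z)) * 180 / pi / 2)
}

# circular sd (degrees) of 180-degree-periodic angles via angle doubling
circ_sd_180 <- function(a_deg) {
  rbar <- Mod(mean(exp(2i * a_deg * pi / 180)))
  if (rbar >= 1) return(0)
  sqrt(-2 * log(rbar)) * 180 / pi / 2
}

#' Estimate the microfibril angle of one fiber cell
#'
#' Samples `n_points` pixels inside the cell mask whose retardance clears
#' a noise floor (by default the pixels with the highest retardance, the
#' strongest crystalline-cellulose signal; ties broken by grid order),
#' computes each pixel's acute angular difference between the map azimuth
#' and the cell's long axis, and returns the absolute circular mean of
#' those differences: the microfibril angle (MFA) relative to the cell
#' axis, in \[0, 90\] degrees. The estimate is invariant to rotating the
#' whole image (adding a constant to azimuth and cell axis alike).
#'
#' @param map An [azimuth_map()].
#' @param roi A [cell_roi()].
#' @param n_points Measurements per cell (default 3).
#' @param noise_floor Retardance threshold below which pixels are ignored;
#'   default 5 percent of the map's 95th retardance percentile.
#' @param sampling `"highest"` (default) or `"random"` (requires `seed`).
#' @param seed Seed for `sampling = "random"`.
#' @return MFA in degrees, in \[0, 90\].
#' @export
estimate_cell_mfa <- function(map, roi, n_points = 3, noise_floor = NULL,
                              sampling = c("highest", "random"),
                              seed = NULL) {
  stopifnot(inherits(map, "azimuth_map"), inherits(roi, "cell_roi"))
  sampling <- match.arg(sampling)
  if (!all(dim(roi$mask) == dim(map$azimuth))) {
    abort("ROI mask and map have different shapes.",
          class = "hygrolam_mfa_error")
  }
  noise_floor <- noise_floor %||%
    (0.05 * quantile(map$retardance, 0.95, names = FALSE))
  idx <- which(roi$mask & map$retardance > noise_floor)
  if (length(idx) < n_points) {
    abort(sprintf(
      "Dark cell: only %d pixel(s) above the retardance noise floor (%.3g), need %d.",
      length(idx), noise_floor, n_points
    ), class = "hygrolam_dark_cell_error")
  }
  picked <- if (sampling == "highest") {
    idx[order(-map$retardance[idx], idx)][seq_len(n_points)]
  } else {
    if (is.null(seed)) {
      abort("`sampling = \"random\"` needs an explicit `seed`.",
            class = "hygrolam_mfa_error")
    }
    withr_seed(seed, sample(idx, n_points))
  }
  d <- fold_180(map$azimuth[picked] - roi$cell_axis_deg)
  abs(circ_mean_180(d))
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Aggregate per-cell microfibril angles
#'
#' Circular mean and circular standard deviation over cells, computed on
#' doubled angles because MFA is a 180-degree-periodic quantity, reported
#' in degrees. Cohorts below the customary sampling floor of five cells
#' trigger a warning, not an error.
#'
#' @param mfas Numeric vector of per-cell MFA values (degrees).
#' @return A one-row tibble: `mfa_mean`, `mfa_sd`, `n`.
#' @export
#' @examples
#' aggregate_mfa(c(6, 8, 10, 8, 8))
aggregate_mfa <- function(mfas) {
  if (!is.numeric(mfas) || length(mfas) < 1L || any(!is.finite(mfas))) {
    abort("`mfas` must be a non-empty finite numeric vector.",
          class = "hygrolam_mfa_error")
  }
  if (length(mfas) < 5L) {
    warn(sprintf("Only %d cell(s); below the usual sampling floor of 5.",
                 length(mfas)),
         class = "hygrolam_small_cohort")
  }
  tibble::tibble(
    mfa_mean = abs(circ_mean_180(mfas)),
    mfa_sd = circ_sd_180(mfas),
    n = length(mfas)
  )
}

#' Draw von Mises angular noise
#'
#' Best-Fisher rejection sampler for the von Mises distribution, here
#' parameterized by an angular standard deviation in degrees (the
#' concentration is `1/sd^2` with sd in radians, the wrapped-normal
#' correspondence). Used for azimuth noise in synthetic maps.
#'
#' @param n Number of draws.
#' @param sd_deg Angular standard deviation in degrees; 0 returns zeros.
#' @return Angular deviations in degrees, centered on 0.
#' @export
rvonmises_deg <- function(n, sd_deg) {
  if (sd_deg < 0) {
    abort("`sd_deg` must be non-negative.", class = "hygrolam_mfa_error")
  }
  if (sd_deg == 0) return(numeric(n))
  kappa <- 1 / (sd_deg * pi / 180)^2
  # Best & Fisher (1979), batched rejection
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) / 0.6))
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(runif(m) - 0.5) * acos(f)
    out <- c(out, theta[keep])
  }
  out[seq_len(n)] * 180 / pi
}
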