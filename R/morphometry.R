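#' One digitized segment trace
#'
#' Ordered 2-D points digitized along a dried longitudinal segment,
#' plus the segment's circumferential width `d`.
#'
#' @param points A data frame with columns `x`, `y` (>= 3 rows, not all
#'   coincident).
#' @param width Segment width `d` (> 0), same length unit as the points.
#' @param id Optional segment identifier.
#' @return An object of class `segment_trace`.
#' @export
segment_trace <- function(points, width, id = NULL) {
  if (!all(c("x", "y") %in% names(points))) {
    abort("`points` needs columns `x` and `y`.",
          class = "hygrolam_trace_error")
  }
  points <- tibble::as_tibble(points)[c("x", "y")]
  if (nrow(points) < 3L) {
    abort("A trace needs at least 3 points.", class = "hygrolam_trace_error")
  }
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    abort("Trace coordinates must be finite.", class = "hygrolam_trace_error")
  }
  if (all(points$x == points$x[1]) && all(points$y == points$y[1])) {
    abort("Trace points are all coincident.", class = "hygrolam_trace_error")
  }
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0) {
    abort("`width` must be a single positive number.",
          class = "hygrolam_trace_error")
  }
  structure(list(points = points, width = width, id = id),
            class = "segment_trace")
}

#' An ordered series of segment traces
#'
#' Traces are kept in anatomical order starting from the split region,
#' mirroring how dissected segments are laid out and photographed.
#'
#' @param traces A list of [segment_trace()] objects.
#' @return An object of class `segment_series`.
#' @export
segment_series <- function(traces) {
  if (length(traces) == 0L) {
    abort("A segment series needs at least one trace.",
          class = "hygrolam_trace_error")
  }
  ok <- vapply(traces, inherits, logical(1), what = "segment_trace")
  if (!all(ok)) {
    abort("All elements must be `segment_trace` objects.",
          class = "hygrolam_trace_error")
  }
  structure(list(traces = traces), class = "segment_series")
}

#' @export
print.segment_series <- function(x, ...) {
  cat(sprintf("<segment_series> %d segment(s), widths: %s\n",
              length(x$traces),
              paste(signif(segment_widths(x), 4), collapse = ", ")))
  invisible(x)
}

segment_widths <- function(series) {
  vapply(series$traces, `[[`, numeric(1), "width")
}

#' Least-squares circle fit
#'
#' Fits a circle to 2-D points by the algebraic Kasa solution, refined by
#' Gauss-Newton iteration on the geometric (orthogonal-distance)
#' objective. Deterministic for a fixed point order. Collinear point sets
#' are flagged as straight segments and carry an infinite radius.
#'
#' @param points A data frame with columns `x`, `y` (>= 3 points), or a
#'   [segment_trace()].
#' @return A list of class `circle_fit`: `center` (length 2), `radius`,
#'   `rms_residual`, `straight` (logical), `n`.
#' @export
#' @examples
#' th <- seq(0, pi / 2, length.out = 12)
#' fit_circle(data.frame(x = 10 * cos(th), y = 10 * sin(th)))
fit_circle <- function(points) {
  if (inherits(points, "segment_trace")) points <- points$points
  if (!all(c("x", "y") %in% names(points))) {
    abort("`points` needs columns `x` and `y`.",
          class = "hygrolam_trace_error")
  }
  x <- points$x
  y <- points$y
  n <- length(x)
  if (n < 3L) {
    abort("Circle fitting needs at least 3 points.",
          class = "hygrolam_trace_error")
  }
  span <- max(max(x) - min(x), max(y) - min(y))
  if (span == 0) {
    abort("Points are all coincident.", class = "hygrolam_trace_error")
  }
  # collinearity check on the centered second-moment matrix
  xc <- x - mean(x)
  yc <- y - mean(y)
  S <- crossprod(cbind(xc, yc)) / n
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  # rms orthogonal deviation from the best line, against rotation round-off
  if (sqrt(max(ev[2], 0)) < 1e-7 * span) {
    return(structure(
      list(center = c(NA_real_, NA_real_), radius = Inf,
           rms_residual = sqrt(max(ev[2], 0)), straight = TRUE, n = n),
      class = "circle_fit"
    ))
  }
  # Kasa: x^2 + y^2 = 2 a x + 2 b y + c (on centered coordinates)
  A <- cbind(2 * xc, 2 * yc, 1)
  b <- xc^2 + yc^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) {
    return(structure(
      list(center = c(NA_real_, NA_real_), radius = Inf,
           rms_residual = NA_real_, straight = TRUE, n = n),
      class = "circle_fit"
    ))
  }
  a0 <- sol[1]
  b0 <- sol[2]
  r0 <- sqrt(sol[3] + a0^2 + b0^2)
  # geometric refinement (Gauss-Newton on center; radius = mean distance)
  cx <- a0
  cy <- b0
  for (iter in 1:100) {
    dx <- xc - cx
    dy <- yc - cy
    ri <- sqrt(dx^2 + dy^2)
    if (any(ri == 0)) break
    R <- mean(ri)
    res <- ri - R
    J <- cbind(-dx / ri + mean(dx / ri), -dy / ri + mean(dy / ri))
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0))
    cx <- cx + step[1]
    cy <- cy + step[2]
    if (sqrt(sum(step^2)) < 1e-14 * max(R, span)) break
  }
  dx <- xc - cx
  dy <- yc - cy
  ri <- sqrt(dx^2 + dy^2)
  R <- mean(ri)
  # guard: a refined radius enormous relative to the data span is straight
  if (!is.finite(R) || R > 1e8 * span) {
    return(structure(
      list(center = c(NA_real_, NA_real_), radius = Inf,
           rms_residual = NA_real_, straight = TRUE, n = n),
      class = "circle_fit"
    ))
  }
  structure(
    list(
      center = c(cx + mean(x), cy + mean(y)),
      radius = R,
      rms_residual = sqrt(mean((ri - R)^2)),
      straight = FALSE,
      n = n
    ),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$straight) {
    cat("<circle_fit> straight segment (R = Inf)\n")
  } else {
    cat(sprintf("<circle_fit> center (%.4g, %.4g), R = %.6g, rms = %.3g\n",
                x$center[1], x$center[2], x$radius, x$rms_residual))
  }
  invisible(x)
}

#' @describeIn fit_circle One-row tibble of the fit.
#' @param x A `circle_fit`.
#' @param ... Unused.
#' @method glance circle_fit
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(
    center_x = x$center[1], center_y = x$center[2],
    radius = x$radius, rms_residual = x$rms_residual,
    straight = x$straight, n = x$n
  )
}

#' Curvature of a segment trace
#'
#' kappa = 1/R from the circle fit; straight segments (the barely bending
#' split-region segment, for instance) map to kappa = 0 rather than an
#' error. The reported curvature is unsigned; the bending direction is
#' attached as the `"bend_sign"` attribute (+1 when the arc bows to the
#' left of the first-to-last chord).
#'
#' @param trace A [segment_trace()] or a data frame of points.
#' @return Curvature (1/length unit of the points).
#' @export
curvature_of <- function(trace) {
  pts <- if (inherits(trace, "segment_trace")) trace$points else trace
  fit <- fit_circle(pts)
  kap <- if (fit$straight) 0 else 1 / fit$radius
  # orientation of the arc relative to its chord
  i_mid <- ceiling(nrow(pts) / 2)
  v1 <- c(pts$x[nrow(pts)] - pts$x[1], pts$y[nrow(pts)] - pts$y[1])
  v2 <- c(pts$x[i_mid] - pts$x[1], pts$y[i_mid] - pts$y[1])
  attr(kap, "bend_sign") <- sign(v1[1] * v2[2] - v1[2] * v2[1])
  kap
}

#' Relative circumferential positions of segments
#'
#' For the nth of N ordered segments with widths \eqn{d_i},
#' \eqn{l_n = \sum_1^n d_i / \sum_1^N d_i}: the cumulative width fraction.
#' The last value is exactly 1 and the sequence is strictly increasing;
#' the result is invariant to uniform rescaling of the widths.
#'
#' @param widths A numeric vector of segment widths, or a
#'   [segment_series()].
#' @return Numeric vector `l_n`.
#' @export
#' @examples
#' relative_positions(c(1, 2, 1))
relative_positions <- function(widths) {
  if (inherits(widths, "segment_series")) widths <- segment_widths(widths)
  if (!is.numeric(widths) || length(widths) == 0L ||
      any(!is.finite(widths)) || any(widths <= 0)) {
    abort("Widths must be positive finite numbers.",
          class = "hygrolam_trace_error")
  }
  cumsum(widths) / sum(widths)
}

#' Measure a curvature profile from dissected segments
#'
#' Fits each trace to a circle, converts to curvature, places each
#' segment at its midpoint position \eqn{l_n - d_n / (2 \sum d_i)} along
#' the circumference, and normalizes by the maximum curvature, giving the
#' measured counterpart of [predict_curvature_profile()]. The end-point
#' convention (`position = "end"`) places segments at \eqn{l_n} instead.
#'
#' @param series A [segment_series()].
#' @param position `"midpoint"` (default) or `"end"`.
#' @return A `curvature_profile` tibble (`s`, `kappa`, `kappa_norm`).
#' @export
measure_curvature_profile <- function(series,
                                      position = c("midpoint", "end")) {
  stopifnot(inherits(series, "segment_series"))
  position <- match.arg(position)
  d <- segment_widths(series)
  l_n <- relative_positions(d)
  s <- if (position == "midpoint") l_n - d / (2 * sum(d)) else l_n
  kappa <- vapply(series$traces, function(tr) as.numeric(curvature_of(tr)),
                  numeric(1))
  if (all(kappa == 0)) {
    warn("No movement: every segment is straight.",
         class = "hygrolam_no_movement")
  }
  mx <- max(kappa)
  new_curvature_profile(tibble::tibble(
    s = s,
    kappa = kappa,
    kappa_norm = if (mx != 0) kappa / mx else kappa * 0
  ))
}

#' Wet/dry shrinkage of a tissue layer
#'
#' Dry-to-wet thickness ratio of same-locus thickness samples, as a
#' percentage of the wet-state thickness, together with the wet/dry fold
#' change (a ratio of 30 percent is a ~3.3-fold, i.e. ~300 percent,
#' change). Values above 100 percent are allowed but flagged as swelling.
#'
#' @param pair A data frame with equal-length positive columns `wet` and
#'   `dry` (same length unit).
#' @return A one-row tibble: `ratio_percent`, `fold_change`, `swelling`,
#'   `n`, plus the per-sample ratios as a list column.
#' @export
#' @examples
#' shrinkage_ratio(data.frame(wet = c(10, 10), dry = c(3, 3)))
shrinkage_ratio <- function(pair) {
  if (!all(c("wet", "dry") %in% names(pair))) {
    abort("`pair` needs columns `wet` and `dry`.",
          class = "hygrolam_shrinkage_error")
  }
  wet <- pair$wet
  dry <- pair$dry
  if (length(wet) != length(dry) || length(wet) == 0L) {
    abort("`wet` and `dry` must be non-empty and of equal length.",
          class = "hygrolam_shrinkage_error")
  }
  if (any(!is.finite(wet)) || any(!is.finite(dry)) ||
      any(wet <= 0) || any(dry <= 0)) {
    abort("Thickness samples must be positive and finite.",
          class = "hygrolam_shrinkage_error")
  }
  ratio <- 100 * mean(dry) / mean(wet)
  tibble::tibble(
    ratio_percent = ratio,
    fold_change = mean(wet) / mean(dry),
    swelling = ratio > 100,
    n = length(wet),
    per_sample_ratios = list(dry / wet)
  )
}
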