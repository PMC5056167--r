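#' Read and write the package's delimited tables
#'
#' All tables are plain CSV with headers. Angles are in degrees,
#' curvatures in 1/length of the trace unit, and circumferential position
#' `s` is always a fraction measured from the split region. Writing then
#' reading a table reproduces the values to within float formatting
#' (better than 1e-12 relative).
#'
#' * profile tables: columns `s, X_M, X_L, X_T`
#' * curvature tables: columns `s, kappa, kappa_norm`
#' * trace tables: columns `segment_id, point_index, x, y`
#' * width tables: columns `segment_id, d`
#'
#' @param path File path.
#' @param profile,curv A [thickness_profile()] / `curvature_profile`.
#' @param series A [segment_series()].
#' @return Readers return the validated object; writers return the path
#'   invisibly.
#' @name hygrolam_io
NULL

read_table_checked <- function(path, col_names) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "hygrolam_io_error")
  }
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(col_names, names(tb))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "hygrolam_io_error")
  }
  for (cn in col_names) {
    bad <- which(!is.finite(tb[[cn]]) | !is.numeric(tb[[cn]]))
    if (length(bad)) {
      abort(sprintf("%s: malformed value in column `%s` at data row %d.",
                    path, cn, bad[1]),
            class = "hygrolam_io_error")
    }
  }
  tb
}

#' @rdname hygrolam_io
#' @export
read_profile <- function(path) {
  thickness_profile(read_table_checked(path, c("s", "X_M", "X_L", "X_T")))
}

#' @rdname hygrolam_io
#' @export
write_profile <- function(profile, path) {
  profile <- thickness_profile(profile)
  readr::write_csv(profile, path)
  invisible(path)
}

#' @rdname hygrolam_io
#' @export
read_curvature <- function(path) {
  curvature_profile(read_table_checked(path, c("s", "kappa")))
}

#' @rdname hygrolam_io
#' @export
write_curvature <- function(curv, path) {
  curv <- curvature_profile(curv)
  readr::write_csv(curv, path)
  invisible(path)
}

#' @rdname hygrolam_io
#' @export
write_traces <- function(series, path) {
  stopifnot(inherits(series, "segment_series"))
  tb <- purrr::map_dfr(seq_along(series$traces), function(i) {
    tr <- series$traces[[i]]
    tibble::tibble(
      segment_id = tr$id %||% i,
      point_index = seq_len(nrow(tr$points)),
      x = tr$points$x,
      y = tr$points$y
    )
  })
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname hygrolam_io
#' @param widths_path Path of the accompanying widths table.
#' @export
read_traces <- function(path, widths_path) {
  pts <- read_table_checked(path, c("segment_id", "point_index", "x", "y"))
  wd <- read_table_checked(widths_path, c("segment_id", "d"))
  ids <- unique(pts$segment_id)
  if (!setequal(ids, wd$segment_id)) {
    abort("Trace and width tables disagree on segment ids.",
          class = "hygrolam_io_error")
  }
  traces <- purrr::map(ids, function(id) {
    p <- dplyr::arrange(dplyr::filter(pts, .data$segment_id == id),
                        .data$point_index)
    segment_trace(p[c("x", "y")],
                  width = wd$d[match(id, wd$segment_id)], id = id)
  })
  segment_series(traces)
}

#' @rdname hygrolam_io
#' @export
write_widths <- function(series, path) {
  stopifnot(inherits(series, "segment_series"))
  tb <- tibble::tibble(
    segment_id = purrr::map_int(seq_along(series$traces), function(i) {
      as.integer(series$traces[[i]]$id %||% i)
    }),
    d = segment_widths(series)
  )
  readr::write_csv(tb, path)
  invisible(path)
}

config_defaults <- function() {
  list(
    params = list(
      stiffness_triplet = c(20, 5, 0.1),
      nu = 0.3,
      eps_parenchyma = -0.7,
      h_total = 1
    ),
    profile = list(
      n_stations = 20L,
      residual_sd = 0.005,
      seed = 1L
    ),
    noise = list(
      arc_point_sd = 0,
      mfa_noise_sd_deg = 2,
      seed = 1L
    ),
    pipeline = list(
      n_segments = 9L,
      arc_length = 1,
      circumference = 1,
      points_per_segment = 25L
    ),
    paths = list(
      out_dir = NULL
    )
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and injects defaults
#' for anything unspecified. Every injected default is recorded in the
#' returned object's `injected` field so a run log can state exactly what
#' was assumed. Profile knots may be overridden under `profile: knots:` as
#' parallel lists `s`, `X_M`, `X_L`, `X_T`.
#'
#' @param path Path to a YAML file, or a named list with the same
#'   structure.
#' @return A validated configuration of class `run_config`.
#' @export
read_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) {
      abort(paste0("Config file not found: ", path),
            class = "hygrolam_io_error")
    }
    yaml::read_yaml(path) %||% list()
  } else if (is.list(path)) {
    path
  } else {
    abort("`path` must be a file path or a list.",
          class = "hygrolam_io_error")
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config section(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hygrolam_config_error")
  }
  injected <- character(0)
  cfg <- defaults
  for (section in names(defaults)) {
    given <- raw[[section]] %||% list()
    allowed <- union(names(defaults[[section]]),
                     if (section == "profile") "knots" else character(0))
    unknown <- setdiff(names(given), allowed)
    if (length(unknown)) {
      abort(sprintf("Unknown key(s) in config section `%s`: %s",
                    section, paste(unknown, collapse = ", ")),
            class = "hygrolam_config_error")
    }
    for (key in names(defaults[[section]])) {
      if (is.null(given[[key]])) {
        injected <- c(injected, paste0(section, ".", key))
      } else {
        cfg[[section]][[key]] <- given[[key]]
      }
    }
    if (section == "profile" && !is.null(given$knots)) {
      cfg$profile$knots <- tibble::as_tibble(given$knots)
    }
  }
  cfg$injected <- injected
  # construct the validated component objects now so errors surface early
  cfg$model_params <- model_params(
    stiffness_triplet = unlist(cfg$params$stiffness_triplet),
    nu = cfg$params$nu,
    eps_parenchyma = cfg$params$eps_parenchyma,
    h_total = cfg$params$h_total
  )
  cfg$profile_spec <- profile_spec(
    n_stations = cfg$profile$n_stations,
    knots = cfg$profile$knots %||% default_profile_knots(),
    residual_sd = cfg$profile$residual_sd,
    seed = cfg$profile$seed
  )
  cfg$noise_spec <- noise_spec(
    arc_point_sd = cfg$noise$arc_point_sd,
    mfa_noise_sd_deg = cfg$noise$mfa_noise_sd_deg,
    seed = cfg$noise$seed
  )
  structure(cfg, class = "run_config")
}

#' Run the end-to-end simulate/predict/measure/compare pipeline
#'
#' Reproduces the full measured-versus-predicted analysis on synthetic
#' data: generate the canonical graded profile, predict its normalized
#' longitudinal curvature, synthesize dissected segment arcs from the
#' prediction, re-measure them by circle fitting, and compare the
#' profiles at the segment midpoints (so a noiseless run round-trips
#' exactly). When `out_dir` is set (argument or config), the profile,
#' both curvature tables, the trace/width tables and a JSON run log
#' (seeds, injected defaults, config hash, package version) are written
#' there; two runs with the same config produce byte-identical tables.
#'
#' @param config A `run_config` from [read_config()], a path to a YAML
#'   config, or `NULL` for all defaults.
#' @param out_dir Output directory; overrides the config's
#'   `paths.out_dir`. `NULL` writes nothing.
#' @param check Optional named list of thresholds to verify, any of
#'   `rmse_max`, `peak_window` (length 2), `r_min`. When supplied, the
#'   report gains a `checks` tibble and a logical `passed`.
#' @return A list of class `pipeline_report`: `profile`, `predicted`,
#'   `measured`, `comparison`, `peak_s`, `no_movement`, `seeds`,
#'   `injected`, `config_hash`, and optionally `checks`/`passed`.
#' @export
#' @examples
#' rep <- run_pipeline()
#' rep$comparison
run_pipeline <- function(config = NULL, out_dir = NULL, check = NULL) {
  cfg <- if (inherits(config, "run_config")) config else {
    read_config(config %||% list())
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed."),
            class = "hygrolam_pipeline_error", parent = e)
    })
  }
  profile <- stage("simulate", canonical_profile(cfg$profile_spec))
  predicted <- stage("predict",
                     predict_curvature_profile(profile, cfg$model_params))
  no_movement <- all(predicted$kappa == 0)
  series <- stage("arcs", arcs_from_profile(
    predicted,
    n_segments = cfg$pipeline$n_segments,
    arc_length = cfg$pipeline$arc_length,
    noise = cfg$noise_spec,
    circumference = cfg$pipeline$circumference,
    points_per_segment = cfg$pipeline$points_per_segment
  ))
  measured <- stage("measure", suppressWarnings(
    measure_curvature_profile(series)
  ))
  # compare on the measurement grid: resample the prediction onto the
  # segment midpoints rather than interpolating the sparse measurement
  predicted_at_m <- resample_profile(predicted, measured$s)
  comparison <- stage("compare", suppressWarnings(
    compare_profiles(predicted_at_m, measured)
  ))
  peak_s <- suppressWarnings(peak_location(predicted))
  report <- list(
    profile = profile,
    predicted = predicted,
    measured = measured,
    comparison = comparison,
    peak_s = peak_s,
    no_movement = no_movement,
    seeds = list(profile = cfg$profile_spec$seed,
                 noise = cfg$noise_spec$seed),
    injected = cfg$injected,
    config_hash = rlang::hash(cfg[c("params", "profile", "noise",
                                    "pipeline")]),
    package_version = as.character(utils::packageVersion("hygrolam"))
  )
  if (!is.null(check)) {
    rows <- list()
    if (!is.null(check$rmse_max)) {
      rows$rmse_max <- c(comparison$rmse_norm,
                         comparison$rmse_norm <= check$rmse_max)
    }
    if (!is.null(check$peak_window)) {
      ok <- !is.na(peak_s) && peak_s >= check$peak_window[1] &&
        peak_s <= check$peak_window[2]
      rows$peak_window <- c(peak_s, ok)
    }
    if (!is.null(check$r_min)) {
      ok <- !is.na(comparison$pearson_r) &&
        comparison$pearson_r >= check$r_min
      rows$r_min <- c(comparison$pearson_r, ok)
    }
    checks <- tibble::tibble(
      criterion = names(rows),
      value = vapply(rows, `[[`, numeric(1), 1),
      passed = as.logical(vapply(rows, `[[`, numeric(1), 2))
    )
    report$checks <- checks
    report$passed <- all(checks$passed)
  }
  out_dir <- out_dir %||% cfg$paths$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(profile, file.path(out_dir, "profile.csv"))
    write_curvature(predicted[c("s", "kappa", "kappa_norm")],
                    file.path(out_dir, "predicted.csv"))
    write_curvature(measured, file.path(out_dir, "measured.csv"))
    write_traces(series, file.path(out_dir, "traces.csv"))
    write_widths(series, file.path(out_dir, "widths.csv"))
    readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
    log <- report[c("peak_s", "no_movement", "seeds", "injected",
                    "config_hash", "package_version")]
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (x$no_movement) {
    cat("  no movement: all predicted curvatures are zero\n")
  } else {
    cat(sprintf("  predicted peak at s = %.4g\n", x$peak_s))
  }
  cat(sprintf("  rmse(norm) = %.4g, pearson r = %.4g, delta peak = %.4g\n",
              x$comparison$rmse_norm, x$comparison$pearson_r,
              x$comparison$delta_peak_s))
  if (!is.null(x$passed)) {
    cat(sprintf("  checks passed: %s\n", x$passed))
  }
  invisible(x)
}
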