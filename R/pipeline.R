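#' Full run configuration
#'
#' Bundles every tunable of the simulate -> analyze -> calibrate -> quantify
#' chain: the phantom renderer, the line detector, and the calibration /
#' quantification settings. Serialises losslessly to and from YAML; every
#' run emits the resolved configuration together with its content hash so
#' that downstream artifacts can be matched to the configuration that
#' produced them.
#'
#' @param phantom A [phantom_config].
#' @param detection A [detection_config].
#' @param ladder Concentrations of the simulated dilution series (ng/ml).
#' @param replicates Replicate strips per concentration.
#' @param smooth_window Odd profile-smoothing window (px).
#' @param flow_axis `"width"` or `"height"`.
#' @param ratio_kind Ratio used for calibration and quantification.
#' @param working_range Inversion range request (ng/ml).
#' @param high_threshold High-risk threshold (ng/ml, inclusive).
#' @param band_breaks Visual-band boundaries (ng/ml).
#' @param lod_grid Concentration grid of the LOD rule (must include 0).
#' @param lod_sigma_r,lod_k LOD separation rule constants.
#' @param seed Root seed.
#' @return A `run_config` object.
#' @examples
#' cfg <- run_config(replicates = 2)
#' cfg$hash <- config_hash(cfg)
#' @export
run_config <- function(phantom = phantom_config(),
                       detection = detection_config(),
                       ladder = default_ladder(),
                       replicates = 5L,
                       smooth_window = 5L,
                       flow_axis = "width",
                       ratio_kind = "tb",
                       working_range = c(0, 600),
                       high_threshold = 250,
                       band_breaks = c(109, 370),
                       lod_grid = c(0, 25, 50, 100, 200, 400, 800),
                       lod_sigma_r = 0.07,
                       lod_k = 2,
                       seed = 1L) {
  validate_phantom_config(phantom)
  stopifnot(inherits(detection, "detection_config"))
  if (!ratio_kind %in% c("tb", "cb", "tc")) {
    stop_lfa("lfaquant_config_error", "ratio_kind must be tb, cb or tc")
  }
  structure(
    list(phantom = phantom,
         detection = detection,
         ladder = ladder,
         replicates = as.integer(replicates),
         smooth_window = as.integer(smooth_window),
         flow_axis = flow_axis,
         ratio_kind = ratio_kind,
         working_range = working_range,
         high_threshold = high_threshold,
         band_breaks = band_breaks,
         lod_grid = lod_grid,
         lod_sigma_r = lod_sigma_r,
         lod_k = lod_k,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %d x %d strips, ratio %s, range [%g, %g], seed %d, hash %s>\n",
              length(x$ladder), x$replicates, x$ratio_kind,
              x$working_range[1], x$working_range[2], x$seed, config_hash(x)))
  invisible(x)
}

#' Content hash of a run configuration
#'
#' MD5 over the canonical YAML serialisation; identical configurations
#' always hash identically.
#'
#' @param cfg A `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  # JSON prints 200 and 200L identically, so the hash is invariant under a
  # YAML round trip that turns whole-number doubles into integers
  writeLines(jsonlite::toJSON(run_config_to_list(cfg), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

run_config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$phantom <- config_to_list(cfg$phantom)
  out$detection <- unclass(cfg$detection)
  out
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$phantom <- config_from_list(lst$phantom)
  lst$detection <- do.call(detection_config, lst$detection)
  do.call(run_config, lst)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(run_config_to_list(cfg), path)
  invisible(path)
}

#' Run the whole pipeline end to end
#'
#' Simulates the configured dilution ladder, analyses every strip, forms
#' per-concentration replicate statistics, fits the calibration curve,
#' estimates the limit of detection on noise-free phantoms over the
#' configured grid, and quantifies every simulated strip back through the
#' fitted curve with risk labels. Rerunning with the same configuration
#' reproduces the summary exactly.
#'
#' @param cfg A [run_config].
#' @param out_dir Optional output directory; when given, writes
#'   `summary.json`, `measurements.csv`, `calibration.yaml`,
#'   `report.csv` (concentration, mean, sd, n) and `config.yaml`.
#' @param log Function used for progress messages (default [message]);
#'   pass `function(...) {}` to silence.
#' @return Invisibly, the summary list: `config_hash`, `strips` (per-strip
#'   table with truth, measurement, estimate and labels), `calibration`
#'   (the `lfa_calibration`), `points`, `lod_ng_ml`.
#' @export
run_end_to_end <- function(cfg = run_config(), out_dir = NULL, log = message) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  log(sprintf("[simulate] %d concentrations x %d replicates (seed %d)",
              length(cfg$ladder), cfg$replicates, cfg$seed))
  series <- dilution_series(cfg$ladder, cfg$replicates, cfg$phantom, seed = cfg$seed)

  log("[analyze] measuring strips")
  measurements <- lapply(seq_along(series$strips), function(i) {
    tryCatch(
      analyze_strip(series$strips[[i]]$image, cfg$phantom$roi, cfg$detection,
                    smooth_window = cfg$smooth_window, flow_axis = cfg$flow_axis),
      error = function(e) {
        stop_lfa("lfaquant_stage_error", "strip %s: %s",
                 series$manifest$strip_id[i], conditionMessage(e))
      })
  })

  log("[calibrate] replicate statistics and quadratic fit")
  conc <- series$manifest$concentration_ng_ml
  points <- replicate_stats(measurements, conc, ratio_kind = cfg$ratio_kind)
  curve <- fit_calibration(points, ratio_kind = cfg$ratio_kind,
                           working_range = cfg$working_range)

  log("[lod] separation rule on noise-free phantoms")
  lod <- pipeline_lod(cfg)

  log("[quantify] inverse prediction per strip")
  ratios <- extract_ratios(measurements, cfg$ratio_kind)
  quant <- estimate_concentration(curve, ratios, high_threshold = cfg$high_threshold)

  strips <- cbind(series$manifest,
                  do.call(rbind, lapply(measurements, measurement_row)),
                  quant[, c("estimated_concentration", "censoring",
                            "risk_label", "band_label")],
                  config_hash = hash,
                  stringsAsFactors = FALSE)

  summary <- list(config_hash = hash,
                  strips = strips,
                  points = points,
                  calibration = curve,
                  lod_ng_ml = lod)

  if (!is.null(out_dir)) write_run_outputs(summary, cfg, out_dir)
  invisible(summary)
}

# LOD of the configured pipeline: noise-free, jitter-free phantoms on the
# configured grid, measured by the full analysis chain.
pipeline_lod <- function(cfg) {
  ph <- cfg$phantom
  ph$pixel_noise_sd <- 0
  ph$strip_jitter_sd <- 0
  ratios <- vapply(cfg$lod_grid, function(c) {
    s <- render_strip(c, ph, seed = 1L)
    m <- analyze_strip(s$image, ph$roi, cfg$detection,
                       smooth_window = cfg$smooth_window, flow_axis = cfg$flow_axis)
    m$ratio_tb
  }, 0)
  lod_estimate(cfg$lod_grid, ratios, sigma_r = cfg$lod_sigma_r, k = cfg$lod_k)
}

write_run_outputs <- function(summary, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$strips, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  report <- summary$points
  names(report) <- c("concentration_ng_ml", "mean_ratio", "sd_ratio", "n")
  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  write_calibration_yaml(summary$calibration, summary$config_hash,
                         file.path(out_dir, "calibration.yaml"))
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  json <- list(config_hash = summary$config_hash,
               lod_ng_ml = summary$lod_ng_ml,
               calibration = calibration_to_list(summary$calibration),
               n_strips = nrow(summary$strips),
               strips = summary$strips)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

calibration_to_list <- function(curve) {
  list(coefficients = as.list(curve$coefficients),
       working_lo = curve$working_lo,
       working_hi = curve$working_hi,
       requested_hi = curve$requested_hi,
       trimmed = curve$trimmed,
       residual_rmse = curve$residual_rmse,
       ratio_kind = curve$ratio_kind)
}

#' Read / write a fitted calibration curve as YAML
#'
#' @param curve An `lfa_calibration`.
#' @param hash Config hash recorded alongside the curve.
#' @param path YAML path.
#' @return `write_calibration_yaml` returns `path` invisibly;
#'   `read_calibration_yaml` returns an `lfa_calibration` (without points)
#'   plus a `config_hash` attribute.
#' @export
write_calibration_yaml <- function(curve, hash, path) {
  lst <- calibration_to_list(curve)
  lst$config_hash <- hash
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_calibration_yaml
#' @export
read_calibration_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  curve <- structure(
    list(coefficients = unlist(lst$coefficients),
         working_lo = lst$working_lo,
         working_hi = lst$working_hi,
         requested_hi = lst$requested_hi,
         trimmed = lst$trimmed,
         residual_rmse = lst$residual_rmse,
         ratio_kind = lst$ratio_kind,
         weighted = FALSE,
         points = data.frame(concentration = numeric(0), mean_ratio = numeric(0)),
         n_points = NA_integer_),
    class = "lfa_calibration"
  )
  attr(curve, "config_hash") <- lst$config_hash
  curve
}
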