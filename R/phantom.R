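#' Test-band depth for a given analyte concentration
#'
#' Saturating band-darkness law: depth grows proportionally to concentration
#' at low concentration (colour formation proportional to captured analyte)
#' and plateaus at `cfg$amp_max` as line binding saturates:
#' `depth(c) = amp_max * c / (c + k_half)`.
#'
#' @param concentration Analyte concentration in ng/ml; must be >= 0.
#'   Vectorised.
#' @param cfg A [phantom_config].
#' @return Band depth in intensity counts below background (noise-free).
#' @examples
#' test_band_depth(300, phantom_config())  # equals the control depth, 80
#' @export
test_band_depth <- function(concentration, cfg = phantom_config()) {
  if (!is.numeric(concentration) || anyNA(concentration)) {
    stop_lfa("lfaquant_config_error", "concentration must be numeric")
  }
  if (any(concentration < 0)) {
    stop_lfa("lfaquant_config_error", "concentration must be >= 0")
  }
  cfg$amp_max * concentration / (concentration + cfg$k_half)
}

#' Render a synthetic strip image with known ground truth
#'
#' Builds `background + illumination ramp - control band - test band`, each
#' band a Gaussian cross-section along the flow axis (the image width) and
#' constant across the transverse axis. Both band amplitudes are multiplied
#' by a single per-strip jitter factor (truncated normal, mean 1, sd
#' `cfg$strip_jitter_sd`); per-pixel additive Gaussian noise of sd
#' `cfg$pixel_noise_sd` is then added, values are clipped to \[0, 255\] and
#' quantised (round half up). Optional integer offset and nearest-neighbour
#' rotation are applied last. The same `(concentration, cfg, seed)` always
#' yields a bit-identical image.
#'
#' @param concentration Analyte concentration in ng/ml.
#' @param cfg A [phantom_config].
#' @param seed Integer seed for the strip's jitter and pixel noise.
#' @return A list with elements `image` (a [strip_image]) and `truth`
#'   (ground-truth record: concentration, true band centers in absolute
#'   image columns, true noise-free band depths after jitter, and the seed).
#' @examples
#' cfg <- phantom_config(pixel_noise_sd = 0, strip_jitter_sd = 0)
#' s <- render_strip(300, cfg, seed = 1)
#' s$truth$true_test_depth
#' @export
render_strip <- function(concentration, cfg = phantom_config(), seed = 1L) {
  validate_phantom_config(cfg)
  depth <- test_band_depth(concentration, cfg)  # validates concentration
  if (length(concentration) != 1) {
    stop_lfa("lfaquant_config_error", "render_strip takes a single concentration")
  }

  with_seed(seed, {
    jitter <- rtruncnorm_unit(cfg$strip_jitter_sd)

    h <- cfg$image_height
    w <- cfg$image_width
    ctrl_c <- cfg$control_center
    test_c <- cfg$control_center - cfg$line_spacing

    cols <- 0:(w - 1)
    ramp <- cfg$illumination_slope * (cols - (w - 1) / 2)
    band <- function(center, amp) amp * exp(-(cols - center)^2 / (2 * cfg$band_sigma^2))
    profile_row <- cfg$background_level + ramp -
      jitter * band(ctrl_c, cfg$control_amplitude) -
      jitter * band(test_c, depth)

    img <- matrix(profile_row, nrow = h, ncol = w, byrow = TRUE)
    if (cfg$pixel_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, cfg$pixel_noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 255)
    img <- round_half_up(img)
    img <- pmin(img, 255)

    if (cfg$offset_px != 0) img <- shift_columns(img, cfg$offset_px, fill = round_half_up(cfg$background_level))
    if (cfg$rotation_deg != 0) img <- rotate_nn(img, cfg$rotation_deg, fill = round_half_up(cfg$background_level))

    list(
      image = strip_image(img),
      truth = list(
        concentration = concentration,
        true_test_center = test_c,
        true_control_center = ctrl_c,
        true_test_depth = jitter * depth,
        true_control_depth = jitter * cfg$control_amplitude,
        seed = as.integer(seed)
      )
    )
  })
}

# Integer shift along the flow axis (columns); vacated columns filled.
shift_columns <- function(img, k, fill) {
  w <- ncol(img)
  out <- matrix(fill, nrow(img), w)
  if (k >= 0) {
    if (k < w) out[, (k + 1):w] <- img[, 1:(w - k)]
  } else {
    k <- -k
    if (k < w) out[, 1:(w - k)] <- img[, (k + 1):w]
  }
  out
}

# Nearest-neighbour rotation about the image center.
rotate_nn <- function(img, deg, fill) {
  th <- deg * pi / 180
  h <- nrow(img); w <- ncol(img)
  rc <- (h + 1) / 2; cc <- (w + 1) / 2
  out <- matrix(fill, h, w)
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  # inverse map: source coordinates for each destination pixel
  dr <- grid$r - rc; dc <- grid$c - cc
  sr <- round(rc + cos(th) * dr + sin(th) * dc)
  sc <- round(cc - sin(th) * dr + cos(th) * dc)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out[cbind(grid$r[ok], grid$c[ok])] <- img[cbind(sr[ok], sc[ok])]
  out
}

#' Render a dilution series of phantom strips
#'
#' Deterministically expands `concentrations x replicates` into rendered
#' strips. Per-strip seeds are derived by a stable hash of
#' `(seed, concentration index, replicate index)`, so the same root seed
#' always reproduces the same series.
#'
#' @param concentrations Vector of concentrations in ng/ml (nonempty).
#' @param replicates Number of replicate strips per concentration (>= 1).
#' @param cfg A [phantom_config].
#' @param seed Root integer seed.
#' @return An object of class `phantom_series`: list with `strips` (list of
#'   `render_strip` results) and `manifest` (data frame with one row per
#'   strip: strip_id, concentration_ng_ml, replicate, seed, true centers and
#'   depths).
#' @examples
#' ser <- dilution_series(c(0, 300), 2, phantom_config(), seed = 7)
#' ser$manifest
#' @export
dilution_series <- function(concentrations, replicates, cfg = phantom_config(), seed = 1L) {
  if (length(concentrations) == 0) {
    stop_lfa("lfaquant_config_error", "concentrations must be nonempty")
  }
  if (replicates < 1) {
    stop_lfa("lfaquant_config_error", "replicates must be >= 1")
  }
  strips <- vector("list", length(concentrations) * replicates)
  rows <- vector("list", length(strips))
  k <- 0L
  for (ci in seq_along(concentrations)) {
    for (ri in seq_len(replicates)) {
      k <- k + 1L
      s <- render_strip(concentrations[ci], cfg, seed = derive_seed(seed, ci, ri))
      strips[[k]] <- s
      t <- s$truth
      rows[[k]] <- data.frame(
        strip_id = sprintf("c%02d_r%02d", ci, ri),
        concentration_ng_ml = t$concentration,
        replicate = ri,
        seed = t$seed,
        true_test_center = t$true_test_center,
        true_control_center = t$true_control_center,
        true_test_depth = t$true_test_depth,
        true_control_depth = t$true_control_depth,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(strips = strips, manifest = do.call(rbind, rows), config = cfg,
         seed = as.integer(seed)),
    class = "phantom_series"
  )
}

#' @export
print.phantom_series <- function(x, ...) {
  cat(sprintf("<phantom_series: %d strips, %d concentrations, root seed %d>\n",
              nrow(x$manifest), length(unique(x$manifest$concentration_ng_ml)),
              x$seed))
  invisible(x)
}

#' Default calibration ladder of the phantom study
#'
#' Ten concentrations forming a 1.5-fold dilution series from 1000 ng/ml
#' down plus a blank. The series passes through every concentration the
#' strip vendor's visual bands name (87, 131, 296, 444, 1000 ng/ml).
#'
#' @return Numeric vector of 10 concentrations (ng/ml), increasing.
#' @examples
#' default_ladder()
#' @export
default_ladder <- function() {
  c(0, 39, 58, 87, 131, 197, 296, 444, 667, 1000)
}

#' Write a phantom series to disk
#'
#' Writes one 8-bit grayscale PNG per strip, a CSV manifest and the phantom
#' configuration as YAML.
#'
#' @param series A `phantom_series` from [dilution_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest with a `filename` column prepended.
#' @export
write_phantom_series <- function(series, dir) {
  stopifnot(inherits(series, "phantom_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- series$manifest
  files <- file.path(dir, paste0(man$strip_id, ".png"))
  for (i in seq_along(series$strips)) {
    write_strip_png(series$strips[[i]]$image, files[i])
  }
  man <- cbind(filename = basename(files), man, stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(config_to_list(series$config), file.path(dir, "phantom_config.yaml"))
  invisible(man)
}

# phantom_config <-> plain list (for YAML round-tripping)
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$roi <- unclass(out$roi)
  out
}

config_from_list <- function(lst) {
  roi <- do.call(roi_rect, lst$roi)
  lst$roi <- NULL
  do.call(phantom_config, c(list(roi = roi), lst))
}
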