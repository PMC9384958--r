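# Shared fixtures, built in code.

# Default phantom with all stochastic terms switched off.
noisefree_cfg <- function(...) {
  phantom_config(pixel_noise_sd = 0, strip_jitter_sd = 0, ...)
}

# Geometrically identical to the default (same RoI size, band positions
# relative to the RoI) but on a much smaller sensor, for Monte-Carlo loops.
small_cfg <- function(...) {
  phantom_config(image_height = 50L, image_width = 260L,
                 roi = roi_rect(5L, 30L, 40L, 200L),
                 control_center = 180L, ...)
}

# Wrap a numeric vector as an intensity profile.
make_profile <- function(values, n_averaged = 1L) {
  structure(list(values = as.numeric(values),
                 positions = seq_along(values) - 1L,
                 n_averaged = as.integer(n_averaged)),
            class = "intensity_profile")
}

# RoI-relative true line centers of a phantom config.
rel_centers <- function(cfg) {
  list(test = cfg$control_center - cfg$line_spacing - cfg$roi$col0,
       control = cfg$control_center - cfg$roi$col0)
}
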