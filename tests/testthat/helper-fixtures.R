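# Shared fixtures, built in code. Expensive objects (the fitted simulator
# calibration) are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

clean_render_config <- function() {
  cfg <- render_config()
  cfg$noise_sd <- 0
  cfg
}

calibration_volumes <- function(n_con = 12, n_cyl = 28) {
  c(seq(60, 1400, length.out = n_con), seq(1600, 12000, length.out = n_cyl))
}

# calibration fitted once from noise-free rendered images
sim_calibration_model <- function() cached("sim_model", {
  set.seed(7)
  fit_calibration(render_calibration_dataset(calibration_volumes(),
                                             clean_render_config()))
})

flat_image <- function(value = 128, h = 60, w = 40) {
  px <- array(value, c(h, w, 3))
  reservoir_image(px, roi = c(1, h, 1, w), patch = c(1, h, 15, 26))
}

# horizontal stripe texture of +/- amplitude around mid-gray in the patch;
# the Laplacian of row stripes is +/- 4*amplitude, variance 16*amplitude^2
striped_image <- function(amplitude, h = 60, w = 40) {
  px <- array(128, c(h, w, 3))
  stripe <- 128 + amplitude * rep_len(c(1, -1), h)
  for (k in 1:3) px[, , k] <- matrix(stripe, h, w)
  reservoir_image(px, roi = c(1, h, 1, w), patch = c(1, h, 15, 26))
}

# two-band image: fluid color below (rows > boundary), air color above
two_band_image <- function(boundary_row, h = 120, w = 40,
                           fluid_rgb = c(64, 128, 160),
                           air_rgb = c(230, 220, 200)) {
  px <- array(0, c(h, w, 3))
  for (k in 1:3) {
    px[, , k] <- air_rgb[k]
    if (boundary_row < h) px[(boundary_row + 1):h, , k] <- fluid_rgb[k]
  }
  reservoir_image(px, roi = c(1, h, 1, w), patch = c(1, h, 15, 26))
}

# blob store wrapper corrupting the first `times` puts
corrupting_store <- function(store, times) {
  self <- new.env(parent = emptyenv())
  self$calls <- 0L
  self$path_for <- store$path_for
  self$put <- function(key, src) {
    self$calls <- self$calls + 1L
    store$put(key, src)
    if (self$calls <= times)
      writeLines("corrupted", store$path_for(key))
    invisible(key)
  }
  self$checksum <- store$checksum
  self$exists <- store$exists
  self
}

null_notifier <- function(msg) invisible(msg)
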