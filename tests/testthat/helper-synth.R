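# Shared synthetic fixtures, built in code and cached across tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small empty-arena scene used for background / detection fixtures
small_scene <- function(seed, n_flies = 0L, noise_sd = 2, ...) {
  scene_config(
    width = 120, height = 120, plate_center = c(60, 60), plate_radius = 50,
    n_flies = n_flies, noise_sd = noise_sd, seed = seed, ...
  )
}

# background model fitted on pre-filtered empty-arena frames
small_bg_model <- function(noise_sd = 2) {
  key <- paste0("bg_", noise_sd)
  cached(key, {
    empty <- data.frame(
      frame = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
      theta = numeric(0), vx = numeric(0), vy = numeric(0), w = numeric(0)
    )
    frames <- lapply(1:11, function(i) {
      preprocess_frame(render_frame(empty, small_scene(300 + i, noise_sd = noise_sd), 0), 1)
    })
    fit_background(frames)
  })
}

# render flies at given poses into the small arena and pre-filter
render_flies <- function(x, y, theta, seed = 1, noise_sd = 2, fly_axes = c(6, 3)) {
  cfg <- small_scene(seed, noise_sd = noise_sd, fly_axes = fly_axes)
  truth <- data.frame(
    frame = 0L, id = seq_along(x), x = x, y = y, theta = theta,
    vx = 0, vy = 0, w = 0
  )
  preprocess_frame(render_frame(truth, cfg, 0), 1)
}

# a pixel grid + Gaussian weights for one rendered blob (full support,
# no threshold truncation): the recovery target of fit_ellipse
gaussian_blob_pixels <- function(cx, cy, theta, a, b, extent = 4) {
  su <- a / 2; sv <- b / 2
  r <- ceiling(extent * su)
  gx <- seq(floor(cx) - r, floor(cx) + r)
  gy <- seq(floor(cy) - r, floor(cy) + r)
  px <- cbind(x = rep(gx, each = length(gy)), y = rep(gy, length(gx)))
  u <- cos(theta) * (px[, 1] - cx) + sin(theta) * (px[, 2] - cy)
  v <- -sin(theta) * (px[, 1] - cx) + cos(theta) * (px[, 2] - cy)
  w <- exp(-u^2 / (2 * su^2) - v^2 / (2 * sv^2))
  keep <- w > 1e-4
  list(pixels = px[keep, , drop = FALSE], weights = w[keep])
}

# the standard 8-fly crossing scenario at the default arena density
crossing_scenario <- function(seed = 11L, n_frames = 500L) {
  key <- paste0("crossing_", seed, "_", n_frames)
  cached(key, {
    cfg <- scene_config(
      n_flies = 8, seed = seed,
      events = list(
        list(type = "crossing", flies = c(1, 2), frame = 180, point = c(160, 200)),
        list(type = "crossing", flies = c(3, 4), frame = 280, point = c(240, 180)),
        list(type = "crossing", flies = c(5, 6), frame = 380, point = c(200, 240))
      )
    )
    sq <- synthetic_sequence(cfg, n_frames)
    res <- track_sequence(sq$frames, pipeline_config(), n_frames = n_frames)
    list(cfg = cfg, truth = sq$truth, result = res)
  })
}

# 4 well-separated flies, no interactions
quiet_scenario <- function(seed = 5L, n_frames = 500L) {
  key <- paste0("quiet_", seed, "_", n_frames)
  cached(key, {
    cfg <- scene_config(
      width = 320, height = 320, plate_center = c(160, 160), plate_radius = 140,
      n_flies = 4, noise_sd = 2, seed = seed, speed_mean = 1.5, turn_sd = 0.2
    )
    sq <- synthetic_sequence(cfg, n_frames)
    res <- track_sequence(sq$frames, pipeline_config(warmup_frames = 60), n_frames = n_frames)
    list(cfg = cfg, truth = sq$truth, result = res)
  })
}
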