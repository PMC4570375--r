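#' Synthetic arena scene configuration
#'
#' Describes a synthetic recording of flies on a circular backlit
#' plate. Defaults emulate the standard imaging conditions of the
#' method: a bright plate of radius 180 px (a 4.5 cm plate at
#' 4 px/mm), 8 flies (0.12 flies/cm^2), 15 fps, dark elliptical
#' fly blobs with a Gaussian brightness profile (darkest at the
#' center, brightening toward the boundary) and additive Gaussian
#' pixel noise. Optional scripted events force crossings,
#' stop-and-merge interactions and boundary-reflection artifacts so
#' that the merge/split and probation logic can be exercised
#' deterministically.
#'
#' @param width,height frame size in px.
#' @param plate_center,plate_radius plate geometry in px.
#' @param n_flies number of flies.
#' @param fps frame rate.
#' @param background_level plate intensity (0-255).
#' @param surround_level intensity outside the plate.
#' @param fly_contrast peak darkening of a fly below the plate level.
#' @param fly_axes ellipse half axes `c(a, b)` of the rendered flies,
#'   px; the Gaussian profile sds are `a/2` and `b/2` so the
#'   weighted-covariance fit recovers `(a, b)` analytically.
#' @param noise_sd additive Gaussian pixel noise sd, intensity units.
#' @param illumination_drift `c(amplitude, period_frames)` of a slow
#'   sinusoidal plate-brightness drift; amplitude 0 disables it.
#' @param speed_mean,speed_sd per-fly walking speed distribution,
#'   px/frame.
#' @param turn_sd heading persistence: sd of the per-frame heading
#'   increment, rad.
#' @param events list of scripted events; each a list with `type`
#'   (`"crossing"`, `"stop_merge"` or `"reflection"`) and fields
#'   `frame`, and per type: `flies` + optional `point` (crossing,
#'   stop_merge), `hold` (stop_merge), `angle` + `duration`
#'   (reflection).
#' @param seed RNG seed for the whole dataset (one shared stream).
#' @return a validated `scene_config`.
#' @export
scene_config <- function(width = 400, height = 400,
                         plate_center = c(200, 200), plate_radius = 180,
                         n_flies = 8, fps = 15,
                         background_level = 220, surround_level = 60,
                         fly_contrast = 120, fly_axes = c(6, 3),
                         noise_sd = 2, illumination_drift = c(0, 1500),
                         speed_mean = 2, speed_sd = 0.5, turn_sd = 0.15,
                         events = list(), seed = 1L) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    plate_center = as.numeric(plate_center), plate_radius = as.numeric(plate_radius),
    n_flies = as.integer(n_flies), fps = fps,
    background_level = background_level, surround_level = surround_level,
    fly_contrast = fly_contrast, fly_axes = as.numeric(fly_axes),
    noise_sd = noise_sd, illumination_drift = as.numeric(illumination_drift),
    speed_mean = speed_mean, speed_sd = speed_sd, turn_sd = turn_sd,
    events = events, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_flies >= 0, cfg$noise_sd >= 0, cfg$plate_radius > 0,
    cfg$plate_center[1] + cfg$plate_radius <= cfg$width,
    cfg$plate_center[2] + cfg$plate_radius <= cfg$height,
    cfg$plate_center[1] - cfg$plate_radius >= 0,
    cfg$plate_center[2] - cfg$plate_radius >= 0,
    cfg$fly_axes[1] >= cfg$fly_axes[2], cfg$fly_axes[2] > 0
  )
  structure(cfg, class = "scene_config")
}

#' Fly density of a scene
#'
#' Flies per cm^2 given the plate radius in px and the spatial
#' resolution.
#'
#' @param cfg a `scene_config`.
#' @param px_per_mm spatial resolution; default 4 px/mm.
#' @return flies/cm^2.
#' @export
scene_density <- function(cfg, px_per_mm = 4) {
  r_cm <- cfg$plate_radius / px_per_mm / 10
  cfg$n_flies / (pi * r_cm^2)
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate ground-truth fly trajectories
#'
#' A smooth heading-persistent random walk per fly: constant individual
#' speed drawn once, per-frame heading increments, and specular
#' reflection at the plate wall. Scripted events override the walk:
#' `crossing` steers two flies through a common point at a given frame
#' (forcing their blobs to overlap), `stop_merge` brings two flies
#' together, holds them still, then separates them. Motion is kinematic
#' — flies pass through each other — which is what exercises the
#' merge/split logic. Fully reproducible from the config seed.
#'
#' @param cfg a [scene_config()].
#' @param n_frames number of frames.
#' @return a `ground_truth` data frame (`frame`, `id`, `x`, `y`,
#'   `theta`, `vx`, `vy`, `w`) with an `overlaps` attribute
#'   (data frame `frame`, `id1`, `id2` of blob-merging pairs).
#' @export
simulate_trajectories <- function(cfg, n_frames) {
  n <- cfg$n_flies
  empty <- data.frame(
    frame = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
    theta = numeric(0), vx = numeric(0), vy = numeric(0), w = numeric(0)
  )
  if (n == 0L || n_frames == 0L) {
    attr(empty, "overlaps") <- data.frame(
      frame = integer(0), id1 = integer(0), id2 = integer(0)
    )
    class(empty) <- c("ground_truth", class(empty))
    return(empty)
  }
  with_seed(cfg$seed, {
    margin <- 2 * cfg$fly_axes[1] + 2
    rmax <- cfg$plate_radius - margin
    # initial placement: uniform in the inner disk, minimum separation
    pos <- matrix(NA_real_, n, 2)
    placed <- 0L
    while (placed < n) {
      r <- rmax * sqrt(stats::runif(1)) * 0.9
      a <- stats::runif(1, 0, 2 * pi)
      p <- cfg$plate_center + r * c(cos(a), sin(a))
      if (placed == 0L ||
        all(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2, p)^2)) >
          4 * cfg$fly_axes[1])) {
        placed <- placed + 1L
        pos[placed, ] <- p
      }
    }
    speed <- pmax(abs(stats::rnorm(n, cfg$speed_mean, cfg$speed_sd)), 0.2)
    heading <- stats::runif(n, -pi, pi)

    X <- array(NA_real_, c(n_frames, n, 2))
    TH <- matrix(NA_real_, n_frames, n)

    # per-fly scripted overrides: steer toward a point until a frame,
    # then optionally hold, then continue straight
    steer_until <- rep(NA_integer_, n)
    steer_point <- matrix(NA_real_, n, 2)
    hold_until <- rep(NA_integer_, n)
    release_until <- rep(NA_integer_, n)
    schedule <- list()
    for (ev in cfg$events) {
      if (!ev$type %in% c("crossing", "stop_merge")) next
      schedule[[length(schedule) + 1L]] <- ev
    }

    # crossings are transversal, as in real fly paths: each participant
    # approaches the common point from a direction ~90 degrees apart,
    # staged so that the final approach is a straight constant-speed leg
    approach <- 40L
    stage_lead <- 160L
    for (t in seq_len(n_frames)) {
      for (ev in schedule) {
        pt <- if (!is.null(ev$point)) ev$point else cfg$plate_center
        if (t == max(ev$frame - stage_lead, 1L)) {
          phi <- stats::runif(1, 0, 2 * pi)
          for (ii in seq_along(ev$flies)) {
            f <- ev$flies[ii]
            dir <- phi + (ii - 1) * pi / 2
            stage <- pt - approach * speed[f] * c(cos(dir), sin(dir))
            rel <- stage - cfg$plate_center
            if (sqrt(sum(rel^2)) > rmax) {
              stage <- cfg$plate_center + rel / sqrt(sum(rel^2)) * (0.9 * rmax)
            }
            steer_until[f] <- ev$frame - approach
            steer_point[f, ] <- stage
          }
        }
        if (t == max(ev$frame - approach, 1L)) {
          for (ii in seq_along(ev$flies)) {
            f <- ev$flies[ii]
            off <- (ii - 1.5) * 1.5 # avoid exact coincidence at the point
            steer_until[f] <- ev$frame
            steer_point[f, ] <- pt + c(off, -off)
            if (ev$type == "stop_merge") {
              hold_until[f] <- ev$frame + (if (is.null(ev$hold)) 60L else ev$hold)
            }
          }
        }
      }
      for (f in seq_len(n)) {
        if (!is.na(steer_until[f]) && t <= steer_until[f]) {
          togo <- steer_until[f] - t + 1L
          d <- steer_point[f, ] - pos[f, ]
          dist <- sqrt(sum(d^2))
          # physical speeds only: capped steering, never teleports
          sp <- min(dist / togo, max(1.75 * speed[f], 3))
          v <- if (dist < 1e-9) c(0, 0) else d / dist * sp
          pos[f, ] <- pos[f, ] + v
          if (dist >= 1e-9) heading[f] <- atan2(v[2], v[1])
          if (t == steer_until[f]) {
            steer_until[f] <- NA_integer_
            release_until[f] <- t + 25L
          }
        } else if (!is.na(hold_until[f]) && t <= hold_until[f]) {
          # stopped in the cluster
          if (t == hold_until[f]) {
            hold_until[f] <- NA_integer_
            heading[f] <- stats::runif(1, -pi, pi)
            release_until[f] <- t + 25L
          }
        } else {
          straight <- !is.na(release_until[f]) && t <= release_until[f]
          if (!straight) {
            heading[f] <- heading[f] + stats::rnorm(1, 0, cfg$turn_sd)
          } else if (t == release_until[f]) {
            release_until[f] <- NA_integer_
          }
          step <- speed[f] * c(cos(heading[f]), sin(heading[f]))
          newp <- pos[f, ] + step
          # specular reflection at the wall
          rel <- newp - cfg$plate_center
          if (sqrt(sum(rel^2)) > rmax) {
            nrm <- rel / sqrt(sum(rel^2))
            dir <- c(cos(heading[f]), sin(heading[f]))
            dir <- dir - 2 * sum(dir * nrm) * nrm
            heading[f] <- atan2(dir[2], dir[1])
            newp <- pos[f, ] + speed[f] * dir
            rel <- newp - cfg$plate_center
            if (sqrt(sum(rel^2)) > rmax) {
              newp <- cfg$plate_center + rel / sqrt(sum(rel^2)) * rmax
            }
          }
          pos[f, ] <- newp
        }
        X[t, f, ] <- pos[f, ]
        TH[t, f] <- heading[f]
      }
    }

    vx <- apply(X[, , 1, drop = FALSE], 2, function(x) c(0, diff(x)))
    vy <- apply(X[, , 2, drop = FALSE], 2, function(x) c(0, diff(x)))
    w <- apply(TH, 2, function(th) c(0, wrap_pi(diff(th))))

    truth <- data.frame(
      frame = rep(seq_len(n_frames) - 1L, each = n),
      id = rep(seq_len(n), n_frames),
      x = as.numeric(t(X[, , 1])),
      y = as.numeric(t(X[, , 2])),
      theta = as.numeric(t(wrap_pi(TH))),
      vx = as.numeric(t(vx)),
      vy = as.numeric(t(vy)),
      w = as.numeric(t(w))
    )
    attr(truth, "overlaps") <- find_overlaps(truth, cfg)
    class(truth) <- c("ground_truth", class(truth))
    truth
  })
}

# pairs whose rendered blobs merge at the default threshold: center
# distance below the sum of the projected threshold-contour radii
find_overlaps <- function(truth, cfg, contour_scale = 1.9) {
  res <- list()
  ru <- contour_scale * cfg$fly_axes[1] / 2
  rv <- contour_scale * cfg$fly_axes[2] / 2
  for (f in unique(truth$frame)) {
    s <- truth[truth$frame == f, ]
    n <- nrow(s)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        dx <- s$x[j] - s$x[i]; dy <- s$y[j] - s$y[i]
        d <- sqrt(dx^2 + dy^2)
        ang <- atan2(dy, dx)
        ri <- ellipse_radius(ang - s$theta[i], ru, rv)
        rj <- ellipse_radius(ang - s$theta[j], ru, rv)
        if (d < ri + rj) {
          res[[length(res) + 1L]] <- data.frame(
            frame = f, id1 = s$id[i], id2 = s$id[j]
          )
        }
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(frame = integer(0), id1 = integer(0), id2 = integer(0))
}

ellipse_radius <- function(phi, a, b) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Render one synthetic frame
#'
#' Bright plate disk on a darker surround; each fly subtracts an
#' anisotropic Gaussian brightness profile (peak `fly_contrast`,
#' profile sds `fly_axes / 2`, rotated to the fly's orientation), so
#' pixels are darkest at the fly center and brighten toward its
#' boundary. Optional boundary-reflection blobs are rendered at
#' reduced contrast just inside the wall; additive Gaussian noise and
#' a slow sinusoidal illumination drift complete the imaging model.
#' Deterministic given `(truth, cfg, frame)`: the noise stream is
#' seeded from the dataset seed and the frame index.
#'
#' @param truth ground-truth data frame (rows of the rendered frame
#'   are selected by `frame`).
#' @param cfg a [scene_config()].
#' @param frame 0-based frame index.
#' @return intensity matrix in \[0, 255\].
#' @export
render_frame <- function(truth, cfg, frame = 0L) {
  h <- cfg$height; w <- cfg$width
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), w), h, w)
  d2 <- (xg - cfg$plate_center[1])^2 + (yg - cfg$plate_center[2])^2
  drift <- if (cfg$illumination_drift[1] > 0) {
    cfg$illumination_drift[1] * sin(2 * pi * frame / cfg$illumination_drift[2])
  } else {
    0
  }
  img <- matrix(cfg$surround_level, h, w)
  img[d2 <= cfg$plate_radius^2] <- cfg$background_level + drift

  rows <- truth[truth$frame == frame, , drop = FALSE]
  su <- cfg$fly_axes[1] / 2
  sv <- cfg$fly_axes[2] / 2
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      img <- subtract_blob(
        img, rows$x[i], rows$y[i], rows$theta[i],
        su, sv, cfg$fly_contrast
      )
    }
  }
  for (ev in cfg$events) {
    if (!identical(ev$type, "reflection")) next
    dur <- if (is.null(ev$duration)) 10L else ev$duration
    if (frame >= ev$frame && frame < ev$frame + dur) {
      rr <- cfg$plate_radius - 4
      cx <- cfg$plate_center[1] + rr * cos(ev$angle)
      cy <- cfg$plate_center[2] + rr * sin(ev$angle)
      img <- subtract_blob(img, cx, cy, ev$angle + pi / 2, su, sv, cfg$fly_contrast * 0.5)
    }
  }
  if (cfg$noise_sd > 0) {
    img <- img + with_seed(
      (cfg$seed + 7919 * (frame + 1L)) %% .Machine$integer.max,
      matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
    )
  }
  pmin(pmax(img, 0), 255)
}

# subtract an anisotropic Gaussian profile within a local window
subtract_blob <- function(img, cx, cy, theta, su, sv, contrast) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * su)
  rs <- max(1L, floor(cy) + 1L - r):min(h, floor(cy) + 1L + r)
  cs <- max(1L, floor(cx) + 1L - r):min(w, floor(cx) + 1L + r)
  if (!length(rs) || !length(cs)) return(img)
  xx <- matrix(rep(cs - 1, each = length(rs)), length(rs)) - cx
  yy <- matrix(rep(rs - 1, length(cs)), length(rs)) - cy
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  img[rs, cs] <- img[rs, cs] - contrast * exp(-u^2 / (2 * su^2) - v^2 / (2 * sv^2))
  img
}

#' Render a whole synthetic sequence in memory
#'
#' @param cfg a [scene_config()].
#' @param n_frames number of frames.
#' @param truth optional precomputed ground truth.
#' @return list with `frames` (generator function), `n_frames` and
#'   `truth`.
#' @export
synthetic_sequence <- function(cfg, n_frames, truth = NULL) {
  if (is.null(truth)) truth <- simulate_trajectories(cfg, n_frames)
  list(
    frames = function(i) render_frame(truth, cfg, i - 1L),
    n_frames = n_frames,
    truth = truth
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes numbered 8-bit grayscale PNG frames, the ground-truth CSV and
#' the scene configuration (YAML) to a directory. Regenerating with the
#' same seed reproduces identical files.
#'
#' @param cfg a [scene_config()].
#' @param n_frames number of frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the written paths.
#' @export
generate_dataset <- function(cfg, n_frames, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  truth <- simulate_trajectories(cfg, n_frames)
  paths <- character(n_frames)
  for (i in seq_len(n_frames)) {
    img <- render_frame(truth, cfg, i - 1L)
    paths[i] <- file.path(out_dir, sprintf("frame_%05d.png", i - 1L))
    png::writePNG(round(img) / 255, paths[i])
  }
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(as.data.frame(truth), truth_path, row.names = FALSE)
  ov_path <- file.path(out_dir, "overlaps.csv")
  utils::write.csv(attr(truth, "overlaps"), ov_path, row.names = FALSE)
  cfg_path <- file.path(out_dir, "scene.yaml")
  cfg_out <- unclass(cfg)
  cfg_out$events <- NULL
  yaml::write_yaml(cfg_out, cfg_path)
  invisible(list(
    frames = paths, truth = truth_path, overlaps = ov_path, config = cfg_path
  ))
}
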