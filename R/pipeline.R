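#' Track a whole image sequence
#'
#' Runs the full three-phase pipeline — background fitting, per-frame
#' segmentation and validation, and Kalman/Hungarian identity tracking —
#' over a frame sequence and returns per-frame results plus a tidy
#' trajectory table. The first `warmup_frames` frames fit the
#' background and the element-area model; tracking starts on the
#' following frame. Identities are never reused; output rows of
#' provisional trackers that fail the stability probation are dropped,
#' so spurious blobs and boundary reflections never reach the
#' trajectory table.
#'
#' @param frames a directory of PNG frames, a list of intensity
#'   matrices, a 3-D array, or a generator `function(i)` (then
#'   `n_frames` is required).
#' @param config a [pipeline_config()].
#' @param n_frames number of frames when `frames` is a function.
#' @return an object of class `fly_tracks`: list with `trajectories`
#'   (data frame: frame, time_s, track_id, x_px, y_px, theta_rad, a_px,
#'   b_px, vx, vy, w, status, n_merged), `frame_results`, `events`,
#'   `background`, `area_model`, `plate`, `config`.
#' @export
track_sequence <- function(frames, config = pipeline_config(), n_frames = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else do.call(pipeline_config, config)
  fp <- frame_provider(frames, n_frames)
  if (fp$n < 1L) stop("empty frame sequence")
  wu <- min(cfg$warmup_frames, max(fp$n - 1L, 3L))
  if (fp$n <= 3L) stop("sequence too short: background fitting needs warmup frames")

  warm <- lapply(seq_len(wu), function(i) preprocess_frame(fp$get(i), cfg$blur_sigma))
  bg <- fit_background(warm, cfg$c_mad, cfg$update_period, cfg$alpha)

  roi <- if (!is.null(cfg$plate)) {
    plate_roi(cfg$plate[1], cfg$plate[2], cfg$plate[3],
      enabled = TRUE, reflection_band_px = cfg$reflection_band
    )
  } else if (isTRUE(cfg$plate_detect)) {
    detect_plate(warm[[1L]], reflection_band_px = cfg$reflection_band)
  } else {
    disabled_roi(warm[[1L]], cfg$reflection_band)
  }

  # element-area model from warmup detections (fitted-ellipse areas)
  areas <- numeric(0)
  for (i in seq(1L, wu, by = 2L)) {
    fgw <- subtract_background(bg, warm[[i]], cfg$N, cfg$polarity, cfg$sigma_floor)
    cps <- Filter(
      function(cp) cp$area >= cfg$min_px,
      connected_components(fgw)
    )
    for (cp in cps) {
      e <- fit_component_ellipse(cp, bg, warm[[i]], cfg$sigma_floor)
      areas <- c(areas, pi * e$a * e$b)
    }
  }
  am <- if (length(areas)) fit_area_model(areas, cfg$c_clean) else NULL
  rm(warm)

  trackers <- list()
  next_id <- 1L
  rows <- list()
  frame_results <- vector("list", fp$n - wu)
  all_events <- list()

  for (i in seq(wu + 1L, fp$n)) {
    fr <- tryCatch(preprocess_frame(fp$get(i), cfg$blur_sigma), error = function(e) NULL)
    if (is.null(fr)) {
      warning("skipping unreadable frame ", i - 1L)
      next
    }
    fidx <- i - 1L # 0-based frame index
    fg <- subtract_background(bg, fr, cfg$N, cfg$polarity, cfg$sigma_floor)
    comps <- Filter(function(cp) cp$area >= cfg$min_px, connected_components(fg))
    if (is.null(am) && length(comps)) {
      a0 <- vapply(comps, function(cp) {
        e <- fit_component_ellipse(cp, bg, fr, cfg$sigma_floor)
        pi * e$a * e$b
      }, numeric(1))
      am <- fit_area_model(a0, cfg$c_clean)
    }
    if (!is.null(am)) comps <- area_filter(comps, am)
    dets <- if (is.null(am)) {
      lapply(comps, fit_component_ellipse, model = bg, frame = fr, sigma_floor = cfg$sigma_floor)
    } else {
      validate_detections(
        comps, am, bg, fr,
        N = cfg$N, dN = cfg$dN, max_steps = cfg$max_steps,
        accept_floor = cfg$accept_floor, improve_tol = cfg$improve_tol,
        sigma_floor = cfg$sigma_floor, polarity = cfg$polarity,
        min_px = cfg$min_px, min_sigma_frac = cfg$min_sigma_frac
      )
    }
    ddf <- detections_df(dets)
    if (nrow(ddf)) {
      keep <- as.integer(rownames(mask_reflections(ddf, roi)))
      dets <- dets[keep]
      ddf <- detections_df(dets)
    }

    live_idx <- which(vapply(trackers, function(t) t$status != "retired", logical(1)))
    for (li in live_idx) trackers[[li]] <- kalman_predict(trackers[[li]], dt = 1)
    live <- trackers[live_idx]

    asn <- assign_identities(live, ddf, gate = cfg$gate)

    id_of <- vapply(trackers, function(t) t$id, integer(1))

    if (nrow(asn$pairs)) {
      for (r in seq_len(nrow(asn$pairs))) {
        ti <- match(asn$pairs$tracker_id[r], id_of)
        trackers[[ti]] <- apply_measurement(trackers[[ti]], dets[[asn$pairs$detection[r]]], cfg)
        trackers[[ti]]$last_detection <- asn$pairs$detection[r]
      }
    }
    n_merged_of <- setNames(integer(length(trackers)), id_of)
    if (length(asn$merged_groups)) {
      for (key in names(asn$merged_groups)) {
        gids <- asn$merged_groups[[key]]
        comp_det <- dets[[as.integer(key)]]
        group <- trackers[match(gids, id_of)]
        outcomes <- resolve_merge(group, comp_det, am, bg, fr, cfg)
        for (oc in outcomes) {
          ti <- match(oc$id, id_of)
          n_merged_of[as.character(oc$id)] <- length(gids)
          if (!is.null(oc$det)) {
            # a resolved split pins each tracker to its own sub-element,
            # so the ambiguity penalty is much smaller than for the
            # shared-blob measurement
            if (oc$mode %in% c("split", "kmeans")) {
              trackers[[ti]] <- apply_measurement(trackers[[ti]], oc$det, cfg,
                R_scale = max(cfg$merge_R_inflation / 10, 1)
              )
            } else {
              trackers[[ti]] <- apply_measurement(trackers[[ti]], oc$det, cfg,
                R_scale = cfg$merge_R_inflation, blob = TRUE
              )
            }
          }
          # without any usable measurement the prediction stands
        }
      }
    }

    lc <- lifecycle_step(trackers, asn, dets, fidx, cfg, next_id)
    trackers <- lc$trackers
    next_id <- lc$next_id
    if (nrow(lc$events)) all_events[[length(all_events) + 1L]] <- lc$events

    # record one row per live tracker; provisional rows are buffered
    id_of <- vapply(trackers, function(t) t$id, integer(1))
    for (ti in seq_along(trackers)) {
      t <- trackers[[ti]]
      if (t$status == "retired") {
        if (t$provisional) trackers[[ti]]$buffer <- list() # drop unreported rows
        next
      }
      nm <- n_merged_of[as.character(t$id)]
      row <- data.frame(
        frame = fidx, time_s = fidx / cfg$fps, track_id = t$id,
        x_px = t$x_state[1], y_px = t$x_state[2], theta_rad = t$x_state[5],
        a_px = t$a, b_px = t$b, vx = t$x_state[3], vy = t$x_state[4],
        w = t$x_state[6], status = t$status,
        n_merged = if (is.na(nm)) 0L else nm
      )
      if (t$provisional) {
        trackers[[ti]]$buffer <- c(t$buffer, list(row))
      } else {
        if (length(t$buffer)) {
          rows <- c(rows, t$buffer)
          trackers[[ti]]$buffer <- list()
        }
        rows[[length(rows) + 1L]] <- row
      }
    }

    frame_results[[i - wu]] <- list(
      frame = fidx,
      detections = ddf,
      assignment = asn
    )

    # periodic selective background update; tracker footprints are
    # frozen so stopped flies never burn into the model
    if ((i - wu) %% cfg$update_period == 0L) {
      mask <- fg$mask | tracker_footprint_mask(trackers, dim(fr))
      bg <- update_background(bg, fr, mask)
    }
  }

  traj <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$frame, out$track_id), , drop = FALSE]
  } else {
    data.frame(
      frame = integer(0), time_s = numeric(0), track_id = integer(0),
      x_px = numeric(0), y_px = numeric(0), theta_rad = numeric(0),
      a_px = numeric(0), b_px = numeric(0), vx = numeric(0),
      vy = numeric(0), w = numeric(0), status = character(0),
      n_merged = integer(0)
    )
  }
  rownames(traj) <- NULL
  structure(
    list(
      trajectories = traj,
      frame_results = frame_results,
      events = if (length(all_events)) do.call(rbind, all_events) else
        data.frame(frame = integer(0), event = character(0), id = integer(0)),
      background = bg,
      area_model = am,
      plate = roi,
      config = cfg
    ),
    class = "fly_tracks"
  )
}

# disks of radius 2a at live tracker positions
tracker_footprint_mask <- function(trackers, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (t in trackers) {
    if (t$status == "retired") next
    r <- max(ceiling(2 * t$a), 4L)
    cx <- round(t$x_state[1]) + 1L
    cy <- round(t$x_state[2]) + 1L
    if (cy + r < 1L || cy - r > dims[1] || cx + r < 1L || cx - r > dims[2]) next
    rs <- max(1L, cy - r):min(dims[1], cy + r)
    cs <- max(1L, cx - r):min(dims[2], cx + r)
    sub <- outer((rs - cy)^2, (cs - cx)^2, `+`) <= r^2
    mask[rs, cs] <- mask[rs, cs] | sub
  }
  mask
}

#' @export
print.fly_tracks <- function(x, ...) {
  nid <- length(unique(x$trajectories$track_id))
  cat(sprintf(
    "fly_tracks: %d frames tracked, %d identities, %d trajectory rows\n",
    length(x$frame_results), nid, nrow(x$trajectories)
  ))
  if (nrow(x$events)) {
    tab <- table(x$events$event)
    cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.fly_tracks <- function(object, ...) {
  tr <- object$trajectories
  occ <- count_occlusion_frames(object$frame_results)
  ids <- unique(tr$track_id)
  per_id <- do.call(rbind, lapply(ids, function(id) {
    s <- tr[tr$track_id == id, ]
    data.frame(
      track_id = id, n_frames = nrow(s),
      mean_speed = mean(sqrt(s$vx^2 + s$vy^2)),
      path_px = sum(sqrt(diff(s$x_px)^2 + diff(s$y_px)^2))
    )
  }))
  out <- list(
    n_identities = length(ids),
    n_frames = length(object$frame_results),
    occlusion_frames = occ,
    per_track = per_id
  )
  class(out) <- "summary.fly_tracks"
  out
}

#' @export
print.summary.fly_tracks <- function(x, ...) {
  cat(sprintf(
    "%d identities over %d frames (%d occlusion frames)\n",
    x$n_identities, x$n_frames, x$occlusion_frames
  ))
  print(x$per_track, row.names = FALSE)
  invisible(x)
}

#' Plot tracked trajectories
#'
#' @param x a `fly_tracks` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fly_tracks <- function(x, ...) {
  tr <- x$trajectories
  if (!nrow(tr)) {
    plot(0, 0, type = "n", xlab = "x (px)", ylab = "y (px)", main = "no tracks")
    return(invisible(x))
  }
  ids <- sort(unique(tr$track_id))
  cols <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")
  plot(NA,
    xlim = range(tr$x_px), ylim = rev(range(tr$y_px)),
    xlab = "x (px)", ylab = "y (px)", asp = 1, ...
  )
  if (inherits(x$plate, "plate_roi") && x$plate$enabled) {
    a <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(
      x$plate$center_x + x$plate$radius * cos(a),
      x$plate$center_y + x$plate$radius * sin(a),
      col = "grey70"
    )
  }
  for (k in seq_along(ids)) {
    s <- tr[tr$track_id == ids[k], ]
    graphics::lines(s$x_px, s$y_px, col = cols[k])
  }
  graphics::legend("topright",
    legend = ids, col = cols[seq_along(ids)],
    lty = 1, cex = 0.7, title = "track"
  )
  invisible(x)
}

#' Write a trajectory table to CSV
#'
#' @param x a `fly_tracks` object or its `trajectories` data frame.
#' @param path output CSV path.
#' @export
write_trajectories <- function(x, path) {
  tr <- if (inherits(x, "fly_tracks")) x$trajectories else x
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
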