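#' Create a tracker for a newly detected fly
#'
#' A tracker owns one fly's identity: its Kalman state and covariance,
#' noise models, lifecycle status (`active`, `merged`, `coasting`,
#' `waiting` or `retired`) and a short measurement history for velocity
#' smoothing. New trackers are provisional: their output is buffered and
#' only committed once they survive the stability probation
#' (50 frames at 15 fps by default), which is what silently removes
#' spurious blobs and boundary reflections.
#'
#' @param id persistent integer identity (never reused).
#' @param det an `ellipse_detection` (or one-row data frame).
#' @param frame_index 0-based frame of first appearance.
#' @param cfg a [pipeline_config()].
#' @return a `tracker` list.
#' @export
make_tracker <- function(id, det, frame_index, cfg = pipeline_config()) {
  structure(
    list(
      id = as.integer(id),
      x_state = c(det$x, det$y, 0, 0, det$theta, 0),
      P = diag(c(4, 4, 4, 4, 0.25, 0.25)),
      Q = process_noise(cfg),
      R = measurement_noise(cfg),
      status = "active",
      provisional = TRUE,
      spawn_frame = as.integer(frame_index),
      age_frames = 0L,
      frames_since_seen = 0L,
      last_known = c(det$x, det$y),
      last_detection = NA_integer_,
      history = matrix(c(det$x, det$y, det$theta), 1, 3,
        dimnames = list(NULL, c("x", "y", "theta"))
      ),
      theta_cont = det$theta,
      a = det$a, b = det$b,
      buffer = list()
    ),
    class = "tracker"
  )
}

push_history <- function(t, x, y, theta_meas, window) {
  th <- unwrap_axis(theta_meas, t$theta_cont)
  t$theta_cont <- th
  t$history <- rbind(t$history, c(x, y, th))
  keep <- max(1L, nrow(t$history) - window)
  t$history <- t$history[keep:nrow(t$history), , drop = FALSE]
  t
}

# full 6-vector measurement from a detection, with smoothed velocities
tracker_measurement <- function(t, det, cfg) {
  t <- push_history(t, det$x, det$y, det$theta, cfg$vel_window + 1L)
  v <- smooth_velocity(t$history, cfg$vel_window)
  z <- c(det$x, det$y, v[1], v[2], t$theta_cont, v[3])
  # express the angle near the predicted value for a small innovation
  z[5] <- unwrap_axis(z[5], t$x_state[5])
  list(tracker = t, z = z)
}

apply_measurement <- function(t, det, cfg, R_scale = 1, blob = FALSE) {
  m <- tracker_measurement(t, det, cfg)
  t <- m$tracker
  t <- kalman_update(t, m$z, R = t$R * R_scale)
  t$last_known <- t$x_state[1:2]
  if (!blob) {
    # the shared blob's shape describes the whole cluster, not this fly
    t$a <- 0.8 * t$a + 0.2 * det$a
    t$b <- 0.8 * t$b + 0.2 * det$b
  }
  t$frames_since_seen <- 0L
  t
}

#' Resolve a merged blob shared by several trackers
#'
#' When the assignment puts two or more trackers on one detection, the
#' blob is first re-segmented with a threshold higher than the base
#' segmentation threshold. If sub-elements appear they are re-assigned
#' within the group by the Gaussian score and used as measurements with
#' inflated uncertainty. If the split fails and the group is static
#' (all predicted speeds below `static_speed`), the component's pixels
#' are clustered by k-means seeded at the trackers' last known
#' positions and refined by expectation-maximization. Otherwise each
#' tracker coasts on its Kalman prediction — the universal fallback.
#'
#' @param group list of trackers sharing the blob.
#' @param component the merged detection (carries `pixels`, `weights`).
#' @param area_model,bg_model,frame segmentation context.
#' @param cfg a [pipeline_config()].
#' @return list with one element per tracker: `list(id, det, mode)`
#'   where `det` is an `ellipse_detection` or `NULL` (coast) and `mode`
#'   is `"split"`, `"kmeans"` or `"coast"`.
#' @export
resolve_merge <- function(group, component, area_model, bg_model, frame, cfg) {
  k <- length(group)
  stopifnot(k >= 2L)
  ids <- vapply(group, function(t) t$id, integer(1))
  # fallback: the shared blob is still a (weakly weighted) position
  # measurement for every tracker in the group; the prediction dominates
  # but drift stays bounded to the blob scale
  blob <- if (inherits(component, "ellipse_detection")) component else NULL
  coast_all <- lapply(ids, function(id) {
    list(id = id, det = blob, mode = if (is.null(blob)) "coast" else "blob")
  })

  sub <- NULL
  mode <- "coast"
  if (!is.null(component$pixels) && nrow(component$pixels) >= 2 * cfg$min_px) {
    comp <- list(
      pixels = component$pixels, idx = component$idx,
      area = nrow(component$pixels)
    )
    # the merge phase probes a higher threshold range than segmentation:
    # two overlapping fly profiles keep a bright saddle that only a
    # substantially raised threshold can cut
    for (s in seq_len(2L * cfg$max_steps)) {
      cand <- split_candidate(
        comp, bg_model, frame, cfg$N + s * cfg$dN,
        cfg$sigma_floor, cfg$polarity, cfg$min_px, max_parts = k
      )
      if (!is.null(cand) && length(cand) >= 2L) {
        sub <- cand
        mode <- "split"
        break
      }
    }
    if (is.null(sub)) {
      speeds <- vapply(group, function(t) sqrt(sum(t$x_state[3:4]^2)), numeric(1))
      if (all(speeds < cfg$static_speed)) {
        centers <- t(vapply(group, function(t) t$last_known, numeric(2)))
        sub <- split_static_cluster(comp, centers, bg_model, frame, cfg)
        if (!is.null(sub)) mode <- "kmeans"
      }
    }
  }
  if (is.null(sub)) return(coast_all)

  # re-assign sub-elements within the group by the Gaussian score
  sdf <- detections_df(sub)
  asn <- assign_identities(group, sdf, gate = 2 * cfg$gate)
  out <- coast_all
  if (nrow(asn$pairs)) {
    for (r in seq_len(nrow(asn$pairs))) {
      i <- match(asn$pairs$tracker_id[r], ids)
      out[[i]] <- list(id = ids[i], det = sub[[asn$pairs$detection[r]]], mode = mode)
    }
  }
  out
}

# k-means on component pixels seeded at last known positions, refined
# by a few EM iterations of an isotropic Gaussian mixture
split_static_cluster <- function(comp, centers, bg_model, frame, cfg) {
  px <- comp$pixels
  if (nrow(px) <= nrow(centers)) return(NULL)
  centers <- centers + 1e-3 * seq_len(nrow(centers)) # guard identical seeds
  km <- tryCatch(
    suppressWarnings(stats::kmeans(px, centers = centers, iter.max = 20)),
    error = function(e) NULL
  )
  if (is.null(km)) return(NULL)
  mu <- km$centers
  k <- nrow(mu)
  sig2 <- rep(max(stats::var(as.numeric(px)), 1), k)
  prop <- rep(1 / k, k)
  for (iter in 1:3) { # EM refinement
    ll <- vapply(seq_len(k), function(j) {
      log(prop[j]) - log(sig2[j]) -
        ((px[, 1] - mu[j, 1])^2 + (px[, 2] - mu[j, 2])^2) / (2 * sig2[j])
    }, numeric(nrow(px)))
    ll <- matrix(ll, ncol = k)
    r <- exp(ll - apply(ll, 1, max))
    r <- r / rowSums(r)
    nk <- colSums(r)
    if (any(nk < 1)) break
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(r[, j] * px) / nk[j]
      sig2[j] <- max(sum(r[, j] * ((px[, 1] - mu[j, 1])^2 + (px[, 2] - mu[j, 2])^2)) /
        (2 * nk[j]), 0.25)
      prop[j] <- nk[j] / nrow(px)
    }
  }
  split_by_centers(comp, mu, bg_model, frame, cfg$sigma_floor)
}

#' Tracker lifecycle bookkeeping for one frame
#'
#' Applies the spawn/probation/coast/wait/retire rules after the
#' assignment has been processed: unassigned detections re-bind to a
#' waiting tracker near their position or spawn a new provisional
#' tracker; a provisional tracker that misses its fly, or contests a
#' detection owned by a mature tracker, is retired on the spot (its
#' buffered output is discarded — this is what removes short-lived
#' reflection blobs); a mature tracker missing its fly coasts on the
#' prediction for up to `max_coast` frames, then waits frozen at its
#' last known position for up to `max_wait` frames, then is retired
#' with an identity-loss event.
#'
#' @param trackers list of trackers (post-update for assigned ones).
#' @param assignment the frame's `assignment_result`.
#' @param detections the frame's detections (list of
#'   `ellipse_detection`).
#' @param frame_index 0-based frame number.
#' @param cfg a [pipeline_config()].
#' @param next_id next fresh identity to hand out.
#' @return list with updated `trackers`, `next_id` and an `events`
#'   data frame (columns `frame`, `event`, `id`).
#' @export
lifecycle_step <- function(trackers, assignment, detections, frame_index,
                           cfg = pipeline_config(), next_id = 1L) {
  events <- list()
  log_event <- function(ev, id) {
    events[[length(events) + 1L]] <<- data.frame(
      frame = frame_index, event = ev, id = id
    )
  }
  ids <- vapply(trackers, function(t) t$id, integer(1))
  merged_ids <- unlist(assignment$merged_groups, use.names = FALSE)
  mature_ids <- ids[!vapply(trackers, function(t) t$provisional, logical(1))]

  for (i in seq_along(trackers)) {
    t <- trackers[[i]]
    if (t$status == "retired") next
    t$age_frames <- t$age_frames + 1L

    if (t$id %in% assignment$pairs$tracker_id) {
      t$status <- "active"
    } else if (t$id %in% merged_ids) {
      t$status <- "merged"
      t$frames_since_seen <- 0L
      # a provisional tracker contesting a mature tracker's fly is the
      # reflection signature: retire it
      if (t$provisional) {
        grp <- Filter(function(g) t$id %in% g, assignment$merged_groups)
        others <- setdiff(unlist(grp), t$id)
        if (any(others %in% mature_ids)) {
          t$status <- "retired"
          log_event("retired_probation", t$id)
        }
      }
    } else {
      t$frames_since_seen <- t$frames_since_seen + 1L
      if (t$provisional) {
        # a short hiccup (e.g. a brief merge) is tolerated; a blob that
        # stays gone was spurious and is dropped before ever reporting
        if (t$frames_since_seen > 2L) {
          t$status <- "retired"
          log_event("retired_probation", t$id)
        } else {
          t$status <- "coasting"
        }
      } else if (t$frames_since_seen <= cfg$max_coast) {
        t$status <- "coasting"
        t$last_known <- t$x_state[1:2]
      } else if (t$frames_since_seen <= cfg$max_coast + cfg$max_wait) {
        t$status <- "waiting"
        t$x_state[1:2] <- t$last_known
        t$x_state[3:4] <- 0
        t$x_state[6] <- 0
      } else {
        t$status <- "retired"
        log_event("identity_lost", t$id)
      }
    }
    if (t$provisional && t$status != "retired" &&
      t$age_frames >= cfg$probation && t$frames_since_seen == 0L) {
      t$provisional <- FALSE
      log_event("matured", t$id)
    }
    trackers[[i]] <- t
  }

  # unassigned detections: re-bind to a waiting tracker, else spawn
  for (j in assignment$unassigned_detections) {
    det <- detections[[j]]
    waiting <- which(vapply(trackers, function(t) {
      t$status == "waiting" &&
        sqrt(sum((t$last_known - c(det$x, det$y))^2)) <= cfg$rebind_radius
    }, logical(1)))
    if (length(waiting)) {
      i <- waiting[[1L]] # nearest-first would tie-break equally well
      t <- trackers[[i]]
      t$x_state[1:2] <- c(det$x, det$y)
      t$x_state[3:4] <- 0
      t$P[1:2, 1:2] <- diag(2) * 4
      t$status <- "active"
      t$frames_since_seen <- 0L
      t <- push_history(t, det$x, det$y, det$theta, cfg$vel_window + 1L)
      t$last_known <- c(det$x, det$y)
      trackers[[i]] <- t
      log_event("rebound", t$id)
    } else {
      t <- make_tracker(next_id, det, frame_index, cfg)
      trackers[[length(trackers) + 1L]] <- t
      log_event("spawned", next_id)
      next_id <- next_id + 1L
    }
  }

  list(
    trackers = trackers,
    next_id = as.integer(next_id),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(frame = integer(0), event = character(0), id = integer(0))
  )
}
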