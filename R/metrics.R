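#' Tracking-quality metrics
#'
#' Identity errors (swaps + losses) are reported in two normalized
#' forms: per occlusion event — an interaction in which two or more
#' flies merge into a single blob — and per fly population density and
#' video duration. Both are percentages; zero errors give zero.
#'
#' @name metrics
NULL

#' Errors per occlusion event
#'
#' `100 * errors / occlusions`, the error rate per fly interaction.
#' Note that occlusion *events* (interactions) and occlusion *frames*
#' (frames containing a merged blob) are distinct counts and must not
#' be conflated.
#'
#' @param errors total identity errors (swaps + losses).
#' @param occlusions number of occlusion events (> 0).
#' @return percentage.
#' @export
error_per_occlusion <- function(errors, occlusions) {
  stopifnot(errors >= 0)
  if (occlusions <= 0) stop("undefined metric: zero occlusion events")
  100 * errors / occlusions
}

#' Errors per population density and time
#'
#' `100 * errors / (density * duration_seconds)` with the duration
#' computed from the frame count and frame rate. Normalizing by density
#' and seconds makes runs with different frame rates and arena loadings
#' comparable.
#'
#' @param errors total identity errors (swaps + losses).
#' @param density fly population density in flies/cm^2 (> 0).
#' @param n_frames video length in frames.
#' @param fps frame rate (> 0).
#' @return percentage.
#' @export
error_per_density_time <- function(errors, density, n_frames, fps) {
  stopifnot(errors >= 0, n_frames >= 0)
  if (density <= 0 || fps <= 0) stop("undefined metric: non-positive density or fps")
  t_s <- n_frames / fps
  if (t_s <= 0) stop("undefined metric: zero duration")
  100 * errors / (density * t_s)
}

#' Count occlusion frames in tracked output
#'
#' Number of frames whose assignment contains at least one merged
#' group, i.e. frames in which two or more flies share a single blob.
#'
#' @param frame_results the `frame_results` list of a `fly_tracks`
#'   object (or the object itself).
#' @return integer count, at most the number of frames.
#' @export
count_occlusion_frames <- function(frame_results) {
  if (inherits(frame_results, "fly_tracks")) frame_results <- frame_results$frame_results
  sum(vapply(frame_results, function(fr) {
    !is.null(fr) && length(fr$assignment$merged_groups) > 0L
  }, logical(1)))
}

#' Score tracked trajectories against ground truth
#'
#' Matches output tracks to ground-truth identities frame by frame
#' (Hungarian assignment on position distance, gated at
#' `match_radius`) and counts: swaps — frames at which an output
#' track's matched truth identity changes; losses — truth identities
#' left unmatched for more than `max_wait` consecutive frames; and
#' spurious — output tracks that never match any truth identity.
#'
#' @param trajectories trajectory data frame (columns `frame`,
#'   `track_id`, `x_px`, `y_px`) or a `fly_tracks` object.
#' @param ground_truth data frame with columns `frame`, `id`, `x`, `y`.
#' @param match_radius maximum matching distance in px; default 10.
#' @param max_wait frames of absence tolerated before a truth identity
#'   counts as lost; default 450.
#' @param min_persist a re-match must persist this many frames to count
#'   as a swap; shorter flicker-and-revert runs during an overlap are
#'   matching ambiguity (the merged flies are closer together than the
#'   matching can discriminate), not identity errors. Default 3.
#' @return list with `swaps`, `losses`, `spurious` and the per-frame
#'   `matches` table.
#' @export
score_against_truth <- function(trajectories, ground_truth, match_radius = 10,
                                max_wait = 450, min_persist = 3) {
  if (inherits(trajectories, "fly_tracks")) trajectories <- trajectories$trajectories
  if (is.null(ground_truth) || nrow(ground_truth) == 0L) stop("empty ground truth")
  frames <- intersect(unique(trajectories$frame), unique(ground_truth$frame))
  frames <- sort(frames)
  matches <- list()
  prev <- NULL # track_id -> truth_id of the previous frame
  for (f in frames) {
    out <- trajectories[trajectories$frame == f, ]
    tru <- ground_truth[ground_truth$frame == f, ]
    if (!nrow(out) || !nrow(tru)) next
    D <- outer(seq_len(nrow(out)), seq_len(nrow(tru)), function(i, j) {
      sqrt((out$x_px[i] - tru$x[j])^2 + (out$y_px[i] - tru$y[j])^2)
    })
    BIG <- 1e6
    C <- ifelse(D <= match_radius, D, BIG)
    # stability tie-break: when two truth flies (nearly) coincide the
    # assignment is ill-defined, so keeping the previous correspondence
    # costs 1 px less; genuine exchanges differ by far more
    if (!is.null(prev)) {
      for (i in seq_len(nrow(out))) {
        pj <- prev[[as.character(out$track_id[i])]]
        if (!is.null(pj)) {
          j <- match(pj, tru$id)
          if (!is.na(j) && C[i, j] < BIG) C[i, j] <- C[i, j] - 1
        }
      }
    }
    n <- max(dim(C))
    Cp <- matrix(BIG, n, n)
    Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
    Cp <- Cp + 1 # keep entries non-negative after the tie-break bonus
    sol <- as.integer(clue::solve_LSAP(Cp))
    cur <- list()
    for (i in seq_len(nrow(out))) {
      j <- sol[i]
      if (j <= nrow(tru) && D[i, j] <= match_radius) {
        matches[[length(matches) + 1L]] <- data.frame(
          frame = f, track_id = out$track_id[i], truth_id = tru$id[j]
        )
        cur[[as.character(out$track_id[i])]] <- tru$id[j]
      }
    }
    prev <- cur
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(frame = integer(0), track_id = integer(0), truth_id = integer(0))

  swaps <- 0L
  for (id in unique(trajectories$track_id)) {
    m <- matches[matches$track_id == id, ]
    if (nrow(m) < 2L) next
    m <- m[order(m$frame), ]
    r <- rle(as.character(m$truth_id))
    # collapse A-B-A flickers shorter than min_persist
    repeat {
      k <- length(r$values)
      cand <- which(r$lengths < min_persist)
      cand <- cand[cand > 1L & cand < k & r$values[cand - 1L] == r$values[cand + 1L]]
      if (!length(cand)) break
      i <- cand[1L]
      r$lengths[i - 1L] <- r$lengths[i - 1L] + r$lengths[i] + r$lengths[i + 1L]
      r$values <- r$values[-c(i, i + 1L)]
      r$lengths <- r$lengths[-c(i, i + 1L)]
    }
    # a boundary run below the persistence floor is not an established
    # correspondence either
    while (length(r$values) > 1L && r$lengths[1L] < min_persist) {
      r$values <- r$values[-1L]; r$lengths <- r$lengths[-1L]
    }
    while (length(r$values) > 1L && r$lengths[length(r$values)] < min_persist) {
      r$values <- r$values[-length(r$values)]
      r$lengths <- r$lengths[-length(r$lengths)]
    }
    swaps <- swaps + length(r$values) - 1L
  }

  losses <- 0L
  for (tid in unique(ground_truth$id)) {
    tf <- sort(unique(ground_truth$frame[ground_truth$id == tid]))
    mf <- sort(unique(matches$frame[matches$truth_id == tid]))
    present <- tf %in% mf
    if (!any(present)) {
      losses <- losses + 1L
      next
    }
    # longest trailing or internal run of absence after first match
    first <- which(present)[1L]
    runs <- rle(present[first:length(present)])
    gaps <- runs$lengths[!runs$values]
    if (length(gaps) && max(gaps) > max_wait) losses <- losses + 1L
  }

  spurious <- sum(!unique(trajectories$track_id) %in% unique(matches$track_id))

  list(swaps = swaps, losses = losses, spurious = spurious, matches = matches)
}
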