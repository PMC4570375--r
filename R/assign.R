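#' Gaussian assignment score
#'
#' Probability density that a detection at `(x, y)` is the fly whose
#' position the Kalman filter predicted at `(mu_x, mu_y)` with
#' prediction errors `(sigma_x, sigma_y)`:
#' `(1 / (2 pi sx sy)) exp(-((x-mx)/sx)^2/2 - ((y-my)/sy)^2/2)`.
#'
#' @param mu_x,mu_y predicted position (px).
#' @param sigma_x,sigma_y positive prediction standard errors (px).
#' @param x,y detection position (px).
#' @return density value (vectorized over detections).
#' @export
assignment_cost <- function(mu_x, mu_y, sigma_x, sigma_y, x, y) {
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) stop("sigma_x and sigma_y must be positive")
  1 / (2 * pi * sigma_x * sigma_y) *
    exp(-0.5 * ((x - mu_x) / sigma_x)^2 - 0.5 * ((y - mu_y) / sigma_y)^2)
}

#' Assign detections to trackers
#'
#' Builds the tracker-by-detection score matrix from
#' [assignment_cost()] (prediction errors taken from each tracker's
#' predicted covariance diagonal) and solves the assignment with the
#' Hungarian algorithm, maximizing the total score via minimization of
#' negative log scores on a square-padded matrix. Pairs whose position
#' Mahalanobis distance exceeds `gate` are inadmissible. A tracker with
#' no admissible detection of its own whose best admissible detection is
#' claimed by (or contested with) other trackers joins that detection's
#' merged group — the situation where several flies have merged into
#' one blob. On equal scores the lower tracker id keeps its incumbent
#' detection (stability bias).
#'
#' @param trackers list of trackers (after prediction).
#' @param detections data frame with columns `x`, `y`.
#' @param gate gating radius in Mahalanobis units; default 4.
#' @return an `assignment_result`: list with `pairs` (data frame
#'   `tracker_id`, `detection`), `unassigned_trackers` (ids),
#'   `unassigned_detections` (row indices) and `merged_groups` (named
#'   list: detection index -> tracker ids).
#' @export
assign_identities <- function(trackers, detections, gate = 4) {
  nt <- length(trackers)
  nd <- if (is.null(detections)) 0L else nrow(detections)
  empty <- list(
    pairs = data.frame(tracker_id = integer(0), detection = integer(0)),
    unassigned_trackers = vapply(trackers, function(t) t$id, integer(1)),
    unassigned_detections = seq_len(nd),
    merged_groups = list()
  )
  class(empty) <- "assignment_result"
  if (nt == 0L || nd == 0L) return(empty)

  ids <- vapply(trackers, function(t) t$id, integer(1))
  S <- matrix(0, nt, nd)
  G <- matrix(FALSE, nt, nd)
  for (i in seq_len(nt)) {
    t <- trackers[[i]]
    p <- t$x_state[1:2]
    sx <- sqrt(max(t$P[1, 1], 1e-6))
    sy <- sqrt(max(t$P[2, 2], 1e-6))
    S[i, ] <- assignment_cost(p[1], p[2], sx, sy, detections$x, detections$y)
    # gating accounts for the detection's own extent: a large merged
    # blob localizes the flies inside it only to its scale, so its
    # center may sit well off any one member's prediction
    ext <- if (!is.null(detections$a)) detections$a / 2 else 0
    gx <- sqrt(sx^2 + ext^2)
    gy <- sqrt(sy^2 + ext^2)
    dx <- (detections$x - p[1]) / gx
    dy <- (detections$y - p[2]) / gy
    G[i, ] <- sqrt(dx^2 + dy^2) <= gate
    # waiting trackers sit at a stale last-known position: they take no
    # part in the assignment and re-acquire only through re-binding
    if (identical(t$status, "waiting")) G[i, ] <- FALSE
  }

  BIG <- 1e8
  cost <- -log(pmax(S, 1e-300))
  cost[!G] <- BIG
  # stability bias: a tracker re-claiming its incumbent detection wins ties
  for (i in seq_len(nt)) {
    li <- trackers[[i]]$last_detection
    if (!is.null(li) && length(li) == 1L && !is.na(li) && li >= 1 && li <= nd) {
      cost[i, li] <- cost[i, li] - 1e-9 * (1 + 1 / ids[i])
    }
  }
  n <- max(nt, nd)
  Cpad <- matrix(BIG, n, n)
  Cpad[seq_len(nt), seq_len(nd)] <- cost
  Cpad <- Cpad - min(Cpad) # solve_LSAP needs non-negative entries
  sol <- as.integer(clue::solve_LSAP(Cpad))

  pair_t <- integer(0); pair_d <- integer(0)
  un_t <- integer(0)
  contested <- integer(0) # per tracker: best gated detection when unpaired
  for (i in seq_len(nt)) {
    j <- sol[i]
    if (j <= nd && G[i, j]) {
      pair_t <- c(pair_t, i); pair_d <- c(pair_d, j)
    } else if (any(G[i, ])) {
      contested[length(contested) + 1L] <- i
      names(contested)[length(contested)] <- which.max(ifelse(G[i, ], S[i, ], -Inf))
    } else {
      un_t <- c(un_t, i)
    }
  }

  merged <- list()
  if (length(contested)) {
    for (k in seq_along(contested)) {
      d <- as.integer(names(contested)[k])
      i <- contested[k]
      key <- as.character(d)
      merged[[key]] <- c(merged[[key]], ids[i])
    }
    # pull the winning tracker of each contested detection into the group
    for (key in names(merged)) {
      d <- as.integer(key)
      hit <- which(pair_d == d)
      if (length(hit)) {
        merged[[key]] <- sort(unique(c(merged[[key]], ids[pair_t[hit]])))
        pair_t <- pair_t[-hit]; pair_d <- pair_d[-hit]
      } else {
        merged[[key]] <- sort(unique(merged[[key]]))
      }
    }
    # a "group" of one tracker on an unclaimed detection is a plain pair
    singles <- names(merged)[vapply(merged, length, integer(1)) == 1L]
    for (key in singles) {
      i <- match(merged[[key]], ids)
      pair_t <- c(pair_t, i); pair_d <- c(pair_d, as.integer(key))
      merged[[key]] <- NULL
    }
  }

  used_d <- c(pair_d, as.integer(names(merged)))
  res <- list(
    pairs = data.frame(tracker_id = ids[pair_t], detection = pair_d),
    unassigned_trackers = ids[un_t],
    unassigned_detections = setdiff(seq_len(nd), used_d),
    merged_groups = merged
  )
  class(res) <- "assignment_result"
  res
}
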