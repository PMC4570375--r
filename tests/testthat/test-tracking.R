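test_that("lifecycle spawns, matures, coasts, waits and retires", {
  cfg <- pipeline_config(probation = 3L, max_coast = 2L, max_wait = 4L)
  det <- list(structure(
    list(x = 10, y = 10, theta = 0, a = 6, b = 3, area = pi * 18,
         weight_sum = 1, likelihood = 1, n_px = 10),
    class = "ellipse_detection"
  ))
  empty_asn <- assign_identities(list(), data.frame(x = 10, y = 10))

  lc <- lifecycle_step(list(), empty_asn, det, 0L, cfg, next_id = 1L)
  expect_length(lc$trackers, 1L)
  expect_true(lc$trackers[[1]]$provisional)
  expect_equal(lc$next_id, 2L)
  expect_equal(lc$events$event, "spawned")

  # keep feeding the fly: the tracker matures after probation
  t <- lc$trackers
  for (f in 1:4) {
    asn <- assign_identities(t, data.frame(x = 10, y = 10))
    t[[1]] <- kalman_predict(t[[1]], 1)
    lc <- lifecycle_step(t, asn, det, f, cfg, 2L)
    t <- lc$trackers
  }
  expect_false(t[[1]]$provisional)
  expect_equal(t[[1]]$status, "active")

  # fly vanishes: coasting, then waiting, then retirement with a loss
  none <- assign_identities(t, data.frame(x = numeric(0), y = numeric(0)))
  statuses <- character(0)
  events <- character(0)
  for (f in 5:12) {
    lc <- lifecycle_step(t, none, list(), f, cfg, 2L)
    t <- lc$trackers
    statuses <- c(statuses, t[[1]]$status)
    events <- c(events, lc$events$event)
  }
  expect_equal(statuses[1:2], c("coasting", "coasting"))
  expect_true("waiting" %in% statuses)
  expect_equal(statuses[length(statuses)], "retired")
  expect_true("identity_lost" %in% events)
})

test_that("a provisional tracker that loses its blob is removed silently", {
  cfg <- pipeline_config(probation = 50L)
  det <- list(structure(
    list(x = 5, y = 5, theta = 0, a = 6, b = 3, area = pi * 18,
         weight_sum = 1, likelihood = 1, n_px = 10),
    class = "ellipse_detection"
  ))
  lc <- lifecycle_step(list(), assign_identities(list(), data.frame(x = 5, y = 5)),
    det, 0L, cfg, 1L
  )
  t <- lc$trackers
  # the blob vanishes for good: a short grace, then silent removal
  none <- assign_identities(t, data.frame(x = numeric(0), y = numeric(0)))
  events <- character(0)
  for (f in 1:4) {
    lc2 <- lifecycle_step(t, none, list(), f, cfg, 2L)
    t <- lc2$trackers
    events <- c(events, lc2$events$event)
  }
  expect_equal(t[[1]]$status, "retired")
  expect_true("retired_probation" %in% events)
})

test_that("a waiting tracker re-binds to a nearby reappearing fly", {
  cfg <- pipeline_config(probation = 1L, max_coast = 1L, max_wait = 100L,
    rebind_radius = 15
  )
  det_at <- function(x, y) list(structure(
    list(x = x, y = y, theta = 0, a = 6, b = 3, area = pi * 18,
         weight_sum = 1, likelihood = 1, n_px = 10),
    class = "ellipse_detection"
  ))
  t <- make_tracker(1L, det_at(20, 20)[[1]], 0L, cfg)
  t$provisional <- FALSE
  t$status <- "waiting"
  t$frames_since_seen <- 10L
  t$age_frames <- 60L
  t$last_known <- c(20, 20)
  asn <- assign_identities(list(t), data.frame(x = 24, y = 21))
  # waiting trackers do not enter the assignment; the detection is free
  expect_equal(asn$unassigned_detections, 1L)
  lc <- lifecycle_step(list(t), asn, det_at(24, 21), 11L, cfg, 2L)
  expect_equal(lc$trackers[[1]]$status, "active")
  expect_equal(lc$events$event, "rebound")
  expect_equal(lc$next_id, 2L) # no new identity was minted
})

test_that("merged blobs resolve by raised-threshold split with correct identities", {
  empty <- data.frame(
    frame = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
    theta = numeric(0), vx = numeric(0), vy = numeric(0), w = numeric(0)
  )
  mk <- function(seed) small_scene(seed, noise_sd = 1)
  bgf <- lapply(1:11, function(i) preprocess_frame(render_frame(empty, mk(300 + i), 0), 1))
  bm <- fit_background(bgf)
  t2 <- data.frame(
    frame = 0L, id = 1:2, x = c(53.5, 66.5), y = 60, theta = 0,
    vx = 0, vy = 0, w = 0
  )
  fr <- preprocess_frame(render_frame(t2, mk(55), 0), 1)
  cps <- connected_components(subtract_background(bm, fr, 10))
  expect_length(cps, 1L)
  comp <- flytrackr:::fit_component_ellipse(cps[[1]], bm, fr, 1)
  am <- fit_area_model(pi * 5.4 * 3.1 * c(0.95, 1, 1.05))
  cfg <- pipeline_config()
  g1 <- make_tracker(1L, list(x = 54, y = 60, theta = 0, a = 5.4, b = 3.1), 0L, cfg)
  g2 <- make_tracker(2L, list(x = 66, y = 60, theta = 0, a = 5.4, b = 3.1), 0L, cfg)
  out <- resolve_merge(list(g1, g2), comp, am, bm, fr, cfg)
  expect_setequal(vapply(out, function(o) o$mode, character(1)), "split")
  x1 <- out[[which(vapply(out, function(o) o$id, integer(1)) == 1L)]]$det$x
  x2 <- out[[which(vapply(out, function(o) o$id, integer(1)) == 2L)]]$det$x
  expect_lt(abs(x1 - 53.5), 2)
  expect_lt(abs(x2 - 66.5), 2)
  # never more sub-elements than requesting trackers plus one
  expect_lte(length(out), 2L + 1L)
})

test_that("a static unsplittable cluster resolves by seeded k-means", {
  # two flies so close their profiles fuse into one unsplittable blob
  empty <- data.frame(
    frame = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
    theta = numeric(0), vx = numeric(0), vy = numeric(0), w = numeric(0)
  )
  mk <- function(seed) small_scene(seed, noise_sd = 1)
  bgf <- lapply(1:11, function(i) preprocess_frame(render_frame(empty, mk(300 + i), 0), 1))
  bm <- fit_background(bgf)
  t2 <- data.frame(
    frame = 0L, id = 1:2, x = c(57, 63), y = 60, theta = 0,
    vx = 0, vy = 0, w = 0
  )
  fr <- preprocess_frame(render_frame(t2, mk(56), 0), 1)
  cps <- connected_components(subtract_background(bm, fr, 10))
  expect_length(cps, 1L)
  comp <- flytrackr:::fit_component_ellipse(cps[[1]], bm, fr, 1)
  am <- fit_area_model(pi * 5.4 * 3.1 * c(0.95, 1, 1.05))
  cfg <- pipeline_config()
  g1 <- make_tracker(1L, list(x = 57, y = 60, theta = 0, a = 5.4, b = 3.1), 0L, cfg)
  g2 <- make_tracker(2L, list(x = 63, y = 60, theta = 0, a = 5.4, b = 3.1), 0L, cfg)
  # both static (zero velocities): the k-means/EM path engages
  out <- resolve_merge(list(g1, g2), comp, am, bm, fr, cfg)
  modes <- vapply(out, function(o) o$mode, character(1))
  expect_true(all(modes %in% c("kmeans", "split")))
  xs <- sort(vapply(out, function(o) o$det$x, numeric(1)))
  expect_lt(abs(xs[1] - 57), 3)
  expect_lt(abs(xs[2] - 63), 3)
})

test_that("identities persist with zero swaps on non-interacting flies", {
  sc <- quiet_scenario()
  expect_equal(nrow(attr(sc$truth, "overlaps")), 0L) # premise: no interactions
  res <- sc$result
  expect_equal(length(unique(res$trajectories$track_id)), 4L)
  s <- score_against_truth(res, sc$truth)
  expect_equal(s$swaps, 0L)
  expect_equal(s$losses, 0L)
  expect_equal(s$spurious, 0L)
  # ids never reused and ages grow monotonically
  expect_true(all(table(res$trajectories$frame) == 4L))
})

test_that("stored orientations never jump by more than pi between frames", {
  sc <- quiet_scenario()
  tr <- sc$result$trajectories
  for (id in unique(tr$track_id)) {
    th <- tr$theta_rad[tr$track_id == id]
    d <- abs(atan2(sin(diff(th)), cos(diff(th))))
    expect_lt(max(d), pi)
  }
})

test_that("an empty arena yields no trackers and an empty table", {
  cfg <- small_scene(21, n_flies = 0)
  sq <- synthetic_sequence(cfg, 30)
  res <- track_sequence(
    sq$frames, pipeline_config(warmup_frames = 10, plate_detect = FALSE),
    n_frames = 30
  )
  expect_equal(nrow(res$trajectories), 0L)
  expect_equal(count_occlusion_frames(res), 0L)
})
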