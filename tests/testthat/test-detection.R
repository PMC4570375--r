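test_that("connected components are 8-connected and deterministically ordered", {
  expect_identical(connected_components(matrix(FALSE, 5, 5)), list())

  # diagonal-only touch joins under 8-connectivity
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_length(connected_components(m), 1L)

  # brute-force flood-fill oracle on random masks
  flood_count <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask)); k <- 0L
    for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
      if (mask[r, c] && lab[r, c] == 0L) {
        k <- k + 1L
        stack <- list(c(r, c)); lab[r, c] <- k
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            rr <- p[1] + dr; cc <- p[2] + dc
            if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
              lab[rr, cc] <- k
              stack[[length(stack) + 1L]] <- c(rr, cc)
            }
          }
        }
      }
    }
    k
  }
  set.seed(501)
  for (i in 1:20) {
    mask <- matrix(runif(15 * 15) < 0.3, 15, 15)
    expect_equal(length(connected_components(mask)), flood_count(mask))
  }

  # ordering by (min row, min col)
  m2 <- matrix(FALSE, 10, 10)
  m2[7:8, 2:3] <- TRUE # lower-left
  m2[2:3, 7:8] <- TRUE # upper-right: first by min row
  cps <- connected_components(m2)
  expect_equal(min(cps[[1]]$pixels[, "y"]), 1) # 0-based row 1
  expect_equal(min(cps[[2]]$pixels[, "y"]), 6)
})

test_that("area model implements the population mean and variance", {
  m <- fit_area_model(c(10, 10, 10))
  expect_equal(m$mu_areas, 10)
  expect_equal(m$sigma_areas, 0)

  m <- fit_area_model(c(8, 10, 12))
  expect_equal(m$mu_areas, 10)
  expect_equal(m$sigma_areas^2, 8 / 3, tolerance = 1e-12)

  # two-pass population-variance oracle on random inputs
  set.seed(502)
  for (i in 1:10) {
    a <- runif(sample(2:40, 1), 5, 200)
    m <- fit_area_model(a)
    expect_equal(m$sigma_areas^2, mean((a - mean(a))^2), tolerance = 1e-9)
  }
  expect_error(fit_area_model(numeric(0)), "at least one")
  expect_equal(fit_area_model(1)$c_clean, 15) # documented default
})

test_that("area filter removes only sub-threshold components", {
  comp <- function(n) list(pixels = cbind(x = seq_len(n), y = 1), area = n)
  m <- fit_area_model(rep(50, 4)) # sigma = 0: sharp threshold at mu
  kept <- area_filter(list(comp(49), comp(50), comp(51)), m)
  expect_equal(vapply(kept, function(cp) cp$area, numeric(1)), 51)
  # with wide sigma the threshold drops to the 1 px^2 floor
  m2 <- fit_area_model(c(10, 90))
  expect_length(area_filter(list(comp(2), comp(1)), m2), 1L)
})

test_that("weighted-covariance ellipse fit matches hand computations", {
  e <- fit_ellipse(cbind(3, 7))
  expect_equal(c(e$x, e$y, e$a, e$b, e$theta), c(3, 7, 0, 0, 0))

  # three collinear pixels, equal weights
  e <- fit_ellipse(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(e$x, 1)
  expect_equal(e$a, 2 * sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(e$b, 0)
  expect_equal(e$theta, 0)

  expect_error(fit_ellipse(cbind(c(0, 1), c(0, 0)), c(0, 0)), "degenerate")
  expect_error(fit_ellipse(matrix(numeric(0), ncol = 2)), "at least one")
})

test_that("ellipse fit recovers rendered Gaussian blob parameters", {
  blob <- gaussian_blob_pixels(40.3, 52.7, pi / 6, a = 12, b = 5)
  e <- fit_ellipse(blob$pixels, blob$weights)
  expect_equal(e$x, 40.3, tolerance = 0.05)
  expect_equal(e$y, 52.7, tolerance = 0.05)
  expect_equal(e$a, 12, tolerance = 12 * 0.05)
  expect_equal(e$b, 5, tolerance = 5 * 0.05)
  expect_lt(abs(atan2(sin(e$theta - pi / 6), cos(e$theta - pi / 6))), 0.02)
})

test_that("ellipse fit is rotation-equivariant about the centroid", {
  blob <- gaussian_blob_pixels(0, 0, 0, a = 10, b = 4)
  e0 <- fit_ellipse(blob$pixels, blob$weights)
  for (phi in c(0.4, 1.1, 2.0)) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    rot <- blob$pixels %*% t(R)
    e1 <- fit_ellipse(rot, blob$weights)
    expect_equal(e1$a, e0$a, tolerance = 0.01 * e0$a)
    expect_equal(e1$b, e0$b, tolerance = 0.01 * e0$b)
    dtheta <- (e1$theta - e0$theta - phi) %% pi
    expect_lt(min(dtheta, pi - dtheta), 0.02)
  }
  # covariance is symmetric PSD and a >= b by construction
  set.seed(503)
  for (i in 1:20) {
    px <- matrix(rnorm(40), ncol = 2)
    e <- fit_ellipse(px, runif(20))
    expect_gte(e$a, e$b)
    expect_gte(e$b, 0)
  }
})

test_that("area likelihood follows the Laplace form around the shape model", {
  m <- fit_area_model(c(45, 50, 55))
  e <- list(a = m$mu_areas / pi, b = 1) # pi a b equals mu exactly
  expect_equal(ellipse_likelihood(e, m), 1)
  e2 <- list(a = (m$mu_areas + m$sigma_areas) / pi, b = 1)
  expect_equal(ellipse_likelihood(e2, m), exp(-1), tolerance = 1e-9)
  # strictly decreasing in |area - mu|
  areas <- m$mu_areas + seq(0, 30, 5)
  p <- vapply(areas, function(a) ellipse_likelihood(list(a = a / pi, b = 1), m), numeric(1))
  expect_true(all(diff(p) < 0))
  m0 <- fit_area_model(c(50, 50))
  expect_warning(p0 <- ellipse_likelihood(list(a = 49 / pi, b = 1), m0), "zero")
  expect_equal(p0, 0)
})

test_that("plate detection finds the disk and degrades gracefully", {
  # rendered disk of known geometry
  m <- matrix(20, 240, 320)
  xg <- matrix(rep(0:319, each = 240), 240)
  yg <- matrix(rep(0:239, 320), 240)
  m[(xg - 160)^2 + (yg - 120)^2 <= 100^2] <- 230
  roi <- detect_plate(m)
  expect_true(roi$enabled)
  expect_lt(abs(roi$center_x - 160), 2)
  expect_lt(abs(roi$center_y - 120), 2)
  expect_lt(abs(roi$radius - 100), 2)

  expect_warning(roi2 <- detect_plate(matrix(128, 100, 100)), "failed")
  expect_false(roi2$enabled)

  # two concentric circles: deterministic pick, reproducible
  m2 <- m
  m2[(xg - 160)^2 + (yg - 120)^2 <= 50^2] <- 20
  r1 <- detect_plate(m2)
  r2 <- detect_plate(m2)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(abs(r1$radius - 100) < 3 || abs(r1$radius - 50) < 3)
})

test_that("reflection masking removes only band-contained detections", {
  roi <- plate_roi(100, 100, 80, reflection_band_px = 12)
  det <- data.frame(
    x = c(100, 100 + 74, 100 + 62),
    y = c(100, 100, 100),
    a = c(5, 5, 12) # center; fully in band (74-5 > 68); straddling (62-12 < 68)
  )
  kept <- mask_reflections(det, roi)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$x %in% c(100, 162)))
  # disabled ROI is a no-op
  roi_off <- plate_roi(0, 0, 1, enabled = FALSE)
  expect_equal(nrow(mask_reflections(det, roi_off)), 3)
})

test_that("validation splits a merged two-fly blob and respects the floor", {
  empty <- data.frame(
    frame = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
    theta = numeric(0), vx = numeric(0), vy = numeric(0), w = numeric(0)
  )
  mk <- function(seed) small_scene(seed, noise_sd = 1)
  bgf <- lapply(1:11, function(i) preprocess_frame(render_frame(empty, mk(300 + i), 0), 1))
  bm <- fit_background(bgf)

  # single-fly area model
  t1 <- data.frame(frame = 0L, id = 1L, x = 53, y = 60, theta = 0, vx = 0, vy = 0, w = 0)
  fr1 <- preprocess_frame(render_frame(t1, mk(66), 0), 1)
  cps1 <- connected_components(subtract_background(bm, fr1, 10))
  e1 <- flytrackr:::fit_component_ellipse(cps1[[1]], bm, fr1, 1)
  am <- fit_area_model(pi * e1$a * e1$b * c(0.95, 1, 1.05, 0.98, 1.02))

  # a typical single fly passes through unchanged
  d1 <- validate_detections(cps1, am, bm, fr1)
  expect_length(d1, 1L)
  expect_gte(d1[[1]]$likelihood, exp(-3))

  # two flies 13 px apart merge into one blob at the base threshold and
  # are split into two ellipses, each within the 2-sigma area band
  t2 <- data.frame(
    frame = 0L, id = 1:2, x = c(53.5, 66.5), y = 60, theta = 0,
    vx = 0, vy = 0, w = 0
  )
  fr2 <- preprocess_frame(render_frame(t2, mk(55), 0), 1)
  cps2 <- connected_components(subtract_background(bm, fr2, 10))
  expect_length(cps2, 1L) # genuinely merged
  d2 <- validate_detections(cps2, am, bm, fr2)
  expect_length(d2, 2L)
  sig <- max(am$sigma_areas, 0.05 * am$mu_areas)
  for (e in d2) {
    expect_lt(abs(pi * e$a * e$b - am$mu_areas), 2 * sig)
  }
  expect_equal(sort(vapply(d2, function(e) e$x, numeric(1))), c(53.5, 66.5),
    tolerance = 0.1
  )

  # raising the local threshold shrinks the measured area
  areas <- vapply(c(10, 15, 20), function(N) {
    sum(subtract_background(bm, fr2, N)$mask)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})
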