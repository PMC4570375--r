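#' Plate region of interest
#'
#' @param center_x,center_y circle center in pixels (0-based).
#' @param radius circle radius in pixels.
#' @param enabled when `FALSE` the ROI covers the whole frame and the
#'   reflection mask is a no-op.
#' @param reflection_band_px width of the boundary band inside which
#'   wholly-contained detections are treated as reflections.
#' @return object of class `plate_roi`.
#' @export
plate_roi <- function(center_x, center_y, radius, enabled = TRUE,
                      reflection_band_px = 12) {
  if (enabled && radius <= 0) stop("radius must be positive for an enabled ROI")
  structure(
    list(
      center_x = center_x, center_y = center_y, radius = radius,
      enabled = enabled, reflection_band_px = reflection_band_px
    ),
    class = "plate_roi"
  )
}

disabled_roi <- function(frame, reflection_band_px = 12) {
  plate_roi(
    center_x = (ncol(frame) - 1) / 2, center_y = (nrow(frame) - 1) / 2,
    radius = max(dim(frame)), enabled = FALSE,
    reflection_band_px = reflection_band_px
  )
}

#' @export
print.plate_roi <- function(x, ...) {
  if (x$enabled) {
    cat(sprintf(
      "Plate ROI: center (%.1f, %.1f), radius %.1f px, band %g px\n",
      x$center_x, x$center_y, x$radius, x$reflection_band_px
    ))
  } else {
    cat("Plate ROI: disabled (full frame)\n")
  }
  invisible(x)
}

#' Detect the circular plate
#'
#' Edge detection (Gaussian blur + Sobel gradient, thresholded at a high
#' magnitude quantile) followed by a circle Hough transform: each edge
#' pixel votes for circle centers along its gradient direction at every
#' candidate radius. The strongest accumulator cell wins; ties break
#' toward the higher vote count, then the smaller radius. When no circle
#' gathers enough support (a blank or cluttered frame) the function
#' degrades to a disabled full-frame ROI with a warning rather than
#' failing.
#'
#' @param frame intensity matrix.
#' @param r_min,r_max radius search band in pixels; defaults to
#'   20--49 percent of the smaller frame dimension.
#' @param r_step radius step of the coarse search.
#' @param blur_sigma edge-detection blur, px.
#' @param edge_quantile gradient-magnitude quantile kept as edges.
#' @param min_vote_frac minimum fraction of the circle circumference
#'   that must vote for a detection to be accepted.
#' @param reflection_band_px stored on the returned ROI.
#' @return a `plate_roi`.
#' @export
detect_plate <- function(frame, r_min = NULL, r_max = NULL, r_step = 2,
                         blur_sigma = 2, edge_quantile = 0.98,
                         min_vote_frac = 0.1, reflection_band_px = 12) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(r_min)) r_min <- max(8L, round(0.2 * min(h, w)))
  if (is.null(r_max)) r_max <- floor(0.49 * min(h, w))
  if (r_max <= r_min) r_max <- r_min + 1L

  g <- preprocess_frame(frame, blur_sigma)
  # Sobel gradients (x = columns, y = rows)
  gx <- shift_mat(g, 0, -1) - shift_mat(g, 0, 1)
  gy <- shift_mat(g, -1, 0) - shift_mat(g, 1, 0)
  mag <- sqrt(gx^2 + gy^2)
  pos <- mag[mag > 0]
  if (length(pos) < 10L) {
    warning("plate detection failed: no edges found; returning full-frame ROI")
    return(disabled_roi(frame, reflection_band_px))
  }
  thr <- stats::quantile(pos, edge_quantile)
  edge <- which(mag >= thr & mag > 1e-6)
  if (length(edge) < 20L) {
    warning("plate detection failed: too few edge pixels; returning full-frame ROI")
    return(disabled_roi(frame, reflection_band_px))
  }
  er <- ((edge - 1L) %% h) + 1L
  ec <- ((edge - 1L) %/% h) + 1L
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]

  radii <- seq(r_min, r_max, by = r_step)
  best <- list(votes = -1, r = NA, row = NA, col = NA)
  for (r in radii) {
    # vote both along and against the gradient (polarity-agnostic)
    cr <- c(er - r * uy, er + r * uy)
    cc <- c(ec - r * ux, ec + r * ux)
    keep <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
    if (!any(keep)) next
    cells <- (round(cc[keep]) - 1L) * h + round(cr[keep])
    tab <- matrix(tabulate(cells, nbins = h * w), h, w)
    # 3x3 box sum absorbs quantization spread of the votes
    acc <- tab + shift_mat(tab, 1, 0) + shift_mat(tab, -1, 0)
    acc <- acc + shift_mat(acc, 0, 1) + shift_mat(acc, 0, -1)
    v <- max(acc)
    if (v > best$votes) {
      cell <- which.max(acc) # ties: smallest linear index, deterministic
      best <- list(
        votes = v, r = r,
        row = ((cell - 1L) %% h) + 1L,
        col = ((cell - 1L) %/% h) + 1L
      )
    }
  }
  if (!is.finite(best$votes) || best$votes < min_vote_frac * 2 * pi * best$r) {
    warning("plate detection failed: insufficient circle support; returning full-frame ROI")
    return(disabled_roi(frame, reflection_band_px))
  }
  # refine the center as the centroid of votes in a 3x3 neighbourhood is
  # overkill at 2 px accuracy; refine the radius on a unit grid instead
  fine <- seq(max(r_min, best$r - r_step), min(r_max, best$r + r_step), by = 1)
  d <- sqrt((ec - best$col)^2 + (er - best$row)^2)
  support <- vapply(fine, function(r) sum(abs(d - r) <= 1), numeric(1))
  r_best <- fine[which.max(support)]
  plate_roi(
    center_x = best$col - 1, center_y = best$row - 1, radius = r_best,
    enabled = TRUE, reflection_band_px = reflection_band_px
  )
}

# shift a matrix by (dr, dc), zero-padding; used for Sobel differences
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Remove boundary-reflection detections
#'
#' Specular reflections at the plate wall produce fly-like blobs in a
#' narrow band at the boundary. Detections whose ellipse lies entirely
#' within that band (or outside the plate) are removed; a detection
#' straddling the band edge is kept. No-op when the ROI is disabled.
#'
#' @param detections data frame of detections (columns `x`, `y`, `a`).
#' @param roi a `plate_roi`.
#' @return filtered detections data frame.
#' @export
mask_reflections <- function(detections, roi) {
  if (!inherits(roi, "plate_roi")) stop("roi must be a plate_roi")
  if (!roi$enabled || nrow(detections) == 0L) return(detections)
  d <- sqrt((detections$x - roi$center_x)^2 + (detections$y - roi$center_y)^2)
  inner <- d - detections$a # closest approach of the ellipse to the center
  keep <- inner < roi$radius - roi$reflection_band_px
  detections[keep, , drop = FALSE]
}
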