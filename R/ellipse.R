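#' Weighted-covariance ellipse fit
#'
#' Fits an oriented ellipse to a set of pixels by eigendecomposition of
#' the weighted covariance matrix. Weights are typically the normalized
#' background deviations `|I - mu| / sigma`, so that a fly's dark core
#' dominates the fit; the weighting is what lets merged blobs be split
#' when the threshold is raised. The half axes are `a = 2 sqrt(l1)`,
#' `b = 2 sqrt(l2)` with `l1 >= l2` the eigenvalues, and the
#' orientation is the direction of the leading eigenvector, stored in
#' (-pi, pi\] (axis orientation, defined modulo pi).
#'
#' @param pixels n x 2 matrix of pixel coordinates (columns x, y).
#' @param weights non-negative per-pixel weights, not all zero.
#' @return object of class `ellipse_detection`: a list with `x`, `y`,
#'   `theta`, `a`, `b`, `area` (= pi a b), `weight_sum` and
#'   `likelihood` (NA until scored).
#' @export
fit_ellipse <- function(pixels, weights = NULL) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  n <- nrow(pixels)
  if (n < 1L) stop("at least one pixel is required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weights")
  Z <- sum(weights)
  if (Z <= 0) stop("degenerate input: all weights are zero")
  ctr <- colSums(pixels * weights) / Z
  d <- sweep(pixels, 2, ctr)
  S <- crossprod(d * weights, d) / Z
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  l <- pmax(e$values, 0)
  a <- 2 * sqrt(l[1]); b <- 2 * sqrt(l[2])
  if (l[1] - l[2] < 1e-12) {
    theta <- 0 # isotropic: orientation undefined, fixed for determinism
  } else {
    v <- e$vectors[, 1]
    theta <- atan2(v[2], v[1])
    # axis orientation modulo pi, normalized to (-pi/2, pi/2]
    if (theta <= -pi / 2) theta <- theta + pi
    if (theta > pi / 2) theta <- theta - pi
  }
  structure(
    list(
      x = ctr[1], y = ctr[2], theta = theta, a = a, b = b,
      area = pi * a * b, weight_sum = Z, likelihood = NA_real_,
      n_px = n
    ),
    class = "ellipse_detection"
  )
}

#' @export
print.ellipse_detection <- function(x, ...) {
  cat(sprintf(
    "Ellipse at (%.2f, %.2f), theta %.3f rad, a %.2f, b %.2f, area %.1f px^2%s\n",
    x$x, x$y, x$theta, x$a, x$b, x$area,
    if (is.na(x$likelihood)) "" else sprintf(", p = %.3f", x$likelihood)
  ))
  invisible(x)
}

#' Fit the element-area shape model
#'
#' Mean and population standard deviation of the element areas observed
#' during warmup, used (i) to clean the foreground of noise specks and
#' (ii) as the location/scale of the area-likelihood that validates
#' candidate flies. The variance is the population form
#' `E[A^2] - mean(A)^2`.
#'
#' @param areas numeric vector of element areas in px^2 (one per
#'   detected element).
#' @param c_clean cleaning multiplier for [area_filter()]; default 15.
#' @return object of class `area_model` with `mu_areas`, `sigma_areas`,
#'   `c_clean`, `n_samples`.
#' @export
fit_area_model <- function(areas, c_clean = 15) {
  areas <- as.numeric(areas)
  if (length(areas) < 1L) stop("at least one area is required to fit the area model")
  mu <- mean(areas)
  v <- mean(areas^2) - mu^2
  structure(
    list(
      mu_areas = mu,
      sigma_areas = sqrt(max(v, 0)),
      c_clean = c_clean,
      n_samples = length(areas)
    ),
    class = "area_model"
  )
}

#' @export
print.area_model <- function(x, ...) {
  cat(sprintf(
    "Area model: mu = %.2f px^2, sigma = %.2f px^2 (n = %d, cleaning c = %g)\n",
    x$mu_areas, x$sigma_areas, x$n_samples, x$c_clean
  ))
  invisible(x)
}

#' Clean the foreground by minimum area
#'
#' Removes components whose pixel area is at or below
#' `max(mu_areas - c_clean * sigma_areas, 1)` px^2. With the default
#' large multiplier this only strips noise specks, deferring real
#' discrimination to the likelihood validation.
#'
#' @param components list from [connected_components()].
#' @param model fitted `area_model`.
#' @return filtered component list.
#' @export
area_filter <- function(components, model) {
  if (!inherits(model, "area_model")) stop("model must be an area_model")
  thmin <- max(model$mu_areas - model$c_clean * model$sigma_areas, 1)
  Filter(function(cp) cp$area > thmin, components)
}

#' Area likelihood of a candidate fly
#'
#' Probability-like score `exp(-|pi a b - mu_areas| / sigma_areas)`
#' comparing the fitted ellipse area to the shape model: 1 for a
#' perfectly typical fly, decaying exponentially with the (scaled)
#' area discrepancy.
#'
#' @param e an `ellipse_detection` (or anything with `a` and `b`).
#' @param model fitted `area_model`.
#' @return likelihood in (0, 1\] (degenerate 0/1 when `sigma_areas` is 0).
#' @export
ellipse_likelihood <- function(e, model) {
  if (!inherits(model, "area_model")) stop("model must be an area_model")
  area <- pi * e$a * e$b
  if (model$sigma_areas == 0) {
    warning("sigma_areas is zero; likelihood degenerates to an indicator")
    return(as.numeric(area == model$mu_areas))
  }
  exp(-abs(area - model$mu_areas) / model$sigma_areas)
}

# Detections as a data frame (one row per ellipse).
detections_df <- function(ellipses) {
  if (length(ellipses) == 0L) {
    return(data.frame(
      x = numeric(0), y = numeric(0), theta = numeric(0), a = numeric(0),
      b = numeric(0), area = numeric(0), weight_sum = numeric(0),
      likelihood = numeric(0), n_px = integer(0)
    ))
  }
  do.call(rbind, lapply(ellipses, function(e) {
    data.frame(
      x = e$x, y = e$y, theta = e$theta, a = e$a, b = e$b, area = e$area,
      weight_sum = e$weight_sum, likelihood = e$likelihood, n_px = e$n_px
    )
  }))
}
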