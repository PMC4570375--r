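#' Likelihood-driven validation of candidate flies
#'
#' Components whose area likelihood is low are re-segmented by locally
#' adjusting the front detection threshold inside the component's region
#' of interest: a too-large component (likely several touching flies) is
#' probed with a raised threshold to split it; a too-small one with a
#' lowered threshold. The search is a bounded hysteresis loop: the
#' threshold multiplier steps by `dN` for at most `max_steps` steps, and
#' a new configuration is adopted only when the product of the
#' sub-element likelihoods improves on the incumbent by more than
#' `improve_tol` (accepted elements are those with likelihood at least
#' `accept_floor`). When a raised threshold reveals k cores, each
#' sub-element is re-fitted on the original component's pixels
#' partitioned by nearest core, so that split flies are scored at their
#' full extent rather than their threshold-shrunken cores. In the worst
#' case the original component is returned unchanged.
#'
#' @param components list from [connected_components()] (after
#'   [area_filter()]).
#' @param area_model fitted `area_model`.
#' @param model fitted `background_model` (gives access to the raw
#'   difference image for local re-thresholding).
#' @param frame the current (pre-filtered) intensity matrix.
#' @param N base front-detection threshold multiplier.
#' @param dN threshold step per iteration.
#' @param max_steps maximum steps in either direction.
#' @param accept_floor minimum likelihood for a sub-element to count as
#'   an actual fly; default `exp(-3)`.
#' @param improve_tol relative improvement required to adopt a new
#'   configuration; default 0.05.
#' @param max_parts cap on the number of sub-elements a split may
#'   produce; default one more than the area ratio suggests.
#' @param sigma_floor,polarity,min_px forwarded segmentation settings.
#' @param min_sigma_frac floor on `sigma_areas` (as a fraction of
#'   `mu_areas`) used when scoring, guarding against a degenerate
#'   area model fitted on near-identical elements.
#' @return list of `ellipse_detection` objects with `likelihood` set;
#'   each carries its `pixels` and `weights` for downstream use.
#' @export
validate_detections <- function(components, area_model, model, frame,
                                N = 10, dN = 2, max_steps = 8,
                                accept_floor = exp(-3), improve_tol = 0.05,
                                max_parts = NULL, sigma_floor = 1,
                                polarity = "dark", min_px = 3,
                                min_sigma_frac = 0.05) {
  out <- list()
  for (cp in components) {
    res <- validate_component(
      cp, area_model, model, frame, N, dN, max_steps, accept_floor,
      improve_tol, max_parts, sigma_floor, polarity, min_px, min_sigma_frac
    )
    out <- c(out, res)
  }
  out
}

# robust area-model scale for scoring
scoring_sigma <- function(area_model, min_sigma_frac) {
  max(area_model$sigma_areas, min_sigma_frac * area_model$mu_areas)
}

score_ellipse <- function(e, area_model, min_sigma_frac) {
  s <- scoring_sigma(area_model, min_sigma_frac)
  exp(-abs(pi * e$a * e$b - area_model$mu_areas) / s)
}

fit_component_ellipse <- function(cp, model, frame, sigma_floor) {
  w <- component_weights(cp, model, frame, sigma_floor)
  if (all(w == 0)) w <- rep(1, length(w))
  e <- fit_ellipse(cp$pixels, w)
  e$pixels <- cp$pixels
  e$weights <- w
  e$idx <- cp$idx
  e
}

validate_component <- function(cp, area_model, model, frame, N, dN, max_steps,
                               accept_floor, improve_tol, max_parts,
                               sigma_floor, polarity, min_px, min_sigma_frac) {
  e0 <- fit_component_ellipse(cp, model, frame, sigma_floor)
  e0$likelihood <- score_ellipse(e0, area_model, min_sigma_frac)
  if (e0$likelihood >= accept_floor) return(list(e0))

  too_large <- pi * e0$a * e0$b > area_model$mu_areas
  if (is.null(max_parts)) {
    max_parts <- max(2L, round(pi * e0$a * e0$b / max(area_model$mu_areas, 1)) + 1L)
  }
  best <- list(score = e0$likelihood, ellipses = list(e0))

  for (s in seq_len(max_steps)) {
    N_s <- N + (if (too_large) s else -s) * dN
    if (N_s <= 0) break
    if (too_large) {
      cand <- split_candidate(
        cp, model, frame, N_s, sigma_floor, polarity, min_px, max_parts
      )
    } else {
      cand <- grow_candidate(cp, model, frame, N_s, sigma_floor, polarity, min_px)
    }
    if (is.null(cand)) next
    ps <- vapply(cand, score_ellipse, numeric(1),
      area_model = area_model, min_sigma_frac = min_sigma_frac
    )
    keep <- ps >= accept_floor
    if (!any(keep)) next
    cand <- cand[keep]
    ps <- ps[keep]
    for (i in seq_along(cand)) cand[[i]]$likelihood <- ps[i]
    score <- prod(ps)
    if (score > best$score * (1 + improve_tol)) {
      best <- list(score = score, ellipses = cand)
    }
  }
  best$ellipses
}

# Re-threshold inside the component at a raised multiplier; if >= 2
# cores appear, partition the ORIGINAL pixels by nearest core and fit
# one full-extent ellipse per part.
split_candidate <- function(cp, model, frame, N_s, sigma_floor, polarity,
                            min_px, max_parts) {
  i <- cp$idx
  s <- pmax(model$sigma[i], sigma_floor)
  diff <- switch(polarity,
    dark = model$mu[i] - frame[i],
    bright = frame[i] - model$mu[i],
    both = abs(frame[i] - model$mu[i])
  )
  sel <- diff > N_s * s
  if (sum(sel) < 2 * min_px) return(NULL)
  core_mask <- matrix(FALSE, nrow(frame), ncol(frame))
  core_mask[i[sel]] <- TRUE
  cores <- connected_components(core_mask)
  cores <- Filter(function(cc) cc$area >= min_px, cores)
  if (length(cores) < 2L) return(NULL)
  if (length(cores) > max_parts) {
    ord <- order(vapply(cores, function(cc) cc$area, numeric(1)), decreasing = TRUE)
    cores <- cores[ord[seq_len(max_parts)]]
  }
  centers <- t(vapply(cores, function(cc) colMeans(cc$pixels), numeric(2)))
  split_by_centers(cp, centers, model, frame, sigma_floor)
}

# Partition a component's pixels by nearest center and fit weighted
# ellipses per part. Shared with merge resolution.
split_by_centers <- function(cp, centers, model, frame, sigma_floor) {
  w <- component_weights(cp, model, frame, sigma_floor)
  d2 <- vapply(seq_len(nrow(centers)), function(k) {
    (cp$pixels[, 1] - centers[k, 1])^2 + (cp$pixels[, 2] - centers[k, 2])^2
  }, numeric(nrow(cp$pixels)))
  part <- max.col(-matrix(d2, ncol = nrow(centers)), ties.method = "first")
  lapply(seq_len(nrow(centers)), function(k) {
    sel <- part == k
    if (!any(sel)) {
      e <- fit_ellipse(centers[k, , drop = FALSE], 1)
    } else {
      e <- fit_ellipse(cp$pixels[sel, , drop = FALSE], w[sel])
      e$pixels <- cp$pixels[sel, , drop = FALSE]
      e$weights <- w[sel]
      e$idx <- cp$idx[sel]
    }
    e
  })
}

# Lowered threshold: let a too-small component grow within a padded
# window around it and re-fit a single ellipse.
grow_candidate <- function(cp, model, frame, N_s, sigma_floor, polarity,
                           min_px, pad = 4L) {
  h <- nrow(frame); w <- ncol(frame)
  rs <- max(1L, min(cp$pixels[, "y"]) + 1L - pad):min(h, max(cp$pixels[, "y"]) + 1L + pad)
  cs <- max(1L, min(cp$pixels[, "x"]) + 1L - pad):min(w, max(cp$pixels[, "x"]) + 1L + pad)
  s <- pmax(model$sigma[rs, cs, drop = FALSE], sigma_floor)
  diff <- switch(polarity,
    dark = model$mu[rs, cs, drop = FALSE] - frame[rs, cs, drop = FALSE],
    bright = frame[rs, cs, drop = FALSE] - model$mu[rs, cs, drop = FALSE],
    both = abs(frame[rs, cs, drop = FALSE] - model$mu[rs, cs, drop = FALSE])
  )
  sub <- diff > N_s * s
  if (!any(sub)) return(NULL)
  mask <- matrix(FALSE, h, w)
  mask[rs, cs] <- sub
  comps <- connected_components(mask)
  # keep the grown component that overlaps the original most
  ov <- vapply(comps, function(cc) length(intersect(cc$idx, cp$idx)), numeric(1))
  if (max(ov) == 0) return(NULL)
  grown <- comps[[which.max(ov)]]
  if (grown$area < min_px) return(NULL)
  list(fit_component_ellipse(grown, model, frame, sigma_floor))
}
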