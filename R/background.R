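#' Robust per-pixel background model
#'
#' The arena background is unimodal (a bright backlit plate), so each
#' pixel is modeled by a single Gaussian whose location and scale are
#' estimated robustly: the temporal median mu and the scaled median
#' absolute deviation sigma = c * MAD, with c = 1.4826 = 1/qnorm(3/4) so
#' that sigma estimates the standard deviation for Gaussian noise.
#' Robust statistics keep slowly moving flies from biasing the model
#' during fitting.
#'
#' @param frames a list of intensity matrices, a 3-D array (h x w x t),
#'   or a directory of PNG frames.
#' @param c_mad MAD-to-sd scale constant, default 1.4826.
#' @param update_period_frames how often (in frames) the model is meant
#'   to be refreshed by [update_background()]; stored for the pipeline.
#' @param alpha exponential blending rate used by selective updating.
#' @return an object of class `background_model` with per-pixel `mu` and
#'   `sigma` matrices.
#' @seealso [subtract_background()], [update_background()]
#' @export
fit_background <- function(frames, c_mad = 1.4826,
                           update_period_frames = 100L, alpha = 0.05) {
  fp <- frame_provider(frames)
  if (fp$n < 3L) stop("at least 3 frames are required to fit a background model")
  fl <- lapply(seq_len(fp$n), fp$get)
  check_frame_dims(fl)
  h <- nrow(fl[[1]]); w <- ncol(fl[[1]])
  m <- vapply(fl, as.numeric, numeric(h * w)) # pixels x frames
  mu <- matrixStats::rowMedians(m)
  sigma <- c_mad * matrixStats::rowMedians(abs(m - mu))
  structure(
    list(
      mu = matrix(mu, h, w),
      sigma = matrix(sigma, h, w),
      c_mad = c_mad,
      n_frames_fitted = fp$n,
      update_period_frames = as.integer(update_period_frames),
      alpha = alpha,
      n_updates = 0L
    ),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "Background model: %d x %d px, fitted on %d frames (c = %.4f)\n",
    nrow(x$mu), ncol(x$mu), x$n_frames_fitted, x$c_mad
  ))
  cat(sprintf(
    "  mu in [%.1f, %.1f], median sigma %.3f, %d selective updates\n",
    min(x$mu), max(x$mu), stats::median(x$sigma), x$n_updates
  ))
  invisible(x)
}

#' Selective background update
#'
#' Refreshes the model toward the current frame, but only at pixels
#' currently classified as background: pixels under the foreground mask
#' are frozen, so a fly that stops never burns a phantom dark spot into
#' the model. The pipeline calls this every
#' `update_period_frames` frames; the function itself blends
#' unconditionally on each call.
#'
#' @param model a fitted `background_model`.
#' @param frame current intensity matrix.
#' @param fg_mask logical matrix, `TRUE` where pixels are foreground
#'   (these are left untouched).
#' @param alpha blending rate in (0, 1\]; defaults to the rate stored in
#'   the model.
#' @return the updated `background_model`.
#' @export
update_background <- function(model, frame, fg_mask, alpha = model$alpha) {
  if (!inherits(model, "background_model")) stop("model must be a fitted background_model")
  if (!all(dim(frame) == dim(model$mu)) || !all(dim(fg_mask) == dim(model$mu))) {
    stop("frame/mask dimensions do not match the background model")
  }
  bg <- !fg_mask
  if (any(bg)) {
    model$mu[bg] <- (1 - alpha) * model$mu[bg] + alpha * frame[bg]
    dev <- model$c_mad * abs(frame[bg] - model$mu[bg])
    model$sigma[bg] <- (1 - alpha) * model$sigma[bg] + alpha * dev
    model$n_updates <- model$n_updates + 1L
  }
  model
}

#' Foreground extraction by thresholded background subtraction
#'
#' A pixel is declared foreground when its darkening relative to the
#' background model exceeds the front detection threshold `N * sigma(p)`.
#' Flies are imaged dark on a bright backlit plate, so the default
#' polarity tests `mu - I > N * sigma`; `polarity = "bright"` tests the
#' opposite sign and `"both"` either. Foreground pixels carry the value
#' `255 - I(p)` (bright blobs on a zero background), background pixels 0.
#'
#' @param model fitted `background_model`.
#' @param frame intensity matrix.
#' @param N threshold multiplier (number of robust standard deviations);
#'   default 10.
#' @param polarity `"dark"` (default), `"bright"` or `"both"`.
#' @param sigma_floor lower bound applied to sigma so the threshold
#'   stays meaningful on noiseless pixels; default 1 intensity unit.
#' @return an object of class `foreground` with `values` (numeric
#'   matrix) and `mask` (logical matrix).
#' @export
subtract_background <- function(model, frame, N = 10, polarity = c("dark", "bright", "both"),
                                sigma_floor = 1) {
  if (!inherits(model, "background_model")) stop("model must be a fitted background_model")
  if (N < 0) stop("threshold multiplier N must be non-negative")
  polarity <- match.arg(polarity)
  s <- pmax(model$sigma, sigma_floor)
  thr <- N * s
  dark <- (model$mu - frame) > thr
  bright <- (frame - model$mu) > thr
  mask <- switch(polarity, dark = dark, bright = bright, both = dark | bright)
  values <- matrix(0, nrow(frame), ncol(frame))
  values[mask] <- 255 - frame[mask]
  structure(list(values = values, mask = mask), class = "foreground")
}
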