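#' Save a background model to a two-band floating-point TIFF
#'
#' Band 1 is mu, band 2 sigma, both in intensity units; lets a fitted
#' model be reused across runs on the same rig.
#'
#' @param model a `background_model`.
#' @param path output `.tif` path.
#' @export
write_background <- function(model, path) {
  if (!inherits(model, "background_model")) stop("model must be a background_model")
  tiff::writeTIFF(list(model$mu / 255, model$sigma / 255), path,
    bits.per.sample = 32L, reduce = FALSE
  )
  invisible(path)
}

#' Load a background model saved by [write_background()]
#'
#' @param path `.tif` path.
#' @param c_mad,update_period_frames,alpha bookkeeping values to attach
#'   (not stored in the image bands).
#' @return a `background_model`.
#' @export
read_background <- function(path, c_mad = 1.4826, update_period_frames = 100L,
                            alpha = 0.05) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(img) || length(img) < 2L) {
    stop("expected a two-page background TIFF")
  }
  structure(
    list(
      mu = img[[1]] * 255, sigma = img[[2]] * 255,
      c_mad = c_mad, n_frames_fitted = NA_integer_,
      update_period_frames = as.integer(update_period_frames),
      alpha = alpha, n_updates = 0L
    ),
    class = "background_model"
  )
}
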