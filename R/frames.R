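#' Frame handling and image input
#'
#' Frames are plain numeric matrices of grayscale intensities in
#' \[0, 255\], indexed as `m[row, col]`. Pixel coordinates used everywhere
#' else in the package are 0-based pixel centers with `x = col - 1`
#' (rightwards) and `y = row - 1` (downwards).
#'
#' @name frames
NULL

#' Read a directory of numbered grayscale frames
#'
#' Reads all PNG files in a directory in lexicographic order and returns
#' them as a list of intensity matrices in \[0, 255\]. Color images are
#' converted to grayscale by the channel average (luminance average).
#'
#' @param path directory containing `*.png` frames.
#' @param pattern filename regular expression, default `"\\.png$"`.
#' @return list of numeric matrices.
#' @export
read_frames <- function(path, pattern = "\\.png$") {
  if (!dir.exists(path)) stop("frame directory not found: ", path)
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no frames matching ", pattern, " in ", path)
  lapply(files, read_frame)
}

#' Read a single grayscale frame from a PNG file
#'
#' @param file path to a PNG image.
#' @return numeric matrix of intensities in \[0, 255\].
#' @export
read_frame <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3L) {
    # channel average; drop alpha if present
    nc <- min(dim(img)[3L], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img * 255
}

#' Pre-filter a frame
#'
#' Gaussian smoothing applied before background subtraction; kernel
#' standard deviation defaults to 1 pixel.
#'
#' @param frame intensity matrix.
#' @param sigma Gaussian kernel sd in pixels; `0` disables filtering.
#' @return filtered matrix, same dimensions.
#' @export
preprocess_frame <- function(frame, sigma = 1) {
  stopifnot(is.matrix(frame))
  if (sigma <= 0) return(frame)
  EBImage::gblur(frame, sigma = sigma)
}

# Normalise the many accepted frame-sequence representations into a
# closure interface: list(n, get(i)) with i in 1..n.
frame_provider <- function(frames, n_frames = NULL) {
  if (is.character(frames) && length(frames) == 1L) {
    frames <- read_frames(frames)
  }
  if (is.function(frames)) {
    if (is.null(n_frames)) stop("n_frames is required for a generator function")
    return(list(n = as.integer(n_frames), get = frames))
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    nf <- dim(frames)[3L]
    return(list(n = nf, get = function(i) frames[, , i]))
  }
  if (is.list(frames)) {
    return(list(n = length(frames), get = function(i) frames[[i]]))
  }
  stop("unsupported frame sequence representation")
}

check_frame_dims <- function(frames) {
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions")
  }
  invisible(dims[, 1])
}
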