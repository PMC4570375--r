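#' 8-connected components of the foreground
#'
#' Labels the foreground mask into 8-connected components and returns
#' them ordered deterministically by (min row, min col) of their pixels.
#' Each component carries its pixel coordinates (0-based, x = column,
#' y = row) and the foreground values at those pixels.
#'
#' @param fg a `foreground` object from [subtract_background()], or a
#'   logical mask matrix.
#' @return list of components; each is a list with `pixels` (n x 2
#'   matrix, columns `x`, `y`), `values`, `area` (pixel count) and
#'   `idx` (linear indices into the frame matrix).
#' @export
connected_components <- function(fg) {
  if (inherits(fg, "foreground")) {
    mask <- fg$mask
    values <- fg$values
  } else {
    mask <- fg
    values <- NULL
  }
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L

  # union-find over foreground pixels, scanning in column-major order;
  # each pixel unions with already-scanned 8-neighbours (W, NW, N, SW in
  # (col,row) scan terms, i.e. smaller linear index)
  key <- function(rr, cc) (cc - 1L) * h + rr
  pos <- integer(h * w) # linear index -> pixel number (0 = not fg)
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(idx)) {
    rr <- r[k]; cc <- c[k]
    for (d in list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))) {
      nr <- rr + d[1L]; nc <- cc + d[2L]
      if (nr < 1L || nr > h || nc < 1L) next
      j <- pos[key(nr, nc)]
      if (j > 0L) {
        ri <- find(k); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  groups <- split(seq_along(idx), root)
  comps <- lapply(groups, function(g) {
    list(
      pixels = cbind(x = c[g] - 1L, y = r[g] - 1L),
      values = if (is.null(values)) rep(1, length(g)) else values[idx[g]],
      area = length(g),
      idx = idx[g]
    )
  })
  ord <- order(
    vapply(comps, function(cp) min(cp$pixels[, "y"]), numeric(1)),
    vapply(comps, function(cp) min(cp$pixels[, "x"]), numeric(1))
  )
  unname(comps[ord])
}

# Per-pixel weights W = |I - mu| / sigma of a component under the
# background model; the pixel weighting that makes components splittable
# during validation.
component_weights <- function(component, model, frame, sigma_floor = 1) {
  i <- component$idx
  abs(frame[i] - model$mu[i]) / pmax(model$sigma[i], sigma_floor)
}
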