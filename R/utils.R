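## Internal helpers shared across modules.

#' Wrap phase angles into (-pi, pi]
#'
#' @param x numeric vector/array of phase values (radians).
#' @return values congruent to `x` modulo 2*pi, in the half-open interval
#'   (-pi, pi].
#' @examples
#' wrapPhase(c(0, pi, -pi, 3.5, -3.5))
#' @export
wrapPhase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

## Voxel-center world coordinate along one axis (1-based index i -> (i-.5)*h,
## origin at the grid corner).
axisCenters <- function(n, h) (seq_len(n) - 0.5) * h

## N x 3 matrix of voxel-center coordinates for linear indices `idx` into an
## array of dimension `dims` with voxel size `vox`.
voxelCenters <- function(idx, dims, vox) {
  idx <- idx - 1L
  i <- idx %% dims[1]
  j <- (idx %/% dims[1]) %% dims[2]
  k <- idx %/% (dims[1] * dims[2])
  cbind((i + 0.5) * vox[1], (j + 0.5) * vox[2], (k + 0.5) * vox[3])
}

## i/j/k (1-based) subscripts for linear indices.
voxelSubscripts <- function(idx, dims) {
  idx <- idx - 1L
  cbind(idx %% dims[1] + 1L,
        (idx %/% dims[1]) %% dims[2] + 1L,
        idx %/% (dims[1] * dims[2]) + 1L)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Shift a 3D array by integer offsets, padding with `fill`.
shiftArray <- function(a, off, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      if (o >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      if (-o >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Binary dilation of a 3D logical array by a box radius (rx, ry, rz).
dilateMask <- function(mask, radius = c(2L, 2L, 1L)) {
  out <- mask
  for (dx in -radius[1]:radius[1])
    for (dy in -radius[2]:radius[2])
      for (dz in -radius[3]:radius[3]) {
        if (dx == 0 && dy == 0 && dz == 0) next
        out <- out | shiftArray(mask, c(dx, dy, dz), fill = FALSE)
      }
  out
}

## Circular mean of angles (radians).
circularMean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
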