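## Spatiotemporal phase unwrapping within the myocardial mask and conversion
## to Eulerian displacement.

#' Phase-quality map
#'
#' Quality is the negative local variance of the wrap-safe phase gradients
#' over a 3x3x3 spatial neighborhood: locally smooth phase gives high (near
#' zero) quality, noisy or discontinuous phase gives strongly negative
#' quality. Invariant under a global phase offset.
#'
#' @param phase 3D wrapped-phase array (radians).
#' @param mask 3D logical array; quality is finite on the mask.
#' @return 3D numeric array; `-Inf` outside the mask.
#' @export
qualityMap <- function(phase, mask) {
  stopifnot(identical(dim(phase), dim(mask)))
  p <- phase
  p[!mask] <- NA_real_
  grads <- list()
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L)
    off[ax] <- 1L
    gf <- wrapPhase(shiftArray(p, -off) - p)  # forward difference
    gb <- wrapPhase(p - shiftArray(p, off))   # backward difference
    grads[[length(grads) + 1L]] <- gf
    grads[[length(grads) + 1L]] <- gb
  }
  ## accumulate neighborhood moments of each gradient component
  n <- s <- s2 <- array(0, dim(phase))
  for (g in grads) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      gs <- shiftArray(g, c(dx, dy, dz))
      ok <- !is.na(gs)
      n <- n + ok
      gs[!ok] <- 0
      s <- s + gs
      s2 <- s2 + gs^2
    }
  }
  q <- array(0, dim(phase))
  pos <- n > 1
  q[pos] <- -(s2[pos] - s[pos]^2 / n[pos]) / (n[pos] - 1)
  q[!mask] <- -Inf
  q
}

## Single-volume quality-guided floodfill. Returns list(unwrapped, k,
## component); unwrapped = wrapped + 2*pi*k with integer k, NA off-mask.
floodfillUnwrap <- function(wrapped, mask, quality = NULL) {
  if (is.null(quality)) quality <- qualityMap(wrapped, mask)
  q <- quality
  q[!is.finite(q) & mask] <- min(q[is.finite(q)], 0) - 1
  q[!mask] <- -Inf
  res <- floodfill_unwrap_cpp(as.numeric(wrapped), as.numeric(q),
                              as.logical(mask), as.integer(dim(wrapped)))
  k <- array(res$k, dim(wrapped))
  comp <- array(res$component, dim(wrapped))
  unw <- wrapped + 2 * pi * k
  unw[!mask] <- NA_real_
  list(unwrapped = unw, k = k, component = comp,
       ncomponents = res$ncomponents)
}

#' Unwrap the encoded phase volumes over space and time
#'
#' Quality-guided floodfill unwrapping extended to three spatial dimensions
#' plus time. The first phase is unwrapped spatially and its per-component
#' global 2*pi offset chosen to minimize the mean absolute phase (the first
#' cardiac phase carries the smallest true motion). Each later phase is
#' predicted voxelwise from the previous unwrapped phase; the wrapped
#' residual is unwrapped spatially by the same floodfill, its per-component
#' integer 2*pi offset chosen to minimize the mean residual, and the
#' prediction added back. Disconnected mask components are handled
#' independently. The output is congruent to the input modulo 2*pi at every
#' masked voxel by construction.
#'
#' @param series a [DenseSeries-class], or a single 4D wrapped-phase array.
#' @param mask 4D logical mask (or 3D, reused at every phase).
#' @return for a series, a list of 4D unwrapped arrays `x`, `y`, `z`; for a
#'   single array, one 4D unwrapped array. `NA` outside the mask.
#' @export
unwrapSpatiotemporal <- function(series, mask) {
  if (is(series, "DenseSeries")) {
    m4 <- expandMask(mask, dim(series@phaseX))
    return(list(x = unwrapOneDirection(series@phaseX, m4),
                y = unwrapOneDirection(series@phaseY, m4),
                z = unwrapOneDirection(series@phaseZ, m4)))
  }
  unwrapOneDirection(series, expandMask(mask, dim(series)))
}

expandMask <- function(mask, d4) {
  if (length(dim(mask)) == 4L) return(mask)
  array(rep(mask, d4[4]), d4)
}

unwrapOneDirection <- function(wrapped4, mask4) {
  d4 <- dim(wrapped4)
  stopifnot(length(d4) == 4L, identical(dim(mask4), d4))
  P <- d4[4]
  out <- array(NA_real_, d4)
  prev <- NULL
  prevMask <- NULL
  for (f in seq_len(P)) {
    w <- array(wrapped4[, , , f], d4[1:3])
    m <- array(mask4[, , , f], d4[1:3])
    if (!any(m)) {
      warning(sprintf("empty mask at phase %d; skipped", f))
      prev <- NULL
      next
    }
    pred <- array(0, d4[1:3])
    if (!is.null(prev)) {
      pred[m & prevMask] <- prev[m & prevMask]
      missing <- which(m & !prevMask)
      if (length(missing)) {
        avail <- which(prevMask)
        if (length(avail)) {
          ms <- voxelSubscripts(missing, d4[1:3])
          as_ <- voxelSubscripts(avail, d4[1:3])
          for (ii in seq_along(missing)) {
            d2 <- (as_[, 1] - ms[ii, 1])^2 + (as_[, 2] - ms[ii, 2])^2 +
              (as_[, 3] - ms[ii, 3])^2
            pred[missing[ii]] <- prev[avail[which.min(d2)]]
          }
        }
      }
    }
    res <- array(0, d4[1:3])
    res[m] <- wrapPhase(w[m] - pred[m])
    ff <- floodfillUnwrap(res, m)
    ## integer 2*pi offset per component: center the residual (phase 1:
    ## center the phase itself, i.e. minimize mean |phase|)
    for (cc in seq_len(ff$ncomponents)) {
      sel <- which(ff$component == cc)
      mshift <- round(mean(ff$unwrapped[sel]) / (2 * pi))
      ff$k[sel] <- ff$k[sel] - mshift
    }
    cand <- pred + res + 2 * pi * ff$k
    ## snap to wrapped + exact integer multiple of 2*pi
    ktot <- round((cand - w) / (2 * pi))
    u <- w + 2 * pi * ktot
    u[!m] <- NA_real_
    out[, , , f] <- u
    prev <- u
    prevMask <- m
  }
  out
}

#' Convert unwrapped phase to displacement
#'
#' Displacement is the unwrapped encoded phase divided by the displacement
#' encoding frequency: `d = phi / (2 * pi * ke)` mm.
#'
#' @param phase unwrapped phase (radians), any shape.
#' @param ke displacement-encoding frequency (cycles/mm), positive.
#' @return displacement in mm, same shape.
#' @examples
#' phaseToDisplacement(pi, ke = 1.1)  # ~0.4545 mm
#' @export
phaseToDisplacement <- function(phase, ke) {
  stopifnotScalar(ke, "ke")
  if (ke <= 0) stop("ke must be positive")
  phase / (2 * pi * ke)
}

#' Assemble per-direction displacements into a vector field
#'
#' Componentwise vector addition of the three orthogonal 1D displacement
#' volumes. Voxels whose displacement magnitude exceeds the physiologic cap
#' are flagged unreliable (kept, not deleted).
#'
#' @param dx,dy,dz 4D displacement arrays (mm), `NA` outside their support.
#' @param mask 4D logical mask; if component supports differ, the
#'   intersection is used with a warning.
#' @param ke encoding frequency (cycles/mm).
#' @param voxelSize voxel size (mm).
#' @param cap physiologic displacement-magnitude cap (mm), default 3.
#' @return a [DisplacementField-class].
#' @export
assembleVectorField <- function(dx, dy, dz, mask = NULL, ke, voxelSize,
                                cap = 3) {
  d4 <- dim(dx)
  stopifnot(identical(dim(dy), d4), identical(dim(dz), d4))
  support <- !is.na(dx) & !is.na(dy) & !is.na(dz)
  if (is.null(mask)) mask <- support
  mask <- expandMask(mask, d4)
  if (any(mask & !support)) {
    warning("mask extends beyond displacement support; intersected")
    mask <- mask & support
  }
  mag <- sqrt(dx^2 + dy^2 + dz^2)
  reliable <- mask & !is.na(mag) & mag <= cap
  reliable[!mask] <- FALSE
  out <- list(dx, dy, dz)
  for (i in 1:3) out[[i]][!mask] <- NA_real_
  new("DisplacementField", dx = out[[1]], dy = out[[2]], dz = out[[3]],
      mask = mask, reliable = reliable, ke = ke, voxelSize = voxelSize)
}

#' Displacement field from a DENSE series
#'
#' Convenience wrapper: unwraps all three encoded directions within the mask
#' and assembles the Eulerian displacement field.
#'
#' @param series a [DenseSeries-class].
#' @param mask 3D or 4D logical myocardial mask.
#' @param cap displacement cap (mm) passed to [assembleVectorField()].
#' @return a [DisplacementField-class].
#' @export
displacementFromSeries <- function(series, mask, cap = 3) {
  unw <- unwrapSpatiotemporal(series, mask)
  assembleVectorField(phaseToDisplacement(unw$x, series@ke),
                      phaseToDisplacement(unw$y, series@ke),
                      phaseToDisplacement(unw$z, series@ke),
                      mask = NULL, ke = series@ke,
                      voxelSize = series@voxelSize, cap = cap)
}
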