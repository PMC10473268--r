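## Finite-difference gradient fields on the masked pixel grid.
##
## Central differences (spacing 1 pixel) where both axis neighbors are
## valid, one-sided differences at mask edges, NA where no valid
## neighbor exists on an axis. Pixels outside the current region mask do
## not leak into the stencil.

axisDiff <- function(v, axis) {
    d <- dim(v)
    shift <- function(m, by) {
        out <- matrix(NA_real_, d[1L], d[2L])
        if (axis == 1L) {
            if (by > 0) out[seq_len(d[1L] - by), ] <- m[seq.int(by + 1L, d[1L]), ]
            else out[seq.int(1L - by, d[1L]), ] <- m[seq_len(d[1L] + by), ]
        } else {
            if (by > 0) out[, seq_len(d[2L] - by)] <- m[, seq.int(by + 1L, d[2L])]
            else out[, seq.int(1L - by, d[2L])] <- m[, seq_len(d[2L] + by)]
        }
        out
    }
    fwd <- shift(v, 1L)   # value at +1 along axis
    bwd <- shift(v, -1L)  # value at -1 along axis
    g <- (fwd - bwd) / 2
    onlyF <- is.na(bwd) & !is.na(fwd)
    onlyB <- is.na(fwd) & !is.na(bwd)
    g[onlyF] <- (fwd - v)[onlyF]
    g[onlyB] <- (v - bwd)[onlyB]
    g[is.na(v)] <- NA_real_
    g
}

#' Smooth a masked pixel field
#'
#' Convolves the field with a unit-sum 2D Gaussian kernel (full width at
#' half maximum \code{width} pixels), renormalized over the valid
#' support, leaving the mask unchanged. Used to stabilize finite
#' differences of noisy per-pixel maps before gradient-based analyses.
#'
#' @param field a [PixelField-class] or masked numeric matrix.
#' @param width kernel FWHM in pixels; 0 disables smoothing.
#' @return object of the same kind as the input.
#' @export
smoothField <- function(field, width = 5) {
    v <- if (is(field, "PixelField")) field@values else field
    if (width > 0)
        v <- maskedConvolve(v, gaussianKernel(width))
    if (is(field, "PixelField")) initialize(field, values = v) else v
}

#' Gradient of a pixel field
#'
#' Computes the 2D finite-difference gradient of a [PixelField-class] (or
#' a bare masked matrix) and its unit-length normalization. Optional
#' Gaussian pre-smoothing (\code{smooth} = kernel FWHM in pixels)
#' suppresses pixel-level jitter that would otherwise dominate the
#' normalized directions where the field is shallow.
#'
#' @param field a [PixelField-class] or numeric matrix with \code{NA}
#'   outside the region of interest.
#' @param smooth FWHM of the Gaussian pre-smoothing kernel in pixels
#'   (default 0 = plain central differences).
#' @return a [GradientField-class]; normalized components are \code{NA}
#'   where the raw gradient is undefined or has zero length.
#' @export
pixelGradient <- function(field, smooth = 0) {
    v <- if (is(field, "PixelField")) field@values else field
    if (smooth > 0) v <- smoothField(v, smooth)
    gx <- axisDiff(v, 1L)
    gy <- axisDiff(v, 2L)
    ## a defined gradient needs at least one valid neighbor on each axis
    und <- is.na(gx) | is.na(gy)
    gx[und] <- NA_real_
    gy[und] <- NA_real_
    len <- sqrt(gx^2 + gy^2)
    zero <- !is.na(len) & len == 0
    nx <- gx / len
    ny <- gy / len
    nx[zero] <- NA_real_
    ny[zero] <- NA_real_
    new("GradientField", gx = gx, gy = gy, nx = nx, ny = ny)
}

#' Normalize a gradient field
#'
#' Divides each defined vector by its Euclidean length; zero-length
#' vectors become undefined entries rather than a division error.
#' (Already performed by \code{\link{pixelGradient}}; exposed for raw
#' vector fields.)
#'
#' @param grad a [GradientField-class].
#' @return the same object with refreshed unit-length components.
#' @export
normalizeGradients <- function(grad) {
    len <- sqrt(grad@gx^2 + grad@gy^2)
    zero <- !is.na(len) & len == 0
    nx <- grad@gx / len
    ny <- grad@gy / len
    nx[zero] <- NA_real_
    ny[zero] <- NA_real_
    initialize(grad, nx = nx, ny = ny)
}

## logical matrix: pixels with a defined normalized gradient
definedGradientMask <- function(grad) {
    !is.na(grad@nx) & !is.na(grad@ny)
}
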