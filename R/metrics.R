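## Region-quality metrics: gradient deviation (gd) and reversal index (ri).
##
## gd measures the orthogonality of the two strongest component
## gradients in a region: the mean absolute deviation from 90 degrees of
## the angle between them, over region pixels where both are defined.
## ri counts, per component, the fraction of unordered pixel pairs whose
## gradients differ by strictly more than 90 degrees, then sums the two
## strongest components; it is 0 for continuous (reversal-free)
## gradients.

#' Angle between two 2D vectors
#'
#' @param u,v numeric length-2 vectors, both nonzero.
#' @return angle in degrees, in \code{[0, 180]}.
#' @export
angleBetween <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
        stop("angle undefined for zero vectors")
    acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

## region mask helper: default = everywhere the gradients allow
asRegionMask <- function(region, grad) {
    if (is.null(region)) !is.na(grad@gx) else region
}

#' Gradient deviation of a region
#'
#' Mean over region pixels of \code{|angle(grad alpha, grad beta) - 90|}
#' in degrees; pixels where either gradient is undefined are excluded.
#'
#' @param gradAlpha,gradBeta [GradientField-class] objects of the two
#'   strongest components.
#' @param region logical matrix selecting region pixels (default: all
#'   pixels with defined gradients).
#' @return gd in degrees, in \code{[0, 90]}; \code{NA} when no pixel has
#'   both gradients defined.
#' @export
gradientDeviation <- function(gradAlpha, gradBeta, region = NULL) {
    region <- asRegionMask(region, gradAlpha)
    ok <- region & definedGradientMask(gradAlpha) & definedGradientMask(gradBeta)
    if (!any(ok)) return(NA_real_)
    dot <- gradAlpha@nx[ok] * gradBeta@nx[ok] + gradAlpha@ny[ok] * gradBeta@ny[ok]
    ang <- acos(pmin(1, pmax(-1, dot))) * 180 / pi
    mean(abs(ang - 90))
}

#' Reversal index of one component in a region
#'
#' Fraction of unordered pixel pairs within the region whose gradient
#' vectors subtend an angle strictly above 90 degrees (negative dot
#' product), normalized by \code{choose(N, 2)} where \code{N} counts the
#' region pixels with a defined gradient.
#'
#' @param grad a [GradientField-class].
#' @param region logical matrix selecting region pixels.
#' @return ri(component, region) in \code{[0, 1]}; \code{NA} with fewer
#'   than 2 usable pixels.
#' @export
reversalIndexComponent <- function(grad, region = NULL) {
    region <- asRegionMask(region, grad)
    ok <- region & definedGradientMask(grad)
    n <- sum(ok)
    if (n < 2L) return(NA_real_)
    G <- cbind(grad@nx[ok], grad@ny[ok])
    dots <- tcrossprod(G)
    ## strictly > 90 degrees <=> dot < 0; unordered pairs
    sum(dots[upper.tri(dots)] < 0) / choose(n, 2)
}

#' Reversal index of a region
#'
#' Sum of the per-component reversal indices of the two strongest
#' components.
#'
#' @inheritParams gradientDeviation
#' @return ri in \code{[0, 2]}.
#' @export
reversalIndex <- function(gradAlpha, gradBeta, region = NULL) {
    reversalIndexComponent(gradAlpha, region) +
        reversalIndexComponent(gradBeta, region)
}

#' Quality metrics of a region evaluated in isolation
#'
#' Re-embeds the region's voxels using only within-region connectivity,
#' flattens the two strongest components onto the region's pixels, and
#' returns gd and ri. This is the context-restricted evaluation: a
#' region is "atomic" when its two strongest gradients are continuous
#' and mutually orthogonal.
#'
#' @param conn a [VoxelizedConnectome-class] (full volume).
#' @param proj the full [FlatProjection-class].
#' @param region logical pixel matrix selecting the region.
#' @param k number of components to embed (2 suffice for the metrics).
#' @param smoothWidth FWHM (pixels) of the Gaussian pre-smoothing applied
#'   to the flattened components before differentiation.
#' @return list with elements \code{gd}, \code{ri}, \code{nPixels}.
#' @export
regionQuality <- function(conn, proj, region, k = 2L, smoothWidth = 5) {
    sub <- subsetRegion(conn, proj, region)
    n <- nVoxels(sub$conn)
    if (n < k + 2L)
        return(list(gd = NA_real_, ri = NA_real_, nPixels = sum(region)))
    emb <- diffusionEmbed(sub$conn, k = k)
    keep <- match(emb@voxelIds, voxelIds(sub$proj))
    subproj <- subsetProjectionVoxels(sub$proj, keep)
    fa <- flattenField(emb@coordinates[, 1L], subproj)
    fb <- flattenField(emb@coordinates[, 2L], subproj)
    va <- fa@values; va[!region] <- NA_real_
    vb <- fb@values; vb[!region] <- NA_real_
    ga <- pixelGradient(va, smooth = smoothWidth)
    gb <- pixelGradient(vb, smooth = smoothWidth)
    list(gd = gradientDeviation(ga, gb),
         ri = reversalIndex(ga, gb),
         nPixels = sum(region))
}

## restrict a connectome + projection to the voxels of a pixel region
subsetRegion <- function(conn, proj, region) {
    idx <- pixelIndex(proj)
    keep <- which(region[idx])
    subconn <- VoxelizedConnectome(
        conn@connectivity[keep, keep, drop = FALSE],
        conn@coords[keep, , drop = FALSE],
        conn@voxelIds[keep])
    subproj <- FlatProjection(proj@voxelIds[keep],
                              proj@pixelX[keep], proj@pixelY[keep],
                              dims = proj@dims)
    list(conn = subconn, proj = subproj, voxelIdx = keep)
}

subsetProjectionVoxels <- function(proj, keep) {
    FlatProjection(proj@voxelIds[keep], proj@pixelX[keep],
                   proj@pixelY[keep], dims = proj@dims)
}
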