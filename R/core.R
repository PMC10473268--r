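#' Construct a voxelized connectome
#'
#' @param connectivity square nonnegative numeric matrix; entry
#'   \code{[i, j]} is the strength of the connection from voxel i to
#'   voxel j.
#' @param coords integer matrix (n x 3) of voxel grid positions.
#' @param voxelIds optional integer ids; defaults to \code{1:n}.
#' @return a [VoxelizedConnectome-class].
#' @export
VoxelizedConnectome <- function(connectivity, coords,
                                voxelIds = seq_len(nrow(connectivity))) {
    connectivity <- as.matrix(connectivity)
    if (nrow(connectivity) != ncol(connectivity))
        stop("connectivity matrix must be square")
    storage.mode(coords) <- "integer"
    new("VoxelizedConnectome",
        voxelIds = as.integer(voxelIds),
        coords = as.matrix(coords),
        connectivity = connectivity)
}

#' Construct a flat projection
#'
#' @param voxelIds integer voxel identifiers.
#' @param pixelX,pixelY per-voxel 0-based pixel coordinates.
#' @param dims pixel grid extent \code{c(nx, ny)}; defaults to the
#'   bounding box of the supplied coordinates.
#' @return a [FlatProjection-class].
#' @export
FlatProjection <- function(voxelIds, pixelX, pixelY,
                           dims = c(max(pixelX) + 1L, max(pixelY) + 1L)) {
    new("FlatProjection",
        voxelIds = as.integer(voxelIds),
        pixelX = as.integer(pixelX),
        pixelY = as.integer(pixelY),
        dims = as.integer(dims))
}

#' @export
#' @rdname accessors
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' Accessors
#'
#' @param x an object of this package.
#' @name accessors
#' @export
setMethod("nVoxels", "VoxelizedConnectome", function(x) length(x@voxelIds))
#' @rdname accessors
#' @export
setMethod("nVoxels", "FlatProjection", function(x) length(x@voxelIds))

#' @rdname accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))
#' @rdname accessors
#' @export
setMethod("connectivity", "VoxelizedConnectome", function(x) x@connectivity)

#' @rdname accessors
#' @export
setGeneric("voxelIds", function(x) standardGeneric("voxelIds"))
#' @rdname accessors
#' @export
setMethod("voxelIds", "VoxelizedConnectome", function(x) x@voxelIds)
#' @rdname accessors
#' @export
setMethod("voxelIds", "FlatProjection", function(x) x@voxelIds)
#' @rdname accessors
#' @export
setMethod("voxelIds", "EmbeddingResult", function(x) x@voxelIds)
#' @rdname accessors
#' @export
setMethod("voxelIds", "Parcellation", function(x) x@voxelIds)

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setMethod("voxelCoords", "VoxelizedConnectome", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setMethod("gridDims", "FlatProjection", function(x) x@dims)
#' @rdname accessors
#' @export
setMethod("gridDims", "PixelField", function(x) x@dims)

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setMethod("pixelValues", "PixelField", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pixelLabels", function(x) standardGeneric("pixelLabels"))
#' @rdname accessors
#' @export
setMethod("pixelLabels", "Parcellation", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))
#' @rdname accessors
#' @export
setMethod("voxelLabels", "Parcellation", function(x) x@voxelLabels)

#' @rdname accessors
#' @export
setGeneric("hierarchy", function(x) standardGeneric("hierarchy"))
#' @rdname accessors
#' @export
setMethod("hierarchy", "Parcellation", function(x) x@hierarchy)

#' @rdname accessors
#' @export
setGeneric("strengths", function(x) standardGeneric("strengths"))
#' @rdname accessors
#' @export
setMethod("strengths", "EmbeddingResult", function(x) x@strengths)

#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setMethod("coordinates", "EmbeddingResult", function(x) x@coordinates)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "ToyModel", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("connectome", function(x) standardGeneric("connectome"))
#' @rdname accessors
#' @export
setMethod("connectome", "ToyModel", function(x) x@connectome)

#' @rdname accessors
#' @export
setGeneric("projection", function(x) standardGeneric("projection"))
#' @rdname accessors
#' @export
setMethod("projection", "ToyModel", function(x) x@projection)

setMethod("show", "VoxelizedConnectome", function(object) {
    cat("VoxelizedConnectome:", nVoxels(object), "voxels,",
        sum(object@connectivity > 0), "nonzero connections\n")
})

setMethod("show", "FlatProjection", function(object) {
    cat("FlatProjection:", nVoxels(object), "voxels onto a",
        object@dims[1L], "x", object@dims[2L], "pixel grid (",
        length(unique(pixelIndex(object))), "valid pixels )\n")
})

setMethod("show", "EmbeddingResult", function(object) {
    cat("EmbeddingResult:", nrow(object@coordinates), "voxels,",
        ncol(object@coordinates), "components; relative strengths",
        paste(round(object@strengths / object@strengths[1L], 3)[
            seq_len(min(5L, length(object@strengths)))], collapse = ", "),
        "...\n")
})

setMethod("show", "Parcellation", function(object) {
    labs <- object@labels
    n <- length(unique(labs[!is.na(labs) & labs > 0]))
    cat("Parcellation:", n, "regions over", sum(!is.na(labs)),
        "valid pixels;", nrow(object@hierarchy), "hierarchy nodes\n")
})

setMethod("show", "ToyModel", function(object) {
    cat("ToyModel (", object@model, "): ", nVoxels(object@connectome),
        " voxels, phi = ", object@phi, ", seed = ", object@seed, "\n",
        sep = "")
})

## ---- internal pixel indexing helpers -------------------------------------

## linear 1-based index into an nx x ny matrix from 0-based pixel coords
pixelIndex <- function(proj, x = proj@pixelX, y = proj@pixelY) {
    x + 1L + proj@dims[1L] * y
}

## list: linear pixel index (as character) -> integer positions of voxels
reverseMap <- function(proj) {
    split(seq_along(proj@voxelIds), pixelIndex(proj))
}

## logical nx x ny matrix of valid (occupied) pixels
validPixelMask <- function(proj) {
    m <- matrix(FALSE, proj@dims[1L], proj@dims[2L])
    m[pixelIndex(proj)] <- TRUE
    m
}

## ---- core operations ------------------------------------------------------

#' Flatten per-voxel values onto the pixel grid
#'
#' Each valid pixel receives the arithmetic mean of the values of the
#' voxels mapping into it; pixels with no voxel are \code{NA}.
#'
#' @param values numeric vector, one value per voxel of \code{proj} (in
#'   the same order as \code{voxelIds(proj)}).
#' @param proj a [FlatProjection-class].
#' @return a [PixelField-class].
#' @export
flattenField <- function(values, proj) {
    if (length(values) != nVoxels(proj))
        stop("need exactly one value per voxel of the projection")
    if (anyNA(values))
        stop("voxel values must not contain NA")
    m <- matrix(NA_real_, proj@dims[1L], proj@dims[2L])
    idx <- pixelIndex(proj)
    sums <- rowsum(values, idx)
    counts <- rowsum(rep(1, length(idx)), idx)
    m[as.integer(rownames(sums))] <- sums / counts
    new("PixelField", values = m, dims = proj@dims)
}

#' Transfer per-pixel labels back to voxels
#'
#' Every voxel inherits the label of its pixel ("unflattening").
#'
#' @param labels integer matrix of per-pixel labels (full grid, \code{NA}
#'   allowed only on invalid pixels).
#' @param proj a [FlatProjection-class].
#' @return integer vector of per-voxel labels, parallel to
#'   \code{voxelIds(proj)}.
#' @export
unflattenLabels <- function(labels, proj) {
    idx <- pixelIndex(proj)
    out <- labels[idx]
    if (anyNA(out))
        stop("every valid pixel must carry a label")
    as.integer(out)
}

#' Within-pixel to across-pixel spread ratio
#'
#' Ratio of the mean within-pixel standard deviation of a per-voxel
#' quantity to the standard deviation of the per-pixel means across a
#' region. Small values indicate that flattening loses little
#' information (voxel columns are internally homogeneous).
#'
#' @param values per-voxel numeric vector.
#' @param proj a [FlatProjection-class].
#' @param region optional logical matrix selecting the pixels to use;
#'   defaults to all valid pixels.
#' @return the nonnegative ratio, or \code{NA} (with attribute
#'   \code{"undefined"}) when the across-pixel variance is zero.
#' @export
withinPixelSpreadRatio <- function(values, proj, region = validPixelMask(proj)) {
    idx <- pixelIndex(proj)
    inRegion <- region[idx]
    rm <- split(values[inRegion], idx[inRegion])
    if (length(rm) < 2L)
        stop("region must contain at least 2 valid pixels")
    means <- vapply(rm, mean, numeric(1))
    sds <- vapply(rm, function(v) if (length(v) > 1L) sd(v) else 0, numeric(1))
    denom <- sd(means)
    if (denom == 0) {
        out <- NA_real_
        attr(out, "undefined") <- TRUE
        return(out)
    }
    mean(sds) / denom
}
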