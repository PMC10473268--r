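#' @import methods
#' @importFrom stats hclust cutree as.dist sd runif quantile predict dist median
#' @importFrom utils head read.csv write.csv
NULL

#' Voxelized connectome
#'
#' A directed connection-strength matrix between voxels of a 3D grid,
#' together with the integer grid position of every voxel. Row/column
#' \code{i} of \code{connectivity} corresponds to voxel
#' \code{voxelIds[i]}. Only the intracortical mode is supported: the set
#' of source voxels equals the set of target voxels.
#'
#' @slot voxelIds integer vector of voxel identifiers (unique).
#' @slot coords integer matrix, one row per voxel, columns \code{i,j,k}
#'   (0-based grid positions).
#' @slot connectivity numeric matrix, \code{connectivity[i, j]} is the
#'   strength of the connection from voxel \code{i} to voxel \code{j};
#'   nonnegative.
#'
#' @export
setClass("VoxelizedConnectome",
    representation(
        voxelIds = "integer",
        coords = "matrix",
        connectivity = "matrix"
    )
)

setValidity("VoxelizedConnectome", function(object) {
    n <- length(object@voxelIds)
    msg <- character()
    if (anyDuplicated(object@voxelIds))
        msg <- c(msg, "voxel ids must be unique")
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
        msg <- c(msg, "coords must be an n x 3 matrix")
    if (nrow(object@connectivity) != n || ncol(object@connectivity) != n)
        msg <- c(msg, "connectivity must be n x n")
    if (n > 0 && min(object@connectivity) < 0)
        msg <- c(msg, "connectivity must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Flat projection of voxels onto a 2D pixel grid
#'
#' A many-to-one map from voxels to pixels of a 2D grid, used as the
#' working view in which gradients and borders are computed. Pixel
#' coordinates are 0-based; \code{x} indexes the first grid axis and
#' \code{y} the second. Pixels receiving no voxel are invalid and are
#' excluded from every downstream computation.
#'
#' @slot voxelIds integer vector, voxel identifiers.
#' @slot pixelX,pixelY integer vectors, per-voxel pixel coordinates
#'   (0-based).
#' @slot dims integer of length 2, pixel grid extent \code{c(nx, ny)}.
#'
#' @export
setClass("FlatProjection",
    representation(
        voxelIds = "integer",
        pixelX = "integer",
        pixelY = "integer",
        dims = "integer"
    )
)

setValidity("FlatProjection", function(object) {
    n <- length(object@voxelIds)
    msg <- character()
    if (length(object@pixelX) != n || length(object@pixelY) != n)
        msg <- c(msg, "pixelX/pixelY must match voxelIds in length")
    if (length(object@dims) != 2L || any(object@dims < 1L))
        msg <- c(msg, "dims must be two positive integers")
    if (anyDuplicated(object@voxelIds))
        msg <- c(msg, "voxel ids must be unique")
    if (n > 0 && (min(object@pixelX) < 0L || min(object@pixelY) < 0L ||
            max(object@pixelX) >= object@dims[1L] ||
            max(object@pixelY) >= object@dims[2L]))
        msg <- c(msg, "pixel coordinates fall outside the declared grid extent")
    if (length(msg)) msg else TRUE
})

#' Per-pixel scalar field
#'
#' Holds one real value per valid pixel of a [FlatProjection-class],
#' stored as a full-grid matrix with \code{NA} on invalid pixels.
#'
#' @slot values numeric matrix \code{nx x ny}; \code{NA} = invalid pixel.
#' @slot dims integer of length 2.
#'
#' @export
setClass("PixelField",
    representation(values = "matrix", dims = "integer")
)

setValidity("PixelField", function(object) {
    if (!all(dim(object@values) == object@dims))
        "values matrix must have dimensions dims" else TRUE
})

#' Per-pixel 2D gradient field
#'
#' The finite-difference gradient of a [PixelField-class] along the two
#' pixel axes, plus the normalized (unit-length) variant. Entries are
#' \code{NA} where the gradient is undefined (no valid neighbor on an
#' axis, or zero-length raw vector for the normalized variant).
#'
#' @slot gx,gy numeric matrices, raw gradient components (per-pixel units).
#' @slot nx,ny numeric matrices, unit-length gradient components.
#'
#' @export
setClass("GradientField",
    representation(gx = "matrix", gy = "matrix", nx = "matrix", ny = "matrix")
)

#' Border map from convolved gradient directions
#'
#' Per-pixel length of the kernel-smoothed unit gradient field and the
#' boolean border flag (length strictly below the threshold). A reversal
#' makes oppositely oriented unit vectors cancel in the convolution,
#' shortening the result.
#'
#' @slot length numeric matrix in \code{[0, 1]} (NA outside the region).
#' @slot border logical matrix.
#' @slot kernelWidth numeric, full width at half maximum in pixels.
#' @slot threshold numeric, border threshold on the convolved length.
#'
#' @export
setClass("BorderMap",
    representation(
        length = "matrix",
        border = "matrix",
        kernelWidth = "numeric",
        threshold = "numeric"
    )
)

#' Diffusion embedding result
#'
#' Coordinates of each voxel in the strongest diffusion components of the
#' Fokker-Planck-normalized transition matrix, eigenvector columns scaled
#' by eigenvalue^t. The trivial stationary component is dropped before
#' numbering; component 1 is the strongest retained one. Signs are
#' arbitrary (fixed deterministically by making the largest-magnitude
#' entry positive).
#'
#' @slot coordinates numeric matrix, n voxels x k components.
#' @slot strengths numeric vector, per-component strength lambda^t,
#'   non-increasing.
#' @slot voxelIds integer vector of the embedded voxels (disconnected
#'   voxels are removed before embedding).
#' @slot t numeric diffusion time (1).
#' @slot alpha numeric anisotropy normalization parameter (0.5, embodied
#'   in the symmetric normalization of the transition matrix).
#'
#' @export
setClass("EmbeddingResult",
    representation(
        coordinates = "matrix",
        strengths = "numeric",
        voxelIds = "integer",
        t = "numeric",
        alpha = "numeric"
    )
)

setValidity("EmbeddingResult", function(object) {
    msg <- character()
    if (length(object@strengths) != ncol(object@coordinates))
        msg <- c(msg, "one strength per component required")
    if (is.unsorted(rev(object@strengths)))
        msg <- c(msg, "strengths must be non-increasing")
    if (nrow(object@coordinates) != length(object@voxelIds))
        msg <- c(msg, "one coordinate row per voxel required")
    if (length(msg)) msg else TRUE
})

#' Parcellation of a flat view
#'
#' A partition of the valid pixels (and, through the projection, the
#' voxels) into labeled regions, plus the hierarchy tree accumulated by
#' recursive splitting. Label 0 is reserved for unlabeled pixels; final
#' parcellations have strictly positive labels on every valid pixel.
#'
#' @slot labels integer matrix \code{nx x ny}; \code{NA} on invalid pixels.
#' @slot voxelLabels integer vector, per-voxel labels (parallel to
#'   \code{voxelIds}).
#' @slot voxelIds integer vector.
#' @slot hierarchy data.frame with columns \code{id, parent, level,
#'   nPixels, gd, ri, leaf, atomic, method, component}; one row per
#'   region node (\code{parent} = NA for the root).
#'
#' @export
setClass("Parcellation",
    representation(
        labels = "matrix",
        voxelLabels = "integer",
        voxelIds = "integer",
        hierarchy = "data.frame"
    )
)

setValidity("Parcellation", function(object) {
    msg <- character()
    if (length(object@voxelLabels) &&
            length(object@voxelLabels) != length(object@voxelIds))
        msg <- c(msg, "voxelLabels must be parallel to voxelIds")
    if (length(msg)) msg else TRUE
})

#' Synthetic toy-model connectome with ground truth
#'
#' A generated [VoxelizedConnectome-class] bundled with its flat
#' projection, the ground-truth parcellation labels, the ground-truth
#' hierarchy, and the generator parameters.
#'
#' @slot connectome a [VoxelizedConnectome-class].
#' @slot projection a [FlatProjection-class] (depth axis projected out).
#' @slot truth a [Parcellation-class] holding the ground-truth labels and
#'   hierarchy.
#' @slot model character, one of \code{"reversing_hierarchy"},
#'   \code{"node_distance"}, \code{"random_split"}.
#' @slot phi numeric, uniform noise amplitude.
#' @slot seed integer seed used for generation.
#' @slot params list of model-specific parameters.
#'
#' @export
setClass("ToyModel",
    representation(
        connectome = "VoxelizedConnectome",
        projection = "FlatProjection",
        truth = "Parcellation",
        model = "character",
        phi = "numeric",
        seed = "integer",
        params = "list"
    )
)
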