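## Cosine-distance-clustering splitter.
##
## For every pair of region pixels, the weighted sum over components of
## the cosine similarity of their unit gradient vectors is computed,
## converted to a distance by subtraction from the maximum attainable
## value (the sum of the weights), and clustered with HDBSCAN. Weights
## are the component strengths normalized to the strongest.

#' Weighted gradient cosine distance matrix
#'
#' \code{S(i, j) = sum_n w_n (g_n(i) . g_n(j))} over components,
#' \code{D = sum_n w_n - S}. Pixels with an undefined gradient in any
#' component are excluded.
#'
#' @param grads list of [GradientField-class] objects (one per component).
#' @param weights numeric component weights.
#' @param region logical matrix of region pixels.
#' @return list with \code{dist} (symmetric matrix over usable pixels),
#'   \code{pixels} (0-based coordinates), \code{usable} (logical matrix of
#'   the pixels included), \code{wsum} (sum of weights).
#' @export
cosineDistanceMatrix <- function(grads, weights, region) {
    stopifnot(length(grads) == length(weights))
    usable <- region
    for (g in grads) usable <- usable & definedGradientMask(g)
    if (!any(usable))
        stop("no pixel has defined gradients in every component")
    npix <- sum(usable)
    S <- matrix(0, npix, npix)
    for (j in seq_along(grads)) {
        G <- cbind(grads[[j]]@nx[usable], grads[[j]]@ny[usable])
        S <- S + weights[j] * tcrossprod(G)
    }
    D <- sum(weights) - S
    D[D < 0] <- 0  # guard rounding
    diag(D) <- 0
    xy <- which(usable, arr.ind = TRUE)
    list(dist = D, pixels = cbind(x = xy[, 1L] - 1L, y = xy[, 2L] - 1L),
         usable = usable, wsum = sum(weights))
}

#' Density split of a cosine distance matrix
#'
#' Runs HDBSCAN on the precomputed distances; points HDBSCAN rejects
#' keep the explicit outlier label 0 and are resolved by
#' post-processing.
#'
#' @param D symmetric distance matrix.
#' @param minClusterSize HDBSCAN minimum cluster size; the default
#'   \code{max(10, 1\% of pixels)} suppresses speckle.
#' @return integer labels (0 = outlier); all zeros or a single cluster
#'   signal "no split".
#' @export
densitySplit <- function(D, minClusterSize = max(10L, ceiling(0.01 * nrow(D)))) {
    hdbscan(D, minClusterSize = minClusterSize)
}

#' Split a region by cosine distance clustering
#'
#' Flattens all embedded components onto the region's pixels, computes
#' the weighted cosine distance matrix of their unit gradients, and
#' clusters it with HDBSCAN. Pixels with undefined gradients and HDBSCAN
#' outliers are returned unlabeled (0) for post-processing.
#'
#' @param emb an [EmbeddingResult-class] of the region's voxels.
#' @param proj a [FlatProjection-class] restricted to those voxels.
#' @param region logical matrix of region pixels.
#' @param minClusterSize see \code{\link{densitySplit}}.
#' @param smoothWidth FWHM (pixels) of the Gaussian pre-smoothing applied
#'   to each flattened component before differentiation.
#' @return list with \code{labels} (integer matrix, 0 = unlabeled, NA
#'   outside region), \code{component} (NA; all components contribute),
#'   \code{atomic} (logical).
#' @export
cosineSplit <- function(emb, proj, region = validPixelMask(proj),
                        minClusterSize = NULL, smoothWidth = 5) {
    nc <- ncol(emb@coordinates)
    grads <- vector("list", nc)
    for (j in seq_len(nc)) {
        fld <- flattenField(emb@coordinates[, j], proj)
        v <- fld@values
        v[!region] <- NA_real_
        grads[[j]] <- pixelGradient(v, smooth = smoothWidth)
    }
    w <- componentWeights(emb)
    cd <- tryCatch(cosineDistanceMatrix(grads, w, region),
                   error = function(e) NULL)
    lab <- matrix(NA_integer_, nrow(region), ncol(region))
    lab[region] <- 0L
    if (is.null(cd))
        return(list(labels = NULL, component = NA_integer_, atomic = TRUE))
    mcs <- if (is.null(minClusterSize))
        max(10L, ceiling(0.01 * nrow(cd$dist))) else minClusterSize
    labs <- densitySplit(cd$dist, minClusterSize = mcs)
    if (length(unique(labs[labs > 0])) < 2L)
        return(list(labels = NULL, component = NA_integer_, atomic = TRUE))
    idx <- cd$pixels[, 1L] + 1L + nrow(region) * cd$pixels[, 2L]
    lab[idx] <- labs
    ## the split must improve the strength-weighted reversal index: the
    ## mean over proposed clusters must fall below the whole-region
    ## value, else the region holds no resolvable direction structure
    weightedRi <- function(reg) {
        ris <- vapply(grads, function(g) {
            r <- reversalIndexComponent(g, reg)
            if (is.na(r)) 0 else r
        }, numeric(1))
        sum(w * ris) / sum(w)
    }
    parentRi <- weightedRi(region)
    subs <- sort(unique(labs[labs > 0]))
    score <- mean(vapply(subs, function(l) {
        m <- matrix(FALSE, nrow(region), ncol(region))
        m[idx[labs == l]] <- TRUE
        weightedRi(m)
    }, numeric(1)))
    if (!is.na(parentRi) && !is.na(score) && score >= parentRi)
        return(list(labels = NULL, component = NA_integer_, atomic = TRUE))
    list(labels = lab, component = NA_integer_, atomic = FALSE,
         score = score, parentRi = parentRi)
}
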