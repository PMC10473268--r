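## Reversal-detection splitter.
##
## A border map flags pixels where the kernel-smoothed unit gradient
## field shortens (opposing orientations cancel); pixel-pair distances
## count border pixels crossed on the shortest 8-neighborhood path
## (Dijkstra, edge weight 1 if either endpoint is a border pixel); Ward
## linkage on those distances with silhouette-based model selection
## gives candidate splits, one per component; the component minimizing
## the mean per-subregion reversal index wins.

gaussianKernel <- function(width, shape = c("gaussian", "uniform")) {
    shape <- match.arg(shape)
    if (shape == "uniform") {
        r <- floor(width / 2)
        k <- matrix(1, 2L * r + 1L, 2L * r + 1L)
        return(k / sum(k))
    }
    sigma <- width / (2 * sqrt(2 * log(2)))  # width = FWHM
    r <- ceiling(3 * sigma)
    ax <- seq.int(-r, r)
    g <- exp(-ax^2 / (2 * sigma^2))
    k <- outer(g, g)
    k / sum(k)
}

## convolve a masked matrix with kernel, renormalizing kernel mass over
## the valid (non-NA) support so mask edges do not shorten vectors
maskedConvolve <- function(m, kernel) {
    d <- dim(m)
    r <- (dim(kernel) - 1L) %/% 2L
    valid <- !is.na(m)
    mz <- m
    mz[!valid] <- 0
    acc <- matrix(0, d[1L], d[2L])
    wacc <- matrix(0, d[1L], d[2L])
    for (dx in seq.int(-r[1L], r[1L])) {
        xs <- seq_len(d[1L]) + dx
        okx <- xs >= 1L & xs <= d[1L]
        for (dy in seq.int(-r[2L], r[2L])) {
            w <- kernel[dx + r[1L] + 1L, dy + r[2L] + 1L]
            ys <- seq_len(d[2L]) + dy
            oky <- ys >= 1L & ys <= d[2L]
            acc[okx, oky] <- acc[okx, oky] +
                w * mz[xs[okx], ys[oky], drop = FALSE]
            wacc[okx, oky] <- wacc[okx, oky] +
                w * valid[xs[okx], ys[oky], drop = FALSE]
        }
    }
    out <- acc / wacc
    out[!valid] <- NA_real_
    out
}

#' Border map of a normalized gradient field
#'
#' Convolves the unit gradient field componentwise with a unit-sum 2D
#' kernel (Gaussian by default, full width at half maximum
#' \code{kernelWidth} pixels, truncated at 3 sigma, renormalized over the
#' valid support near mask edges) and flags pixels whose convolved
#' vector is strictly shorter than \code{threshold} as potential border.
#'
#' @param grad a [GradientField-class] (normalized components are used).
#' @param kernelWidth kernel width in pixels (default 5).
#' @param threshold border threshold on the convolved length (default
#'   0.97).
#' @param shape kernel shape, \code{"gaussian"} (default) or
#'   \code{"uniform"}.
#' @return a [BorderMap-class]. If the region's bounding box is smaller
#'   than the kernel width on both axes, a warning is issued and no
#'   pixel is flagged.
#' @export
borderMap <- function(grad, kernelWidth = 5, threshold = 0.97,
                      shape = c("gaussian", "uniform")) {
    shape <- match.arg(shape)
    ok <- definedGradientMask(grad)
    len <- matrix(NA_real_, nrow(grad@nx), ncol(grad@nx))
    border <- matrix(FALSE, nrow(grad@nx), ncol(grad@nx))
    if (any(ok)) {
        w <- which(ok, arr.ind = TRUE)
        bbox <- c(diff(range(w[, 1L])) + 1L, diff(range(w[, 2L])) + 1L)
        if (all(bbox < kernelWidth)) {
            warning("region smaller than the kernel width; no border detected")
            len[ok] <- 1
        } else {
            kern <- gaussianKernel(kernelWidth, shape)
            cx <- maskedConvolve(grad@nx, kern)
            cy <- maskedConvolve(grad@ny, kern)
            len <- sqrt(cx^2 + cy^2)
            border <- !is.na(len) & len < threshold
        }
    }
    new("BorderMap", length = len, border = border,
        kernelWidth = kernelWidth, threshold = threshold)
}

## 8-neighborhood edge list of a set of pixels (linear indices into an
## nx x ny grid); returns two-column matrix of positions into `cells`
gridEdges <- function(mask) {
    d <- dim(mask)
    id <- matrix(NA_integer_, d[1L], d[2L])
    cells <- which(mask)
    id[cells] <- seq_along(cells)
    xy <- which(mask, arr.ind = TRUE)
    from <- integer(0); to <- integer(0)
    for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
        nx <- xy[, 1L] + off[1L]
        ny <- xy[, 2L] + off[2L]
        ok <- nx >= 1L & nx <= d[1L] & ny >= 1L & ny <= d[2L]
        nb <- id[cbind(nx[ok], ny[ok])]
        keep <- !is.na(nb)
        from <- c(from, which(ok)[keep])
        to <- c(to, nb[keep])
    }
    cbind(from, to)
}

#' Border-crossing distances between region pixels
#'
#' Builds the 8-neighborhood pixel graph of the region, weights each
#' edge 1 if either endpoint is flagged as border and 0 otherwise, and
#' returns all-pairs shortest-path distances (Dijkstra). The distance is
#' 0 exactly for pixel pairs connected by a border-free path;
#' disconnected pairs get \code{Inf}.
#'
#' @param bmap a [BorderMap-class].
#' @param region logical matrix of the region's pixels; defaults to all
#'   pixels with a defined convolved length.
#' @return list with \code{dist} (symmetric matrix), \code{pixels}
#'   (two-column matrix of 0-based pixel coordinates), and \code{border}
#'   (logical vector parallel to the pixels).
#' @export
borderDistances <- function(bmap, region = !is.na(bmap@length)) {
    cells <- which(region)
    xy <- which(region, arr.ind = TRUE)
    isBorder <- bmap@border[cells]
    edges <- gridEdges(region)
    w <- as.numeric(isBorder[edges[, 1L]] | isBorder[edges[, 2L]])
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(cells) - igraph::vcount(g)))
    D <- igraph::distances(g, weights = w, algorithm = "dijkstra")
    dimnames(D) <- NULL
    list(dist = D, pixels = cbind(x = xy[, 1L] - 1L, y = xy[, 2L] - 1L),
         border = isBorder)
}

#' Ward clustering with silhouette model selection
#'
#' Ward linkage on a precomputed distance matrix; the number of clusters
#' is chosen in \code{[kMin, kMax]} by maximizing the mean silhouette
#' width computed on the same distances (ties towards fewer clusters).
#' All-zero distances yield a single cluster ("no split").
#'
#' @param D symmetric distance matrix (\code{Inf} allowed for
#'   disconnected pairs; replaced by a large finite surrogate).
#' @param kMin,kMax cluster-count search range (defaults 2 and 10).
#' @return integer vector of cluster labels (all 1 when no split).
#' @export
wardSilhouette <- function(D, kMin = 2L, kMax = 10L) {
    n <- nrow(D)
    if (n < kMin + 1L || all(D[upper.tri(D)] == 0))
        return(rep(1L, n))
    if (any(!is.finite(D))) {
        big <- 2 * max(D[is.finite(D)]) + n
        D[!is.finite(D)] <- big
    }
    hc <- hclust(as.dist(D), method = "ward.D2")
    ks <- seq.int(kMin, min(kMax, n - 1L))
    best <- NULL; bestSil <- -Inf
    for (k in ks) {
        labs <- cutree(hc, k = k)
        if (length(unique(labs)) < 2L) next
        sil <- cluster::silhouette(labs, dmatrix = D)
        msil <- mean(sil[, "sil_width"])
        if (is.finite(msil) && msil > bestSil + 1e-12) {
            bestSil <- msil
            best <- labs
        }
    }
    if (is.null(best)) rep(1L, n) else as.integer(best)
}

## score of a candidate split for component selection: mean over
## subregions of ri(omega, kappa), i.e. sum_kappa ri / m
splitScore <- function(grad, labelMatrix) {
    labs <- unique(labelMatrix[!is.na(labelMatrix) & labelMatrix > 0])
    m <- length(labs)
    if (m == 0L) return(Inf)
    ris <- vapply(labs, function(l) {
        r <- reversalIndexComponent(grad, region = !is.na(labelMatrix) &
                                        labelMatrix == l)
        if (is.na(r)) 0 else r
    }, numeric(1))
    sum(ris) / m
}

#' Select the splitting component
#'
#' Given one candidate labeling per component, picks the component
#' minimizing the mean per-subregion reversal index of its own gradient
#' (sum over subregions of ri divided by the number of subregions).
#' Ties break towards the lower component index.
#'
#' @param candidates list of integer label matrices, one per component
#'   (0/NA = unlabeled).
#' @param grads list of [GradientField-class] objects, parallel to
#'   \code{candidates}.
#' @return integer index of the winning component.
#' @export
selectComponent <- function(candidates, grads) {
    stopifnot(length(candidates) == length(grads), length(candidates) > 0)
    scores <- mapply(function(lab, g) splitScore(g, lab),
                     candidates, grads)
    which.min(scores)  # which.min takes the first (lowest index) on ties
}

#' Split a region by reversal detection
#'
#' For each embedded component: flatten onto the region's pixels, take
#' the normalized gradient, build the border map, compute border-crossing
#' distances, cluster them with Ward + silhouette, unlabel the border
#' pixels and post-process into a candidate parcellation. The component
#' whose resulting parcellation minimizes the mean per-subregion
#' reversal index of its own gradient is selected (ties to the lower
#' index); reversal-free components propose no split and are not
#' eligible.
#'
#' @param emb an [EmbeddingResult-class] of the region's voxels.
#' @param proj a [FlatProjection-class] restricted to those voxels.
#' @param region logical matrix of the region's pixels; defaults to the
#'   valid pixels of \code{proj}.
#' @param kernelWidth,threshold,shape see \code{\link{borderMap}}.
#' @param kMin,kMax see \code{\link{wardSilhouette}}.
#' @param minSize minimum region size used when post-processing the
#'   candidate parcellations.
#' @param smoothWidth FWHM (pixels) of the Gaussian pre-smoothing applied
#'   to each flattened component before differentiation (default: the
#'   border kernel width).
#' @return list with \code{labels} (integer label matrix of the winning
#'   post-processed parcellation; NA outside region), \code{component}
#'   (selected index, NA when atomic), \code{atomic} (logical).
#' @export
reversalSplit <- function(emb, proj, region = validPixelMask(proj),
                          kernelWidth = 5, threshold = 0.97,
                          shape = "gaussian", kMin = 2L, kMax = 10L,
                          minSize = 10L, smoothWidth = kernelWidth) {
    nc <- ncol(emb@coordinates)
    cells <- which(region)
    candidates <- vector("list", nc)  # post-processed candidate labels
    grads <- vector("list", nc)
    for (j in seq_len(nc)) {
        fld <- flattenField(emb@coordinates[, j], proj)
        v <- fld@values
        v[!region] <- NA_real_
        grad <- pixelGradient(v, smooth = smoothWidth)
        grads[[j]] <- grad
        if (!any(definedGradientMask(grad))) next
        bm <- withCallingHandlers(
            borderMap(grad, kernelWidth, threshold, shape),
            warning = function(w) invokeRestart("muffleWarning"))
        bd <- borderDistances(bm, region = region)
        labs <- wardSilhouette(bd$dist, kMin, kMax)
        if (length(unique(labs)) < 2L) next
        lab <- matrix(NA_integer_, nrow(region), ncol(region))
        idx <- bd$pixels[, 1L] + 1L + nrow(region) * bd$pixels[, 2L]
        lab[idx] <- labs
        lab[idx[bd$border]] <- 0L  # border pixels provisional
        post <- tryCatch(postProcess(lab, minSize = minSize),
                         error = function(e) NULL)
        if (is.null(post)) next
        if (length(unique(post[!is.na(post)])) < 2L) next
        candidates[[j]] <- post
    }
    splitters <- which(!vapply(candidates, is.null, logical(1)))
    if (!length(splitters))
        return(list(labels = NULL, component = NA_integer_, atomic = TRUE))
    best <- splitters[selectComponent(candidates[splitters],
                                      grads[splitters])]
    ## a split must improve the reversal index of its component: the
    ## mean per-subregion ri must fall below the whole-region ri, else
    ## the region holds no resolvable reversal structure and stays whole
    score <- splitScore(grads[[best]], candidates[[best]])
    parentRi <- reversalIndexComponent(grads[[best]], region = region)
    if (!is.na(parentRi) && !is.na(score) && score >= parentRi)
        return(list(labels = NULL, component = NA_integer_, atomic = TRUE))
    list(labels = candidates[[best]], component = best, atomic = FALSE,
         score = score, parentRi = parentRi)
}
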