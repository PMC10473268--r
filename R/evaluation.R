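## Parcellation-evaluation statistics: entropy, mutual information,
## uncertainty coefficient, modularity, intersection-over-union, and the
## two random-control parcellation generators (Voronoi seeds and random
## line splits). Natural logarithms are used throughout; the uncertainty
## coefficient is a ratio, so the base cancels.

asLabelVector <- function(x) {
    if (is(x, "Parcellation")) {
        v <- x@labels[!is.na(x@labels)]
    } else if (is.matrix(x)) {
        v <- x[!is.na(x)]
    } else {
        v <- x[!is.na(x)]
    }
    as.integer(v)
}

#' Entropy of a parcellation's label distribution
#'
#' \code{H = -sum p_i log p_i} with \code{p_i = n_i / N}, natural log.
#'
#' @param x label vector, label matrix, or [Parcellation-class].
#' @return entropy in nats.
#' @export
labelEntropy <- function(x) {
    p <- table(asLabelVector(x))
    p <- p / sum(p)
    -sum(p * log(p))
}

#' Mutual information of two parcellations
#'
#' \code{I = sum_ij p_ij log(p_ij / (p_i p_j))}; zero-probability joint
#' cells contribute 0. Both parcellations must label the same elements
#' in the same order.
#'
#' @param x,y label vectors/matrices/[Parcellation-class] objects on the
#'   same element set.
#' @return mutual information in nats (symmetric, nonnegative).
#' @export
mutualInformation <- function(x, y) {
    lx <- asLabelVector(x); ly <- asLabelVector(y)
    if (length(lx) != length(ly))
        stop("parcellations must be defined on the same element set")
    joint <- table(lx, ly) / length(lx)
    px <- rowSums(joint); py <- colSums(joint)
    ratio <- joint / outer(px, py)
    sum(joint[joint > 0] * log(ratio[joint > 0]))
}

#' Uncertainty coefficient U(X; Y)
#'
#' Mutual information normalized by the entropy of \code{x}:
#' \code{U = I(X; Y) / H(X)}, in \code{[0, 1]}; 1 when the parcellations
#' are identical, 0 when statistically independent. Asymmetric in its
#' arguments.
#'
#' @inheritParams mutualInformation
#' @return U in \code{[0, 1]}; \code{NA} (flagged undefined) when
#'   \code{x} has a single region.
#' @export
uncertaintyCoefficient <- function(x, y) {
    h <- labelEntropy(x)
    if (h == 0) {
        out <- NA_real_
        attr(out, "undefined") <- TRUE
        return(out)
    }
    mutualInformation(x, y) / h
}

#' Modularity of a parcellation with respect to a connectivity matrix
#'
#' The fraction of total connection strength between same-region element
#' pairs minus the fraction of same-region element pairs,
#' \code{gamma_M(X) - phi(X)}; both sums include the diagonal. In
#' \code{[-1, 1]}; 0 in expectation when connectivity is independent of
#' the parcellation.
#'
#' @param x label vector/matrix/[Parcellation-class].
#' @param M nonnegative connectivity (or similarity) matrix over the same
#'   elements.
#' @return modularity value; \code{NA} (flagged) when \code{M} sums to 0.
#' @export
labelModularity <- function(x, M) {
    labs <- asLabelVector(x)
    if (length(labs) != nrow(M) || nrow(M) != ncol(M))
        stop("M must be square over the elements of the parcellation")
    tot <- sum(M)
    if (tot == 0) {
        out <- NA_real_
        attr(out, "undefined") <- TRUE
        return(out)
    }
    same <- outer(labs, labs, `==`)
    gamma <- sum(M[same]) / tot
    n <- table(labs)
    phi <- sum(n^2) / length(labs)^2
    gamma - phi
}

#' Intersection-over-union matrix of two parcellations
#'
#' Entry \code{(i, j)} is \code{|r_i ∩ s_j| / |r_i ∪ s_j|} for
#' region i of \code{x} and region j of \code{y}.
#'
#' @inheritParams mutualInformation
#' @return numeric matrix, rows = regions of \code{x}, columns = regions
#'   of \code{y}.
#' @export
iouMatrix <- function(x, y) {
    lx <- asLabelVector(x); ly <- asLabelVector(y)
    if (length(lx) != length(ly))
        stop("parcellations must be defined on the same element set")
    inter <- table(lx, ly)
    nx <- rowSums(inter); ny <- colSums(inter)
    uni <- outer(nx, ny, `+`) - inter
    out <- inter / uni
    out[uni == 0] <- 0
    unclass(as.matrix(out))
}

## ---- random control parcellations ------------------------------------------

## Voronoi control: seeds uniform in the bounding box of valid pixels;
## seeds owning zero pixels are redrawn
voronoiParcellation <- function(mask, nRegions) {
    xy <- which(mask, arr.ind = TRUE)
    lo <- apply(xy, 2L, min); hi <- apply(xy, 2L, max)
    for (attempt in seq_len(1000L)) {
        seeds <- cbind(runif(nRegions, lo[1L], hi[1L]),
                       runif(nRegions, lo[2L], hi[2L]))
        d2 <- outer(xy[, 1L], seeds[, 1L], `-`)^2 +
              outer(xy[, 2L], seeds[, 2L], `-`)^2
        assign <- max.col(-d2, ties.method = "first")
        if (length(unique(assign)) == nRegions) {
            lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
            lab[mask] <- assign
            return(lab)
        }
    }
    stop("could not place non-empty Voronoi seeds")
}

## random-line-split control on the flat mask, reusing the random-split
## geometry; splits the largest region until nRegions exist
randomSplitParcellation <- function(mask, nRegions) {
    xy <- which(mask, arr.ind = TRUE)
    n <- nrow(xy)
    regions <- list(list(idx = seq_len(n), theta = NA_real_))
    guard <- 0L
    while (length(regions) < nRegions) {
        guard <- guard + 1L
        if (guard > 1000L) stop("random split control failed to reach target")
        sizes <- vapply(regions, function(r) length(r$idx), integer(1))
        pick <- which.max(sizes)
        r <- regions[[pick]]
        if (sizes[pick] < 2L) stop("regions exhausted before target count")
        theta <- if (is.na(r$theta)) runif(1, 0, 2 * pi) else
            runif(1, r$theta + pi / 2 - 0.5, r$theta + pi / 2 + 0.5)
        sp <- splitByLine(xy[r$idx, , drop = FALSE], theta)
        if (!any(sp$side) || all(sp$side)) next
        regions[[pick]] <- list(idx = r$idx[sp$side], theta = theta)
        regions[[length(regions) + 1L]] <- list(idx = r$idx[!sp$side],
                                                theta = theta)
    }
    lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
    cells <- which(mask)
    for (i in seq_along(regions))
        lab[cells[regions[[i]]$idx]] <- i
    lab
}

#' Random control parcellations
#'
#' Generates spatially continuous random parcellations of the valid
#' pixels with a prescribed region count: half by nearest-random-seed
#' (Voronoi) assignment with seeds uniform in the bounding box (empty
#' seeds redrawn), half by recursive random line splits.
#'
#' @param mask logical matrix of valid pixels.
#' @param nRegions target region count (each control has exactly this
#'   many nonempty regions).
#' @param count total number of controls (default 100, half per
#'   algorithm).
#' @param seed integer seed.
#' @return list of integer label matrices.
#' @export
randomControls <- function(mask, nRegions, count = 100L, seed = 1L) {
    stopifnot(nRegions >= 1L)
    if (nRegions > sum(mask))
        stop("more regions requested than valid pixels")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    nv <- count %/% 2L
    out <- vector("list", count)
    for (i in seq_len(nv))
        out[[i]] <- voronoiParcellation(mask, nRegions)
    for (i in seq.int(nv + 1L, count))
        out[[i]] <- if (nRegions == 1L) {
            lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
            lab[mask] <- 1L
            lab
        } else randomSplitParcellation(mask, nRegions)
    out
}
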