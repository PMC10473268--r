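## Synthetic toy-model connectomes with ground truth.
##
## All three models live in a voxelized unit cube. The first grid axis
## (x) is the depth axis that the flat projection removes; the second
## and third axes (y, z) form the flat view. Hierarchy models split the
## cube along alternating flat axes (y, then z, then y, ...), prescribe
## a triangle-wave target alpha along the split axis (reversing at every
## internal region border) and the orthogonal flat coordinate as beta,
## and convert target distances to connection strengths with a Gaussian
## profile. Uniform noise in (-phi, phi) is added last; negative entries
## are clamped to 0 so that profiles remain valid.

## voxel grid over the unit cube; dims = c(depth, ny, nz)
voxelGrid <- function(dims) {
    g <- expand.grid(i = seq_len(dims[1L]) - 1L,
                     j = seq_len(dims[2L]) - 1L,
                     k = seq_len(dims[3L]) - 1L)
    as.matrix(g)
}

## unit-cube coordinate of a 0-based grid index (voxel centers)
unitCoord <- function(idx, extent) (idx + 0.5) / extent

## triangle wave with n half-periods over [0, 1]: continuous, spans
## [0, 1], reverses slope at every internal border u = i/n
triangleWave <- function(u, n) 2 * abs(u * n / 2 - round(u * n / 2))

#' Add uniform noise to a connectivity matrix
#'
#' Adds i.i.d. uniform(-phi, phi) noise to every entry and clamps
#' negative results to 0 (connection strengths must stay nonnegative for
#' profile normalization). The noise-free signal of the toy models has
#' maximum 1, so \code{phi} is the noise amplitude relative to the
#' strength of the signal.
#'
#' @param C numeric matrix.
#' @param phi noise amplitude; 0 returns \code{C} unchanged.
#' @param seed optional integer seed applied locally.
#' @return noisy matrix, same shape.
#' @export
addNoise <- function(C, phi, seed = NULL) {
    if (phi == 0) return(C)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    out <- C + matrix(runif(length(C), -phi, phi), nrow(C), ncol(C))
    out[out < 0] <- 0
    out
}

## per-split-generation target fields for the hierarchy models.
## generation g (1-based) splits along y when odd, z when even; the
## number of bands along that axis doubles each time it is revisited.
## "levels" in the exported generators counts tree levels including the
## root, so a model with `levels` has `levels - 1` split generations
## (levels = 3: two orthogonal binary splits, the quadrants of the unit
## cube).
levelSpec <- function(gen) {
    axis <- if (gen %% 2L == 1L) "y" else "z"
    nBands <- 2L^((gen + 1L) %/% 2L)
    list(axis = axis, nBands = nBands)
}

## strength matrix of one split generation per the target-distance rule
levelStrengths <- function(coords, dims, gen) {
    spec <- levelSpec(gen)
    uy <- unitCoord(coords[, 2L], dims[2L])
    uz <- unitCoord(coords[, 3L], dims[3L])
    if (spec$axis == "y") {
        alpha <- triangleWave(uy, spec$nBands)
        beta <- uz
    } else {
        alpha <- triangleWave(uz, spec$nBands)
        beta <- uy
    }
    S <- sqrt(outer(alpha, alpha, `-`)^2 + outer(beta, beta, `-`)^2)
    sigma <- 0.1 * max(S)
    exp(-S^2 / (2 * sigma^2))
}

## ground-truth leaf labels after `gens` alternating binary splits
hierarchyTruthLabels <- function(coords, dims, gens) {
    yBands <- 2L^ceiling(gens / 2)
    zBands <- 2L^floor(gens / 2)
    by <- pmin(floor(unitCoord(coords[, 2L], dims[2L]) * yBands), yBands - 1L)
    bz <- pmin(floor(unitCoord(coords[, 3L], dims[3L]) * zBands), zBands - 1L)
    as.integer(by * zBands + bz + 1L)
}

## ground-truth hierarchy data.frame (regions nested by split generation)
hierarchyTruthTree <- function(gens) {
    nodes <- data.frame(id = 1L, parent = NA_integer_, level = 0L)
    nextId <- 2L
    frontier <- 1L
    for (l in seq_len(gens)) {
        newFrontier <- integer(0)
        for (p in frontier) {
            for (i in 1:2) {
                nodes <- rbind(nodes, data.frame(id = nextId, parent = p,
                                                 level = l))
                newFrontier <- c(newFrontier, nextId)
                nextId <- nextId + 1L
            }
        }
        frontier <- newFrontier
    }
    nodes
}

## flat projection dropping the depth (first) axis
flatProjectionOf <- function(coords, dims) {
    FlatProjection(seq_len(nrow(coords)), coords[, 2L], coords[, 3L],
                   dims = dims[2:3])
}

truthParcellation <- function(labels, coords, dims, tree) {
    proj <- flatProjectionOf(coords, dims)
    m <- matrix(NA_integer_, dims[2L], dims[3L])
    m[pixelIndex(proj)] <- labels
    new("Parcellation", labels = m, voxelLabels = as.integer(labels),
        voxelIds = seq_len(nrow(coords)), hierarchy = tree)
}

#' Reversing-hierarchy toy model
#'
#' Hierarchically splits the unit cube along alternating flat axes into
#' equal bands; per level, target alpha is a triangle wave along the
#' split axis (reversing at every internal border) and beta the
#' orthogonal flat coordinate; the per-level Gaussian strength matrices
#' are combined by elementwise multiplication; uniform noise is added
#' last.
#'
#' @param levels depth of the region hierarchy including the root
#'   (default 3: two orthogonal binary splits, i.e. the four quadrants
#'   of the unit cube as leaves).
#' @param dims voxel grid \code{c(depth, ny, nz)}; default
#'   \code{c(4, 16, 16)}.
#' @param phi uniform noise amplitude.
#' @param seed integer seed.
#' @return a [ToyModel-class].
#' @export
reversingHierarchyModel <- function(levels = 3L, dims = c(4L, 16L, 16L),
                                    phi = 0.1, seed = 1L) {
    stopifnot(levels >= 2L)
    gens <- levels - 1L
    if (dims[2L] < 4L * 2L^(ceiling(gens / 2) - 1L) ||
        dims[3L] < 4L * max(1L, 2L^(floor(gens / 2) - 1L)))
        stop("grid too coarse to represent the deepest hierarchy level")
    coords <- voxelGrid(dims)
    ## each level matrix carries its own Eq.-13 noise; levels are then
    ## combined by elementwise multiplication
    C <- matrix(1, nrow(coords), nrow(coords))
    for (g in seq_len(gens))
        C <- C * addNoise(levelStrengths(coords, dims, g), phi,
                          seed = seed + g)
    labels <- hierarchyTruthLabels(coords, dims, gens)
    new("ToyModel",
        connectome = VoxelizedConnectome(C, coords),
        projection = flatProjectionOf(coords, dims),
        truth = truthParcellation(labels, coords, dims,
                                  hierarchyTruthTree(gens)),
        model = "reversing_hierarchy", phi = phi, seed = as.integer(seed),
        params = list(levels = levels, dims = dims))
}

## tree path distance between leaf regions of the alternating binary
## hierarchy with `gens` split generations; same-region pairs get 1 (a
## literal distance of 0 would be undefined as a divisor)
leafPathDistance <- function(gens) {
    yBands <- 2L^ceiling(gens / 2)
    zBands <- 2L^floor(gens / 2)
    nLeaf <- yBands * zBands
    ## recover the branch path of each leaf: splits alternate y, z, y, ...
    paths <- matrix(0L, nLeaf, gens)
    for (leaf in seq_len(nLeaf)) {
        by <- (leaf - 1L) %/% zBands
        bz <- (leaf - 1L) %% zBands
        yi <- 0L; zi <- 0L
        for (l in seq_len(gens)) {
            if (l %% 2L == 1L) {
                yi <- yi + 1L
                paths[leaf, l] <- (by %/% (yBands %/% 2L^yi)) %% 2L
            } else {
                zi <- zi + 1L
                paths[leaf, l] <- (bz %/% (zBands %/% 2L^zi)) %% 2L
            }
        }
    }
    D <- matrix(1, nLeaf, nLeaf)
    for (a in seq_len(nLeaf)) {
        for (b in seq_len(nLeaf)) {
            if (a == b) next
            shared <- 0L
            for (l in seq_len(gens)) {
                if (paths[a, l] == paths[b, l]) shared <- shared + 1L
                else break
            }
            D[a, b] <- 2L * (gens - shared)
        }
    }
    D
}

#' Node-distance toy model
#'
#' Builds the strength matrix of the deepest hierarchy level only, then
#' divides each entry by the hierarchy-tree path distance between the
#' ground-truth regions of its two voxels (within-region pairs use
#' divisor 1). Uniform noise is added last.
#'
#' @inheritParams reversingHierarchyModel
#' @return a [ToyModel-class].
#' @export
nodeDistanceModel <- function(levels = 3L, dims = c(4L, 16L, 16L),
                              phi = 0.1, seed = 1L) {
    stopifnot(levels >= 2L)
    gens <- levels - 1L
    coords <- voxelGrid(dims)
    C <- levelStrengths(coords, dims, gens)
    labels <- hierarchyTruthLabels(coords, dims, gens)
    ## noise enters the lowest-level matrix (Eq.-13 construction) and is
    ## then divided by the tree path distance along with the signal
    C <- addNoise(C, phi, seed = seed)
    D <- leafPathDistance(gens)
    C <- C / D[cbind(rep(labels, times = length(labels)),
                     rep(labels, each = length(labels)))]
    new("ToyModel",
        connectome = VoxelizedConnectome(C, coords),
        projection = flatProjectionOf(coords, dims),
        truth = truthParcellation(labels, coords, dims,
                                  hierarchyTruthTree(gens)),
        model = "node_distance", phi = phi, seed = as.integer(seed),
        params = list(levels = levels, dims = dims))
}

## ---- random-split model ----------------------------------------------------

## split a set of flat points (rows: x, y in pixel units) by a line with
## angle `theta` so that the smaller side holds a fraction in [0.4, 0.6]
splitByLine <- function(pts, theta) {
    nrm <- c(-sin(theta), cos(theta))
    s <- pts %*% nrm
    f <- runif(1, 0.4, 0.6)
    cut <- quantile(s, probs = f, names = FALSE, type = 7)
    side <- as.vector(s <= cut)
    ## anchor point on the line: midpoint of projections at the cut
    anchor <- colMeans(pts) + (cut - sum(colMeans(pts) * nrm)) * nrm
    list(side = side, normal = nrm, anchor = anchor, theta = theta)
}

mirrorPoints <- function(pts, normal, anchor) {
    s <- sweep(pts, 2L, anchor) %*% normal
    pts - 2 * as.vector(s) %*% t(normal)
}

#' Random-split toy model
#'
#' Recursively splits the flat view at randomly drawn lines (first angle
#' uniform on \code{[0, 2*pi)}, each subsequent angle uniform within 0.5
#' rad of the previous split's angle plus 90 degrees; the line placed so
#' the areas split 40-60 at worst). Each line defines a mirror: the
#' strength of connections from a point P is
#' \code{Pi(L) * exp(-d(P', Q) / rho(L)) + 1}, where P' is the mirror
#' image of P, \code{Pi = 1/max(4 - L, 1)}, \code{rho = 25 exp(-L/3)},
#' and L the 1-based hierarchy level of the line. Contributions from the
#' ancestor lines of the source point are summed, the matrix is
#' symmetrized, and uniform noise is added.
#'
#' @param maxRegions stop once this many regions exist (default 8).
#' @param minRegionSize stop splitting regions below this pixel count
#'   (default 50).
#' @param dims voxel grid \code{c(depth, ny, nz)}; default
#'   \code{c(2, 24, 24)}.
#' @param phi uniform noise amplitude (default 0.5).
#' @param seed integer seed.
#' @return a [ToyModel-class]; the hierarchy of splits is recorded in the
#'   ground-truth parcellation.
#' @export
randomSplitModel <- function(maxRegions = 8L, minRegionSize = 50L,
                             dims = c(2L, 24L, 24L), phi = 0.5, seed = 1L) {
    stopifnot(maxRegions >= 1L, minRegionSize >= 1L)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    coords <- voxelGrid(dims)
    nvox <- nrow(coords)
    ## work in flat pixel units (y, z axes)
    flat <- cbind(coords[, 2L] + 0.5, coords[, 3L] + 0.5)

    regions <- list(list(idx = seq_len(nvox), theta = NA_real_, level = 0L,
                         node = 1L))
    lines <- list()  # each: normal, anchor, level, members (voxel idx)
    tree <- data.frame(id = 1L, parent = NA_integer_, level = 0L)
    nextId <- 2L
    done <- list()
    while (length(regions) &&
           (length(regions) + length(done)) < maxRegions) {
        ## split the largest splittable region first (deterministic order)
        sizes <- vapply(regions, function(r) length(r$idx), integer(1))
        ord <- order(-sizes)
        r <- regions[[ord[1L]]]
        regions[[ord[1L]]] <- NULL
        if (length(unique(flat[r$idx, 1L])) < 2L &&
            length(unique(flat[r$idx, 2L])) < 2L ||
            length(r$idx) < 2L * minRegionSize) {
            done[[length(done) + 1L]] <- r
            next
        }
        theta <- if (is.na(r$theta)) runif(1, 0, 2 * pi) else
            runif(1, r$theta + pi / 2 - 0.5, r$theta + pi / 2 + 0.5)
        sp <- splitByLine(flat[r$idx, , drop = FALSE], theta)
        n1 <- sum(sp$side); n2 <- sum(!sp$side)
        if (n1 < minRegionSize || n2 < minRegionSize) {
            done[[length(done) + 1L]] <- r  # degenerate sliver: stop here
            next
        }
        lvl <- r$level + 1L
        lines[[length(lines) + 1L]] <- list(normal = sp$normal,
                                            anchor = sp$anchor,
                                            level = lvl,
                                            members = r$idx)
        for (part in list(r$idx[sp$side], r$idx[!sp$side])) {
            tree <- rbind(tree, data.frame(id = nextId, parent = r$node,
                                           level = lvl))
            regions[[length(regions) + 1L]] <-
                list(idx = part, theta = theta, level = lvl, node = nextId)
            nextId <- nextId + 1L
        }
    }
    done <- c(done, regions)

    ## connectivity: sum mirror contributions over the lines that split a
    ## region containing the source voxel
    M <- matrix(0, nvox, nvox)
    for (ln in lines) {
        L <- ln$level
        Pi <- 1 / max(4 - L, 1)
        rho <- 25 * exp(-L / 3)
        mir <- mirrorPoints(flat[ln$members, , drop = FALSE],
                            ln$normal, ln$anchor)
        ## distance from each mirrored source to every target pixel
        Dx <- outer(mir[, 1L], flat[, 1L], `-`)
        Dy <- outer(mir[, 2L], flat[, 2L], `-`)
        M[ln$members, ] <- M[ln$members, ] +
            Pi * exp(-sqrt(Dx^2 + Dy^2) / rho) + 1
    }
    C <- (M + t(M)) / 2
    C <- addNoise(C, phi)

    labels <- integer(nvox)
    for (i in seq_along(done)) labels[done[[i]]$idx] <- i
    new("ToyModel",
        connectome = VoxelizedConnectome(C, coords),
        projection = flatProjectionOf(coords, dims),
        truth = truthParcellation(labels, coords, dims, tree),
        model = "random_split", phi = phi, seed = as.integer(seed),
        params = list(maxRegions = maxRegions, minRegionSize = minRegionSize,
                      dims = dims, nLines = length(lines)))
}
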