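## Shared fixtures, built in code.

## a tiny projection: `nx` x `ny` grid, `depth` voxels per pixel
gridProjection <- function(nx, ny, depth = 1L) {
    px <- rep(rep(seq_len(nx) - 1L, times = ny), each = depth)
    py <- rep(rep(seq_len(ny) - 1L, each = nx), each = depth)
    FlatProjection(seq_along(px), px, py, dims = c(nx, ny))
}

## gradient field with prescribed constant vectors on a full grid
constantGradientField <- function(nx, ny, vx, vy) {
    f <- matrix(0, nx, ny)
    g <- pixelGradient(f)
    gx <- matrix(vx, nx, ny)
    gy <- matrix(vy, nx, ny)
    len <- sqrt(gx^2 + gy^2)
    new("GradientField", gx = gx, gy = gy, nx = gx / len, ny = gy / len)
}

## gradient field from explicit per-pixel vectors (matrices)
fieldFromVectors <- function(gx, gy) {
    len <- sqrt(gx^2 + gy^2)
    nx <- gx / len; ny <- gy / len
    nx[!is.na(len) & len == 0] <- NA_real_
    ny[!is.na(len) & len == 0] <- NA_real_
    new("GradientField", gx = gx, gy = gy, nx = nx, ny = ny)
}

## brute-force all-pairs shortest paths (Floyd-Warshall) on the pixel
## graph with border-dependent edge weights; oracle for borderDistances
floydWarshallDistances <- function(region, border) {
    cells <- which(region)
    n <- length(cells)
    d <- dim(region)
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    xy <- which(region, arr.ind = TRUE)
    for (a in seq_len(n)) {
        for (b in seq_len(n)) {
            if (a == b) next
            if (max(abs(xy[a, ] - xy[b, ])) == 1L) {
                D[a, b] <- as.numeric(border[cells[a]] || border[cells[b]])
            }
        }
    }
    for (k in seq_len(n)) {
        for (a in seq_len(n)) {
            nd <- D[a, k] + D[k, ]
            upd <- nd < D[a, ]
            D[a, upd] <- nd[upd]
        }
    }
    D
}

## small random connectome for embedding tests
randomConnectome <- function(n, seed = 1L, symmetric = TRUE) {
    set.seed(seed)
    C <- matrix(runif(n * n), n, n)
    if (symmetric) C <- (C + t(C)) / 2
    diag(C) <- 0
    C
}
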