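test_that("border map of a uniform direction field flags nothing", {
    g <- constantGradientField(12, 12, 1, 0)
    bm <- borderMap(g)
    expect_true(all(abs(bm@length - 1) < 1e-9))
    expect_equal(sum(bm@border), 0L)
})

test_that("opposite half-fields produce a border band at the dividing line", {
    gx <- rbind(matrix(1, 8, 16), matrix(-1, 8, 16))
    g <- fieldFromVectors(gx, matrix(0, 16, 16))
    bm <- borderMap(g)
    ## direct convolution of the constructed field: shortening is
    ## confined to rows near the divide, full length far away
    expect_true(all(bm@border[7:10, ]))
    expect_false(any(bm@border[c(1:3, 14:16), ]))

    ## threshold 0: lengths are nonnegative, nothing can be flagged
    bm0 <- borderMap(g, threshold = 0)
    expect_equal(sum(bm0@border), 0L)
})

test_that("tiny regions yield a warning and no border", {
    g <- constantGradientField(3, 3, 1, 1)
    g@nx[1, ] <- NA; g@ny[1, ] <- NA   # 2 x 3 region, smaller than kernel
    expect_warning(bm <- borderMap(g), "kernel")
    expect_equal(sum(bm@border), 0L)
})

test_that("border distances count crossings and match brute force", {
    ## no border: all distances zero
    region <- matrix(TRUE, 4, 4)
    bm <- new("BorderMap", length = matrix(1, 4, 4),
              border = matrix(FALSE, 4, 4), kernelWidth = 5, threshold = 0.97)
    bd <- borderDistances(bm, region)
    expect_true(all(bd$dist == 0))

    ## 5x5 grid, middle column border: crossing costs 2
    region <- matrix(TRUE, 5, 5)
    border <- matrix(FALSE, 5, 5)
    border[, 3] <- TRUE
    bm <- new("BorderMap", length = matrix(1, 5, 5), border = border,
              kernelWidth = 5, threshold = 0.97)
    bd <- borderDistances(bm, region)
    xy <- bd$pixels
    left <- which(xy[, "y"] == 0)
    right <- which(xy[, "y"] == 4)
    sameSide <- which(xy[, "y"] <= 1)
    expect_true(all(bd$dist[left, right] == 2))
    expect_true(all(bd$dist[sameSide, sameSide] == 0))

    ## random masks up to 6x6: equality with Floyd-Warshall
    set.seed(31)
    for (rep in 1:5) {
        nx <- sample(3:6, 1); ny <- sample(3:6, 1)
        region <- matrix(TRUE, nx, ny)
        border <- matrix(runif(nx * ny) < 0.3, nx, ny)
        bm <- new("BorderMap", length = matrix(1, nx, ny), border = border,
                  kernelWidth = 5, threshold = 0.97)
        bd <- borderDistances(bm, region)
        expect_equal(bd$dist, floydWarshallDistances(region, border))
    }
})

test_that("distances are symmetric and satisfy the triangle inequality", {
    set.seed(17)
    region <- matrix(TRUE, 6, 6)
    border <- matrix(runif(36) < 0.4, 6, 6)
    bm <- new("BorderMap", length = matrix(1, 6, 6), border = border,
              kernelWidth = 5, threshold = 0.97)
    D <- borderDistances(bm, region)$dist
    expect_equal(D, t(D))
    n <- nrow(D)
    for (k in seq_len(n)) {
        expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-9))
    }
})

test_that("Ward with silhouette selection recovers planted group counts", {
    blockDist <- function(sizes, between = 5) {
        n <- sum(sizes)
        lab <- rep(seq_along(sizes), sizes)
        D <- matrix(between, n, n)
        D[outer(lab, lab, `==`)] <- 0
        D
    }
    ## two groups
    labs <- wardSilhouette(blockDist(c(6, 7)))
    expect_equal(length(unique(labs)), 2L)
    expect_equal(length(unique(labs[1:6])), 1L)
    ## three groups
    labs3 <- wardSilhouette(blockDist(c(5, 6, 7)))
    expect_equal(length(unique(labs3)), 3L)
    ## all-zero distances: no split
    expect_equal(wardSilhouette(matrix(0, 8, 8)), rep(1L, 8))
})

test_that("component selection minimizes mean subregion ri with index tie-break", {
    lab2 <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
    clean <- constantGradientField(2, 2, 1, 0)
    messy <- fieldFromVectors(matrix(c(1, -1, 1, -1), 2, 2), matrix(0, 2, 2))
    ## single candidate
    expect_equal(selectComponent(list(lab2), list(clean)), 1L)
    ## zero-ri candidate beats one with positive score
    expect_equal(selectComponent(list(lab2, lab2), list(messy, clean)), 2L)
    ## exact tie: lowest index wins
    expect_equal(selectComponent(list(lab2, lab2), list(clean, clean)), 1L)
})

test_that("reversal split recovers the planted halves of a toy connectome", {
    tm <- nodeDistanceModel(levels = 2L, dims = c(2L, 12L, 12L),
                            phi = 0.05, seed = 4)
    emb <- diffusionEmbed(connectome(tm), k = 10)
    res <- suppressWarnings(reversalSplit(emb, projection(tm)))
    expect_false(res$atomic)
    labs <- res$labels
    truth <- pixelLabels(groundTruth(tm))
    uc <- uncertaintyCoefficient(truth, labs)
    expect_gte(uc, 0.9)
})

test_that("split results are invariant to flipping a component's sign", {
    tm <- nodeDistanceModel(levels = 2L, dims = c(2L, 12L, 12L),
                            phi = 0.05, seed = 4)
    emb <- diffusionEmbed(connectome(tm), k = 6)
    res <- suppressWarnings(reversalSplit(emb, projection(tm)))
    flipped <- emb
    flipped@coordinates[, res$component] <- -flipped@coordinates[, res$component]
    res2 <- suppressWarnings(reversalSplit(flipped, projection(tm)))
    expect_equal(res2$component, res$component)
    expect_equal(res2$labels, res$labels)
})
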