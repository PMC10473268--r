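test_that("cosine distances hit their analytic extremes", {
    n <- 3  # components
    mk <- function(vx, vy) fieldFromVectors(matrix(vx, 4, 4), matrix(vy, 4, 4))
    region <- matrix(TRUE, 4, 4)
    w <- c(1, 0.5, 0.25)

    ## identical directions in every component: distance 0
    grads <- replicate(n, mk(1, 0), simplify = FALSE)
    cd <- cosineDistanceMatrix(grads, w, region)
    expect_true(all(abs(cd$dist) < 1e-12))

    ## opposite directions: 2 * sum(w); orthogonal: sum(w)
    gx <- matrix(1, 4, 4); gx[, 3:4] <- -1
    gradsOpp <- replicate(n, fieldFromVectors(gx, matrix(0, 4, 4)),
                          simplify = FALSE)
    cdOpp <- cosineDistanceMatrix(gradsOpp, w, region)
    expect_equal(max(cdOpp$dist), 2 * sum(w))

    gy <- matrix(0, 4, 4); gy[, 3:4] <- 1
    gxo <- matrix(1, 4, 4); gxo[, 3:4] <- 0
    gradsOrth <- replicate(n, fieldFromVectors(gxo, gy), simplify = FALSE)
    cdOrth <- cosineDistanceMatrix(gradsOrth, w, region)
    expect_equal(max(cdOrth$dist), sum(w))

    ## all-undefined: rejected
    gna <- fieldFromVectors(matrix(0, 4, 4), matrix(0, 4, 4))
    expect_error(cosineDistanceMatrix(list(gna), 1, region), "no pixel")
})

test_that("halving the weights halves distances and keeps the clustering", {
    set.seed(41)
    grads <- replicate(3, fieldFromVectors(matrix(rnorm(64), 8, 8),
                                           matrix(rnorm(64), 8, 8)),
                       simplify = FALSE)
    region <- matrix(TRUE, 8, 8)
    w <- c(1, 0.6, 0.3)
    cd1 <- cosineDistanceMatrix(grads, w, region)
    cd2 <- cosineDistanceMatrix(grads, w / 2, region)
    expect_equal(cd2$dist, cd1$dist / 2, tolerance = 1e-12)
    expect_equal(densitySplit(cd1$dist, minClusterSize = 5),
                 densitySplit(cd2$dist, minClusterSize = 5))
})

test_that("density split separates two compact direction groups", {
    gx <- matrix(1, 8, 8); gx[5:8, ] <- -1
    grads <- replicate(2, fieldFromVectors(gx, matrix(0, 8, 8)),
                       simplify = FALSE)
    cd <- cosineDistanceMatrix(grads, c(1, 1), matrix(TRUE, 8, 8))
    labs <- densitySplit(cd$dist, minClusterSize = 5)
    expect_equal(length(unique(labs[labs > 0])), 2L)
    expect_equal(sum(labs == 0), 0L)
})

test_that("degenerate all-identical gradients leave the region atomic", {
    tmConst <- nodeDistanceModel(levels = 2L, dims = c(2L, 10L, 10L),
                                 phi = 0, seed = 1)
    emb <- diffusionEmbed(connectome(tmConst), k = 5)
    ## overwrite every component with the same linear ramp: all pixels
    ## share one gradient direction, so no density split exists
    emb@coordinates[] <- seq_len(nrow(emb@coordinates))
    res <- cosineSplit(emb, projection(tmConst), smoothWidth = 0)
    expect_true(res$atomic)
})

test_that("cosine split recovers planted halves and routes outliers to 0", {
    tm <- nodeDistanceModel(levels = 2L, dims = c(2L, 12L, 12L),
                            phi = 0.05, seed = 4)
    emb <- diffusionEmbed(connectome(tm), k = 10)
    res <- cosineSplit(emb, projection(tm))
    expect_false(res$atomic)
    post <- postProcess(res$labels, minSize = 10)
    uc <- uncertaintyCoefficient(pixelLabels(groundTruth(tm)), post)
    expect_gte(uc, 0.9)
})
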