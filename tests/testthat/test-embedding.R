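test_that("connectivity profiles concatenate outgoing and incoming strengths", {
    C <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)  # [[0,1],[2,0]]
    P <- buildProfiles(C)
    expect_equal(P, cbind(C, t(C)))
    expect_equal(P[1, ], c(0, 1, 0, 2))
    expect_equal(P[2, ], c(2, 0, 1, 0))

    expect_equal(buildProfiles(matrix(0, 3, 3)), matrix(0, 3, 6))

    ## symmetric C: first and second half of each row coincide
    S <- randomConnectome(5, seed = 3)
    PS <- buildProfiles(S)
    expect_equal(PS[, 1:5], PS[, 6:10])

    expect_error(buildProfiles(matrix(0, 2, 3)), "square")
})

test_that("profile normalization produces unit row sums and is idempotent", {
    expect_equal(normalizeProfiles(matrix(c(1, 1, 2), 1, 3)),
                 matrix(c(0.25, 0.25, 0.5), 1, 3))
    P <- matrix(runif(20), 4, 5)
    Pn <- normalizeProfiles(P)
    expect_equal(rowSums(Pn), rep(1, 4), tolerance = 1e-12)
    expect_equal(normalizeProfiles(Pn), Pn)
    expect_error(normalizeProfiles(rbind(P, 0)), "zero")
})

test_that("Fokker-Planck normalization matches hand evaluation and is symmetric", {
    S <- matrix(c(2, 0, 0, 3), 2, 2)
    expect_equal(fokkerPlanck(S), diag(2))

    ## identical rows in P' give equal similarity entries
    Pn <- normalizeProfiles(matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = TRUE))
    SS <- similarityMatrix(Pn)
    expect_true(max(abs(SS - SS[1, 1])) < 1e-12)

    set.seed(1)
    S2 <- similarityMatrix(normalizeProfiles(matrix(runif(40), 4, 10)))
    W <- fokkerPlanck(S2)
    expect_equal(W, t(W))
})

test_that("diffusion embedding agrees with a from-scratch dense eigendecomposition", {
    n <- 30
    C <- randomConnectome(n, seed = 7)
    emb <- diffusionEmbed(C, k = 5)

    ## independent oracle: rebuild the operator from its definition
    P <- cbind(C, t(C))
    Pn <- P / rowSums(P)
    S <- Pn %*% t(Pn)
    d <- rowSums(S)
    W <- diag(1 / sqrt(d)) %*% S %*% diag(1 / sqrt(d))
    eig <- eigen((W + t(W)) / 2, symmetric = TRUE)
    oracleVecs <- eig$vectors[, 2:6]   # drop the stationary component
    oracleVals <- eig$values[2:6]

    expect_equal(strengths(emb), oracleVals, tolerance = 1e-10)
    for (j in 1:5) {
        cosine <- abs(sum(coordinates(emb)[, j] * oracleVecs[, j])) /
            (sqrt(sum(coordinates(emb)[, j]^2)) * sqrt(sum(oracleVecs[, j]^2)))
        expect_gte(cosine, 0.999)
    }
})

test_that("embedding contracts: sorted strengths, identical profiles, equivariance", {
    C <- randomConnectome(25, seed = 9)
    emb <- diffusionEmbed(C, k = 6)
    expect_false(is.unsorted(rev(strengths(emb))))

    ## duplicated profile rows embed at distance zero
    C2 <- C
    C2[2, ] <- C2[1, ]
    C2[, 2] <- C2[, 1]
    emb2 <- diffusionEmbed(C2, k = 4)
    expect_lt(max(abs(coordinates(emb2)[1, ] - coordinates(emb2)[2, ])), 1e-8)

    ## permuting the voxels permutes the coordinates identically
    perm <- sample(25)
    embP <- diffusionEmbed(C[perm, perm], k = 6)
    for (j in 1:6) {
        a <- coordinates(emb)[perm, j]
        b <- coordinates(embP)[, j]
        cosine <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
        expect_gte(cosine, 0.999)
    }

    ## disconnected voxel removed with a warning
    C3 <- C
    C3[3, ] <- 0
    C3[, 3] <- 0
    expect_warning(emb3 <- diffusionEmbed(C3, k = 4), "disconnected")
    expect_equal(nrow(coordinates(emb3)), 24)
    expect_false(3L %in% voxelIds(emb3))

    ## too few voxels rejected
    expect_error(diffusionEmbed(randomConnectome(5), k = 4), "at least")
})

test_that("component weights are relative to the strongest component", {
    C <- randomConnectome(25, seed = 11)
    emb <- diffusionEmbed(C, k = 5)
    w <- componentWeights(emb)
    expect_equal(w[1], 1)
    expect_true(all(diff(w) <= 1e-12))
    expect_equal(w, strengths(emb) / strengths(emb)[1])
})
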