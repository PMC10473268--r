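test_that("angleBetween covers the canonical angles", {
    expect_equal(angleBetween(c(1, 0), c(0, 1)), 90)
    expect_equal(angleBetween(c(1, 0), c(-1, 0)), 180)
    expect_equal(angleBetween(c(1, 0), c(1, 1)), 45)
    expect_error(angleBetween(c(0, 0), c(1, 0)), "zero")
})

test_that("gradient deviation measures departure from orthogonality", {
    ga <- constantGradientField(4, 4, 1, 0)
    gb <- constantGradientField(4, 4, 0, 1)
    expect_equal(gradientDeviation(ga, gb), 0)

    gpar <- constantGradientField(4, 4, 1, 0)
    expect_equal(gradientDeviation(ga, gpar), 90)

    ## half the pixels orthogonal, half parallel: mean deviation 45
    gx <- rbind(matrix(0, 2, 4), matrix(1, 2, 4))
    gy <- rbind(matrix(1, 2, 4), matrix(0, 2, 4))
    gmix <- fieldFromVectors(gx, gy)
    expect_equal(gradientDeviation(ga, gmix), 45)

    ## swapping the two components leaves gd unchanged
    expect_equal(gradientDeviation(gmix, ga), gradientDeviation(ga, gmix))
})

test_that("reversal index counts strictly-reversed pixel pairs", {
    ## all parallel: zero
    g <- constantGradientField(4, 4, 1, 0)
    expect_equal(reversalIndexComponent(g), 0)

    ## 4 pixels, two (1,0) and two (-1,0): 4 of 6 pairs reversed
    gx <- matrix(c(1, 1, -1, -1), 2, 2)
    gy <- matrix(0, 2, 2)
    g2 <- fieldFromVectors(gx, gy)
    expect_equal(reversalIndexComponent(g2), 4 / 6)

    ## exactly-90-degree pairs are not counted (strict inequality)
    gx <- matrix(c(1, 0, 1, 0), 2, 2)
    gy <- matrix(c(0, 1, 0, 1), 2, 2)
    g3 <- fieldFromVectors(gx, gy)
    expect_equal(reversalIndexComponent(g3), 0)

    ## fewer than 2 usable pixels: undefined
    g1 <- fieldFromVectors(matrix(1, 1, 1), matrix(0, 1, 1))
    expect_true(is.na(reversalIndexComponent(g1,
        region = matrix(c(TRUE), 1, 1) & FALSE)))
})

test_that("region reversal index sums its two component indices", {
    gx <- matrix(c(1, 1, -1, -1), 2, 2)
    g2 <- fieldFromVectors(gx, matrix(0, 2, 2))
    gpar <- constantGradientField(2, 2, 0, 1)
    expect_equal(reversalIndex(gpar, gpar), 0)
    expect_equal(reversalIndex(g2, g2), 2 * 4 / 6)
    expect_equal(reversalIndex(gpar, g2), 4 / 6)
})

test_that("pair counting equals a brute-force double loop", {
    set.seed(13)
    for (rep in 1:3) {
        gx <- matrix(rnorm(100), 10, 10)
        gy <- matrix(rnorm(100), 10, 10)
        g <- fieldFromVectors(gx, gy)
        fast <- reversalIndexComponent(g)
        ## brute force over all unordered pairs
        vx <- g@nx[!is.na(g@nx)]
        vy <- g@ny[!is.na(g@ny)]
        n <- length(vx)
        count <- 0L
        for (a in seq_len(n - 1)) {
            for (b in seq.int(a + 1L, n)) {
                if (vx[a] * vx[b] + vy[a] * vy[b] < 0) count <- count + 1L
            }
        }
        expect_equal(fast, count / choose(n, 2))
    }
})

test_that("ri is invariant under a global rotation of all gradients", {
    set.seed(21)
    gx <- matrix(rnorm(36), 6, 6)
    gy <- matrix(rnorm(36), 6, 6)
    g <- fieldFromVectors(gx, gy)
    base <- reversalIndexComponent(g)
    for (theta in c(pi / 7, pi / 2, 2)) {
        rx <- cos(theta) * gx - sin(theta) * gy
        ry <- sin(theta) * gx + cos(theta) * gy
        expect_equal(reversalIndexComponent(fieldFromVectors(rx, ry)), base)
    }
})
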