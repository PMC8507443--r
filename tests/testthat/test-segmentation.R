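test_that("dual thresholds partition simple intensities correctly", {
    vol <- CTVolume(array(c(100, 200, 300), c(3, 1, 1)))
    m <- thresholdSegment(vol, pipelineParams(tBone = 150, tSeed = 250))
    expect_identical(as.vector(voxelData(m$bone)),
        c(FALSE, TRUE, TRUE))
    expect_identical(as.vector(voxelData(m$seed)),
        c(FALSE, FALSE, TRUE))

    below <- CTVolume(array(-50, c(4, 4, 4)))
    m2 <- thresholdSegment(below, pipelineParams())
    expect_false(any(voxelData(m2$bone)))
    expect_false(any(voxelData(m2$seed)))
})

test_that("threshold masks equal a per-voxel comparison oracle", {
    ph <- generatePhantom(smallSpec(seed = 21))
    p <- pipelineParams()
    m <- thresholdSegment(ph$volume, p)
    v <- voxelData(ph$volume)
    expect_identical(voxelData(m$bone), v >= 200)
    expect_identical(voxelData(m$seed), v >= 400)
    expect_true(all(voxelData(m$seed) <= voxelData(m$bone)))
})

test_that("parameter invariants are enforced", {
    expect_error(pipelineParams(tBone = 200, tSeed = 100), "tSeed")
    expect_error(pipelineParams(tBone = 200, tSeed = 200), "tSeed")
    expect_error(pipelineParams(boxN = 8), "odd")
    expect_error(pipelineParams(acceptLow = 10, acceptHigh = 0),
        "acceptLow")
    expect_error(localMaximumMask(CTVolume(array(0, c(5, 5, 5))),
        boxN = 4), "odd")
})

test_that("local-maximum mask handles constant and spike volumes", {
    const <- CTVolume(array(7, c(9, 9, 9)))
    expect_false(any(voxelData(localMaximumMask(const, 3))))

    spike <- array(0, c(9, 9, 9))
    spike[5, 5, 5] <- 1000
    m <- voxelData(localMaximumMask(CTVolume(spike), 3))
    expect_true(m[5, 5, 5])       # 1000 > 1000/27
    expect_false(m[1, 1, 1])      # far from the spike: 0 > 0 is false
    expect_false(any(m & spike == 0 &
        bfBoxMean(spike, 3) == 0))  # ties give 0
})

test_that("local-maximum mask matches explicit-summation means", {
    set.seed(31)
    for (n in c(3L, 5L, 9L)) {
        arr <- array(rnorm(15^3, 100, 200), c(15, 15, 15))
        m <- voxelData(localMaximumMask(CTVolume(arr), n))
        expect_identical(m, arr > bfBoxMean(arr, n),
            label = sprintf("boxN = %d", n))
    }
})

test_that("local-maximum mask is invariant under adding a constant", {
    set.seed(32)
    arr <- array(rnorm(12^3), c(12, 12, 12))
    m1 <- voxelData(localMaximumMask(CTVolume(arr), 5))
    m2 <- voxelData(localMaximumMask(CTVolume(arr + 500), 5))
    expect_identical(m1, m2)
})

test_that("region growing covers a fully admissible block from one seed", {
    vol <- CTVolume(array(500, c(3, 3, 3)))
    seeds <- array(FALSE, c(3, 3, 3)); seeds[2, 2, 2] <- TRUE
    lmax <- BinaryMask(array(TRUE, c(3, 3, 3)), geometryFrom = vol)
    g <- regionGrow(vol, BinaryMask(seeds, geometryFrom = vol), lmax,
        pipelineParams())
    expect_true(all(voxelData(g)))
})

test_that("region growing stops when neighbours fail the acceptance range", {
    vals <- array(0, c(5, 5, 5))   # below acceptLow = 150
    vals[3, 3, 3] <- 500
    vol <- CTVolume(vals)
    seeds <- vals >= 400
    lmax <- BinaryMask(array(TRUE, dim(vals)), geometryFrom = vol)
    g <- regionGrow(vol, BinaryMask(seeds, geometryFrom = vol), lmax,
        pipelineParams())
    expect_identical(voxelData(g), seeds)
})

test_that("region growing equals a brute-force BFS on random instances", {
    set.seed(33)
    for (rep in 1:20) {
        d <- c(12L, 12L, 12L)
        vals <- array(sample(c(0, 300), prod(d), replace = TRUE,
            prob = c(0.4, 0.6)), d)
        lmax <- array(runif(prod(d)) < 0.7, d)
        seeds <- array(runif(prod(d)) < 0.05, d)
        vol <- CTVolume(vals)
        p <- pipelineParams(acceptLow = 150, acceptHigh = Inf)
        g <- regionGrow(vol, BinaryMask(seeds, geometryFrom = vol),
            BinaryMask(lmax, geometryFrom = vol), p)
        oracle <- bfFlood(lmax & vals >= 150, seeds, neighbours26)
        expect_identical(voxelData(g), oracle)
        # invariant: seeds <= grown <= admissible | seeds
        expect_true(all(voxelData(g)[seeds]))
        expect_true(all(voxelData(g) <= ((lmax & vals >= 150) | seeds)))
    }
})

test_that("region growing is invariant to splitting the seed mask", {
    set.seed(34)
    d <- c(10L, 10L, 10L)
    vals <- array(sample(c(0, 300), prod(d), replace = TRUE), d)
    lmax <- array(runif(prod(d)) < 0.6, d)
    seeds <- array(runif(prod(d)) < 0.08, d)
    vol <- CTVolume(vals)
    p <- pipelineParams()
    lm <- BinaryMask(lmax, geometryFrom = vol)
    whole <- voxelData(regionGrow(vol,
        BinaryMask(seeds, geometryFrom = vol), lm, p))
    half <- array(FALSE, d); half[1:5, , ] <- TRUE
    g1 <- voxelData(regionGrow(vol,
        BinaryMask(seeds & half, geometryFrom = vol), lm, p))
    g2 <- voxelData(regionGrow(vol,
        BinaryMask(seeds & !half, geometryFrom = vol), lm, p))
    expect_identical(whole, g1 | g2)
})

test_that("empty seed masks grow nothing, with a warning", {
    vol <- CTVolume(array(500, c(4, 4, 4)))
    empty <- BinaryMask(array(FALSE, c(4, 4, 4)), geometryFrom = vol)
    lmax <- BinaryMask(array(TRUE, c(4, 4, 4)), geometryFrom = vol)
    expect_warning(g <- regionGrow(vol, empty, lmax, pipelineParams()),
        "empty seed")
    expect_false(any(voxelData(g)))
})

test_that("combineMasks is the voxelwise union", {
    d <- c(6L, 6L, 6L)
    set.seed(35)
    a <- array(runif(prod(d)) < 0.3, d)
    b <- array(runif(prod(d)) < 0.3, d)
    A <- BinaryMask(a); B <- BinaryMask(b)
    u <- voxelData(combineMasks(A, B))
    expect_identical(u, a | b)
    expect_identical(u, voxelData(combineMasks(B, A)))  # commutative
    expect_true(all(u[a]) && all(u[b]))                 # superset
    expect_identical(voxelData(combineMasks(A, A)), a)  # idempotent
    # disjoint cardinality
    x <- array(FALSE, d); x[1:10] <- TRUE
    y <- array(FALSE, d); y[101:120] <- TRUE
    expect_equal(sum(voxelData(combineMasks(BinaryMask(x),
        BinaryMask(y)))), 30)
    # misaligned masks are rejected
    expect_error(combineMasks(A, BinaryMask(array(FALSE, c(5, 6, 6)))),
        "aligned")
})
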