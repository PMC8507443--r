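test_that("matching a volume to its own histogram is a near-identity", {
    ph <- generatePhantom(smallSpec(seed = 11))
    ref <- referenceHistogram(ph$volume)
    out <- matchHistogram(ph$volume, ref)
    # no voxel may move by more than one bin width (1 HU)
    expect_lt(max(abs(voxelData(out) - voxelData(ph$volume))), 1)
    # idempotence: matching twice changes nothing further
    out2 <- matchHistogram(out, ref)
    expect_lt(max(abs(voxelData(out2) - voxelData(out))), 1)
})

test_that("matching removes a global shift (small KS distance)", {
    ph <- generatePhantom(smallSpec(seed = 12))
    ref <- referenceHistogram(ph$volume, sourceId = "unshifted")
    shifted <- CTVolume(voxelData(ph$volume) + 100,
        geometryFrom = ph$volume)
    matched <- matchHistogram(shifted, ref)
    expect_gt(ksToReference(shifted, ref), 0.2)
    expect_lt(ksToReference(matched, ref), 0.05)
})

test_that("a constant volume maps to the reference midpoint quantile", {
    ph <- generatePhantom(smallSpec(seed = 13))
    ref <- referenceHistogram(ph$volume)
    const <- CTVolume(array(0, c(8, 8, 8)))
    expect_warning(out <- matchHistogram(const, ref), "degenerate")
    inv <- BoneSeg3D:::.inverseCDF(ref@binEdges, ref@cdf)
    expect_equal(unique(as.vector(voxelData(out))), inv(0.5),
        tolerance = 1e-9)
})

test_that("the intensity transform is monotone nondecreasing", {
    ref <- referenceHistogram(generatePhantom(smallSpec())$volume)
    set.seed(5)
    for (rep in 1:5) {
        v <- sort(runif(500, -800, 1500))
        vol <- CTVolume(array(rep(v, each = 2), c(2, 500, 1)))
        mapped <- voxelData(matchHistogram(vol, ref))[1, , 1]
        expect_true(all(diff(mapped) >= -1e-9))
    }
})

test_that("reference histograms survive text and YAML serialization", {
    ph <- generatePhantom(smallSpec(seed = 14))
    ref <- referenceHistogram(ph$volume, sourceId = "roundtrip test")
    for (ext in c("ref.tsv", "ref.yaml")) {
        f <- file.path(tempdir(), ext)
        writeReferenceHistogram(ref, f)
        back <- readReferenceHistogram(f)
        # the sparse serialization must reproduce the same mapping
        out1 <- matchHistogram(ph$volume, ref)
        out2 <- matchHistogram(ph$volume, back)
        expect_lt(max(abs(voxelData(out1) - voxelData(out2))), 1e-3)
    }
    expect_match(readReferenceHistogram(
        file.path(tempdir(), "ref.tsv"))@sourceId, "roundtrip")
})

test_that("removeTable removes a detached slab but not the body", {
    # body ellipsoid at 0 HU plus a smaller disjoint slab at -300 HU
    d <- c(40, 40, 20)
    g <- function(n) seq_len(n) - (n + 1) / 2
    X <- array(g(40), d)
    Y <- array(rep(g(40), each = 40), d)
    body <- (X / 15)^2 + (Y / 10)^2 <= 1
    vals <- array(-1000, d)
    vals[body] <- 0
    slab <- abs(X) <= 12 & Y >= 16 & Y <= 19
    vals[slab] <- -300
    vol <- CTVolume(vals)
    out <- removeTable(vol, airThreshold = -500)
    expect_true(all(voxelData(out$volume)[slab] == -1000))
    expect_identical(voxelData(out$volume)[body], vals[body])
    expect_true(all(voxelData(out$body)[body]))
})

test_that("a single connected component passes through unchanged", {
    d <- c(20, 20, 10)
    vals <- array(-1000, d)
    vals[5:15, 5:15, 3:8] <- 40
    out <- removeTable(CTVolume(vals), airThreshold = -500)
    expect_identical(voxelData(out$volume)[vals > -500],
        vals[vals > -500])
})

test_that("an all-air volume raises the empty-body error", {
    vol <- CTVolume(array(-1000, c(8, 8, 8)))
    expect_error(removeTable(vol), "empty body")
})
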