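test_that("generation is deterministic for a fixed spec and seed", {
    a <- generatePhantom(smallSpec(seed = 9))
    b <- generatePhantom(smallSpec(seed = 9))
    expect_identical(voxelData(a$volume), voxelData(b$volume))
    expect_identical(voxelData(a$truth), voxelData(b$truth))
})

test_that("ground truth is independent of the noise seed", {
    a <- generatePhantom(smallSpec(seed = 1))
    b <- generatePhantom(smallSpec(seed = 2))
    expect_identical(voxelData(a$truth), voxelData(b$truth))
    expect_false(identical(voxelData(a$volume), voxelData(b$volume)))
})

test_that("phantom generation leaves the caller's RNG stream alone", {
    set.seed(123); before <- runif(3)
    set.seed(123); invisible(runif(1))
    invisible(generatePhantom(smallSpec(seed = 77)))
    after <- runif(2)
    expect_identical(before[2:3], after)
})

test_that("noiseless, unblurred phantoms have exact tissue intensities", {
    ph <- generatePhantom(smallSpec(noiseSDHU = 0, blurSigmaMM = 0))
    v <- voxelData(ph$volume)
    tr <- voxelData(ph$truth)
    expect_true(all(v[tr == 1L] == 1200))
    expect_true(all(v[tr == 2L] == 150))
})

test_that("default bone fraction is plausible (2-15% of body voxels)", {
    ph <- generatePhantom(phantomSpec())
    body <- sum(voxelData(ph$volume) > -500)
    frac <- sum(voxelData(ph$truth) > 0L) / body
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.15)
})

test_that("presets cover the study conditions and generate at 64^3", {
    specs <- presetSpecs(shape = c(64L, 64L, 64L))
    expect_setequal(names(specs), c("default", "osteoporosis",
        "kissing_joint", "perforated", "canal"))
    expect_lt(specs$kissing_joint@jointGapMM, specs$default@jointGapMM)
    expect_equal(specs$osteoporosis@osteoporosisFactor, 0.5)
    expect_gt(specs$perforated@nForamina, specs$default@nForamina)
    for (nm in names(specs)) {
        ph <- generatePhantom(specs[[nm]])
        expect_s4_class(ph$volume, "CTVolume")
        expect_true(all(voxelData(ph$truth) %in% 0:2), label = nm)
        expect_gt(sum(voxelData(ph$truth) == 1L), 0, label = nm)
    }
    # the canal fixture has no enclosed marrow by construction
    expect_equal(sum(voxelData(generatePhantom(
        presetSpecs(shape = c(64L, 64L, 64L))$canal)$truth) == 2L), 0)
})

test_that("impossible specs are rejected", {
    expect_error(phantomSpec(osteoporosisFactor = 0), "0, 1")
    expect_error(phantomSpec(osteoporosisFactor = 0.1), "marrowHU")
    expect_error(phantomSpec(marrowHU = -10), "marrowHU must exceed")
    expect_error(phantomSpec(shape = c(16, 64, 64)), ">= 32")
    expect_error(generatePhantom(phantomSpec(jointGapMM = 40)),
        "exceed")
})

test_that("osteoporosis lowers cortical intensity and regional density", {
    ph1 <- generatePhantom(smallSpec(noiseSDHU = 0, blurSigmaMM = 0))
    ph0 <- generatePhantom(smallSpec(noiseSDHU = 0, blurSigmaMM = 0,
        osteoporosisFactor = 0.5))
    tr <- voxelData(ph1$truth)
    v1 <- voxelData(ph1$volume); v0 <- voxelData(ph0$volume)
    expect_true(all(v0[tr == 1L] <= 600 + 1e-9))
    expect_gt(max(v1[tr == 1L]) , max(v0[tr == 1L]))
    # density patches: osteoporotic cortex is spatially heterogeneous
    expect_gt(stats::sd(v0[tr == 1L]), stats::sd(v1[tr == 1L]))
    # marrow contrast shrinks toward soft tissue
    expect_lt(unique(v0[tr == 2L]), unique(v1[tr == 2L]))
})
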