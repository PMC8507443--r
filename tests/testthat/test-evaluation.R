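test_that("Dice matches closed-form values", {
    d <- c(4, 4, 4)
    a <- array(FALSE, d); a[1:4] <- TRUE
    b <- array(FALSE, d); b[3:6] <- TRUE
    r <- diceCoefficient(BinaryMask(a), BinaryMask(b))
    expect_equal(r$dice, 0.5)  # 2*2/(4+4)
    expect_equal(r$n_intersection, 2L)
    # identity and disjoint
    expect_equal(diceCoefficient(BinaryMask(a), BinaryMask(a))$dice, 1)
    c0 <- array(FALSE, d); c0[10:12] <- TRUE
    expect_equal(diceCoefficient(BinaryMask(a), BinaryMask(c0))$dice, 0)
})

test_that("Dice is symmetric and respects positive-label pooling", {
    set.seed(51)
    d <- c(8, 8, 8)
    p <- LabelVolume(array(sample(0:2, prod(d), TRUE), d))
    t <- LabelVolume(array(sample(0:2, prod(d), TRUE), d))
    expect_equal(diceCoefficient(p, t)$dice,
        diceCoefficient(t, p)$dice)
    r1 <- diceCoefficient(p, t, positiveLabels = 1L)
    r12 <- diceCoefficient(p, t, positiveLabels = c(1L, 2L))
    expect_equal(r1$n_truth, sum(voxelData(t) == 1L))
    expect_equal(r12$n_truth, sum(voxelData(t) > 0L))
    expect_lte(r12$n_intersection,
        min(r12$n_truth, r12$n_pred))
})

test_that("both-empty masks give Dice 1 with a warning", {
    e <- BinaryMask(array(FALSE, c(3, 3, 3)))
    expect_warning(r <- diceCoefficient(e, e), "empty")
    expect_equal(r$dice, 1)
})

test_that("misaligned grids are rejected", {
    a <- BinaryMask(array(TRUE, c(3, 3, 3)))
    b <- BinaryMask(array(TRUE, c(4, 3, 3)))
    expect_error(diceCoefficient(a, b), "aligned")
})

test_that("summaries report exact statistics and conserve counts", {
    mk <- function(d, id) data.frame(case_id = id, dice = d,
        n_truth = 1L, n_pred = 1L, n_intersection = 1L)
    s1 <- summarizeDice(mk(0.73, "only"))
    expect_equal(s1$mean, 0.73)
    expect_equal(s1$min, 0.73)
    expect_equal(s1$max, 0.73)
    s2 <- summarizeDice(rbind(mk(0.8, "a"), mk(1.0, "b")))
    expect_equal(s2$mean, 0.9)
    expect_equal(s2$min, 0.8)
    set.seed(52)
    many <- do.call(rbind, lapply(1:30, function(i)
        mk(runif(1, 0.6, 1), paste0("c", i))))
    s3 <- summarizeDice(many, bins = 10)
    expect_equal(sum(s3$counts), 30)
    # histogram is invariant to ordering
    s4 <- summarizeDice(many[sample(30), ], bins = 10)
    expect_identical(s3$counts, s4$counts)
    expect_error(summarizeDice(many[0, ]), "no Dice")
})
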