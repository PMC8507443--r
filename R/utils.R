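# Internal helpers: neighbourhood offsets, structuring elements,
# separable filters, geometry checks and stage-tagged errors.

.connOffsets <- function(connectivity = 26L) {
    stopifnot(connectivity %in% c(6L, 18L, 26L))
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    nz <- rowSums(abs(g))
    keep <- switch(as.character(connectivity),
        "6"  = nz == 1L,
        "18" = nz >= 1L & rowSums(abs(g) > 0) <= 2L,
        "26" = nz >= 1L)
    storage.mode(g) <- "integer"
    unname(g[keep, , drop = FALSE])
}

# in-plane 4-connectivity; dz = 0 keeps axial slices independent
.connOffsets2D <- function() {
    matrix(c(-1L, 0L, 0L,  1L, 0L, 0L,  0L, -1L, 0L,  0L, 1L, 0L),
        ncol = 3L, byrow = TRUE)
}

# Integer offsets of a spacing-aware ellipsoid of physical radius r (mm).
# Always contains the origin, so r = 0 gives the identity element.
.ellipsoidOffsets <- function(radiusMM, spacing) {
    if (radiusMM <= 0)
        return(matrix(0L, nrow = 1L, ncol = 3L))
    half <- pmax(0L, as.integer(floor(radiusMM / spacing)))
    g <- as.matrix(expand.grid(dx = -half[1]:half[1],
        dy = -half[2]:half[2], dz = -half[3]:half[3]))
    d2 <- (g[, 1] * spacing[1] / radiusMM)^2 +
          (g[, 2] * spacing[2] / radiusMM)^2 +
          (g[, 3] * spacing[3] / radiusMM)^2
    g <- g[d2 <= 1, , drop = FALSE]
    storage.mode(g) <- "integer"
    unname(g)
}

.checkAligned <- function(a, b, what = "volumes") {
    if (!identical(dim(a@voxels), dim(b@voxels)))
        stop(sprintf("%s are not aligned: dimensions differ (%s vs %s)",
            what, paste(dim(a@voxels), collapse = "x"),
            paste(dim(b@voxels), collapse = "x")), call. = FALSE)
    if (max(abs(a@spacing - b@spacing)) > 1e-6)
        stop(sprintf("%s are not aligned: spacing differs", what),
            call. = FALSE)
    invisible(TRUE)
}

# Sliding-window sum of length 2r+1 along the first axis of a matrix,
# window shrunk at the borders (sum over the in-volume part only).
.runSum1 <- function(m, r) {
    n <- nrow(m)
    cs <- apply(m, 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
    cs <- rbind(0, cs)
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r, 1L)
    cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
}

.axisFirst <- function(arr, axis) {
    perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
        `3` = c(3L, 1L, 2L))
    aperm(arr, perm)
}

.axisBack <- function(arr, axis) {
    perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
        `3` = c(2L, 3L, 1L))
    aperm(arr, perm)
}

# Mean over the n x n x n box intersected with the volume (shrinking
# window): separable sliding sums divided by the per-voxel window size.
.boxMean <- function(arr, boxN) {
    r <- (boxN - 1L) %/% 2L
    d <- dim(arr)
    s <- arr
    for (axis in 1:3) {
        s <- .axisFirst(s, axis)
        ds <- dim(s)
        s <- array(.runSum1(matrix(s, nrow = ds[1]), r), ds)
        s <- .axisBack(s, axis)
    }
    cnt1 <- function(n) pmin(seq_len(n) + r, n) - pmax(seq_len(n) - r, 1L) + 1L
    counts <- outer(outer(cnt1(d[1]), cnt1(d[2])), cnt1(d[3]))
    s / counts
}

# Separable Gaussian convolution with replicate padding; sigma in mm,
# spacing-aware.  sigma = 0 returns the input unchanged.
.gaussianBlur <- function(arr, sigmaMM, spacing) {
    if (sigmaMM <= 0) return(arr)
    for (axis in 1:3) {
        sigmaVox <- sigmaMM / spacing[axis]
        half <- max(1L, as.integer(ceiling(3 * sigmaVox)))
        w <- exp(-0.5 * ((-half:half) / sigmaVox)^2)
        w <- w / sum(w)
        arr <- .axisFirst(arr, axis)
        ds <- dim(arr)
        m <- matrix(arr, nrow = ds[1])
        n <- ds[1]
        acc <- matrix(0, n, ncol(m))
        for (j in seq_along(w)) {
            idx <- pmin(pmax(seq_len(n) + (j - half - 1L), 1L), n)
            acc <- acc + w[j] * m[idx, , drop = FALSE]
        }
        arr <- .axisBack(array(acc, ds), axis)
    }
    arr
}

# Re-raise any error from a pipeline stage with the stage name attached.
.withStage <- function(stage, expr) {
    withCallingHandlers(expr,
        error = function(e) {
            if (is.null(attr(e, "bonesegStage"))) {
                e2 <- simpleError(sprintf("[stage: %s] %s", stage,
                    conditionMessage(e)))
                attr(e2, "bonesegStage") <- stage
                stop(e2)
            }
        })
}

.stageLog <- function(verbose, fmt, ...) {
    if (isTRUE(verbose)) message(sprintf(fmt, ...))
    invisible(NULL)
}
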