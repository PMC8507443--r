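# Independent brute-force oracles and small fixture builders.  These
# deliberately avoid the package's own kernels: neighbourhood means are
# recomputed by explicit summation, reachability by a hand-written BFS.

# explicit-summation box mean (shrinking window at the borders)
bfBoxMean <- function(arr, n) {
    r <- (n - 1L) %/% 2L
    d <- dim(arr)
    out <- array(NA_real_, d)
    for (k in seq_len(d[3])) for (j in seq_len(d[2]))
        for (i in seq_len(d[1])) {
            xs <- max(1L, i - r):min(d[1], i + r)
            ys <- max(1L, j - r):min(d[2], j + r)
            zs <- max(1L, k - r):min(d[3], k + r)
            out[i, j, k] <- mean(arr[xs, ys, zs])
        }
    out
}

neighbours26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
neighbours26 <- neighbours26[rowSums(abs(neighbours26)) > 0, ]
neighbours6 <- neighbours26[rowSums(abs(neighbours26)) == 1, ]

# breadth-first reachability over an admissibility array; seeds always
# included, growth into admissible neighbours only
bfFlood <- function(admissible, seeds, offsets) {
    d <- dim(admissible)
    vis <- array(FALSE, d)
    queue <- which(seeds)
    vis[queue] <- TRUE
    idx <- arrayInd(queue, d)
    head <- 1L
    coords <- idx
    while (head <= nrow(coords)) {
        cur <- coords[head, ]
        head <- head + 1L
        for (m in seq_len(nrow(offsets))) {
            nb <- cur + offsets[m, ]
            if (any(nb < 1L) || any(nb > d)) next
            if (!vis[nb[1], nb[2], nb[3]] &&
                admissible[nb[1], nb[2], nb[3]]) {
                vis[nb[1], nb[2], nb[3]] <- TRUE
                coords <- rbind(coords, nb)
            }
        }
    }
    vis
}

# border-reachable background (6-connectivity), the hole-fill oracle
bfBorderReach <- function(mask) {
    d <- dim(mask)
    bg <- !mask
    seeds <- array(FALSE, d)
    seeds[c(1, d[1]), , ] <- TRUE
    seeds[, c(1, d[2]), ] <- TRUE
    seeds[, , c(1, d[3])] <- TRUE
    bfFlood(bg, bg & seeds, neighbours6)
}

# Kolmogorov-Smirnov distance between a volume's body histogram and a
# reference histogram
ksToReference <- function(vol, ref, airThreshold = -500) {
    v <- voxelData(vol)
    v <- v[v > airThreshold]
    grid <- seq(-1024, 2000, by = 1)
    refCdf <- stats::approx(ref@binEdges, ref@cdf, xout = grid,
        rule = 2)$y
    max(abs(refCdf - stats::ecdf(v)(grid)))
}

# hollow sphere shell mask (outer/inner radius in voxels)
hollowShell <- function(n = 24, outer = 10, inner = 7, perforation = 0) {
    c0 <- (n + 1) / 2
    g <- seq_len(n) - c0
    D <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
    shell <- D <= outer & D > inner
    if (perforation > 0) {
        # carve a hole where the +x axis meets the shell
        P <- sqrt(outer(outer((g - (outer + inner) / 2)^2, g^2, "+"),
            g^2, "+"))
        shell <- shell & P > perforation
    }
    shell
}

smallSpec <- function(...) phantomSpec(shape = c(48L, 48L, 48L), ...)

diceOf <- function(lab, truth) {
    p <- voxelData(lab) > 0L
    t <- voxelData(truth) > 0L
    2 * sum(p & t) / (sum(p) + sum(t))
}
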