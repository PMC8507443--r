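.HU_FLOOR <- -1024
.HU_CEIL <- 3071

#' Build a reference intensity histogram from a CT volume
#'
#' Computes the cumulative intensity distribution of the body voxels
#' (intensity above `airThreshold`) of a volume, on 1-HU-wide bins over
#' `[-1024, 3071]`.  The result is used as the matching target of
#' [matchHistogram()].
#'
#' @param vol a [CTVolume-class].
#' @param airThreshold HU; voxels at or below it (air) are excluded.
#' @param sourceId free-text description stored with the histogram.
#' @return a [ReferenceHistogram-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 48)))
#' ref <- referenceHistogram(ph$volume, sourceId = "demo phantom")
#' ref
#' @export
referenceHistogram <- function(vol, airThreshold = -500,
                               sourceId = "unnamed reference") {
    stopifnot(is(vol, "CTVolume"))
    v <- vol@voxels[vol@voxels > airThreshold]
    if (length(v) == 0L)
        stop("no voxels above the air threshold", call. = FALSE)
    edges <- seq(.HU_FLOOR - 0.5, .HU_CEIL + 0.5, by = 1)
    v <- pmin(pmax(v, .HU_FLOOR), .HU_CEIL)
    counts <- tabulate(floor(v - .HU_FLOOR + 0.5) + 1L,
        nbins = length(edges) - 1L)
    cdf <- c(0, cumsum(counts) / sum(counts))
    cdf[length(cdf)] <- 1
    new("ReferenceHistogram", binEdges = edges, cdf = cdf,
        sourceId = sourceId)
}

# Piecewise-linear inverse CDF over the bin edges.  Every quantile is
# inverted inside the mass bin that carries it (empty bins never
# stretch a segment), so the inverse of the forward interpolation is
# exact within each bin.  An integer-valued intensity sits mid-bin, so
# a constant volume maps through quantile 0.5 (midpoint convention).
.inverseCDF <- function(edges, cdf) {
    inc <- which(diff(cdf) > 0)
    if (length(inc) == 0L) {
        v <- edges[1]
        return(function(q) rep(v, length(q)))
    }
    fLo <- cdf[inc]; fHi <- cdf[inc + 1L]
    eLo <- edges[inc]; eHi <- edges[inc + 1L]
    K <- length(inc)
    function(q) {
        q <- pmin(pmax(q, fLo[1]), fHi[K])
        k <- pmin(findInterval(q, fHi, left.open = TRUE) + 1L, K)
        t <- (q - fLo[k]) / (fHi[k] - fLo[k])
        t <- pmin(pmax(t, 0), 1)
        eLo[k] + t * (eHi[k] - eLo[k])
    }
}

#' Match a CT volume's intensities to a reference histogram
#'
#' Classical CDF (quantile) matching: each intensity is sent to the
#' reference value at its own body-restricted quantile.  The transform
#' is monotone nondecreasing, so intensity order is preserved, and it is
#' idempotent up to one bin width (1 HU).  Matching compensates global
#' intensity differences such as a different tube voltage; air voxels
#' (at or below `airThreshold`) do not influence the estimated mapping
#' but are still mapped, through a slope-one extension of the transform
#' below the body intensity range.  Geometry is unchanged.
#'
#' @param vol a [CTVolume-class].
#' @param ref a [ReferenceHistogram-class].
#' @param airThreshold HU; estimation is restricted to voxels above it.
#' @return a new [CTVolume-class] with matched intensities.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 48)))
#' ref <- referenceHistogram(ph$volume)
#' shifted <- CTVolume(voxelData(ph$volume) + 100, geometryFrom = ph$volume)
#' matched <- matchHistogram(shifted, ref)
#' @export
matchHistogram <- function(vol, ref, airThreshold = -500) {
    stopifnot(is(vol, "CTVolume"), is(ref, "ReferenceHistogram"))
    src <- referenceHistogram(vol, airThreshold = airThreshold,
        sourceId = "input")
    mass <- which(diff(src@cdf) > 0)
    if (length(mass) <= 1L)
        warning("degenerate (constant) body intensities; ",
            "mapping to the reference CDF-midpoint quantile",
            call. = FALSE)
    # bin edges bounding the source's mass-carrying range
    vLo <- src@binEdges[min(mass)]
    vHi <- src@binEdges[max(mass) + 1L]
    inv <- .inverseCDF(ref@binEdges, ref@cdf)
    # forward quantile of every voxel, then the reference inverse CDF
    v <- vol@voxels
    inside <- v >= vLo & v <= vHi
    out <- v
    q <- stats::approx(src@binEdges, src@cdf, xout = v[inside],
        rule = 2, ties = "ordered")$y
    out[inside] <- inv(q)
    # voxels outside the estimation support (air and extreme values)
    # follow a slope-one extension of the transform
    mLo <- inv(stats::approx(src@binEdges, src@cdf, xout = vLo,
        rule = 2, ties = "ordered")$y)
    mHi <- inv(stats::approx(src@binEdges, src@cdf, xout = vHi,
        rule = 2, ties = "ordered")$y)
    out[v < vLo] <- mLo + (v[v < vLo] - vLo)
    out[v > vHi] <- mHi + (v[v > vHi] - vHi)
    CTVolume(out, geometryFrom = vol)
}

#' Remove the patient table from a CT volume
#'
#' Keeps the largest 26-connected component of voxels above the air
#' threshold -- the patient body -- after a morphological closing that
#' bridges small gaps in the skin, and resets every other voxel (table,
#' cushions, cables) to -1000 HU.
#'
#' @param vol a [CTVolume-class] with at least one voxel above
#'   `airThreshold`.
#' @param airThreshold HU separating air from tissue (default -500).
#' @param closingRadiusVox radius, in voxels, of the spherical closing
#'   applied before component analysis (default 2).
#' @return a list with elements `volume` (the cleaned [CTVolume-class])
#'   and `body` (the retained [BinaryMask-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 48)))
#' cleaned <- removeTable(ph$volume)
#' sum(voxelData(cleaned$body))
#' @export
removeTable <- function(vol, airThreshold = -500, closingRadiusVox = 2) {
    stopifnot(is(vol, "CTVolume"))
    above <- vol@voxels > airThreshold
    if (!any(above))
        stop("empty body: no voxel above the air threshold",
            call. = FALSE)
    d <- dim(above)
    se <- .ellipsoidOffsets(closingRadiusVox, c(1, 1, 1))
    closed <- .erode_mask(.dilate_mask(as.vector(above), d, se), d, se,
        TRUE)
    closed <- closed | as.vector(above)
    lab <- .label_components(closed, d, .connOffsets(26L))
    if (max(lab) > 0L) {
        sizes <- tabulate(lab[lab > 0L])
        body <- array(lab == which.max(sizes), d)
    } else {
        body <- array(closed, d)
    }
    out <- vol@voxels
    out[!body] <- -1000
    list(volume = CTVolume(out, geometryFrom = vol),
        body = BinaryMask(body, geometryFrom = vol))
}

#' Read and write reference histograms
#'
#' A [ReferenceHistogram-class] is serialized as plain text: comment
#' lines starting with `#` (carrying the source description), then two
#' whitespace-separated columns `bin_edge cdf`.  Interior edges of flat
#' CDF runs are omitted on writing; linear interpolation restores the
#' identical mapping.  A `.yaml`/`.yml` path uses an equivalent YAML
#' mapping with keys `source_id`, `bin_edges`, `cdf`.
#'
#' @param path file path; format chosen by extension.
#' @param ref a [ReferenceHistogram-class].
#' @return `readReferenceHistogram()`: a [ReferenceHistogram-class];
#'   `writeReferenceHistogram()`: the path, invisibly.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 48)))
#' ref <- referenceHistogram(ph$volume)
#' f <- file.path(tempdir(), "ref.tsv")
#' writeReferenceHistogram(ref, f)
#' ref2 <- readReferenceHistogram(f)
#' @export
readReferenceHistogram <- function(path) {
    if (!file.exists(path))
        stop(sprintf("reference histogram '%s' does not exist", path),
            call. = FALSE)
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        y <- yaml::read_yaml(path)
        return(new("ReferenceHistogram",
            binEdges = as.numeric(y$bin_edges), cdf = as.numeric(y$cdf),
            sourceId = as.character(y$source_id %||% "yaml reference")))
    }
    lines <- readLines(path)
    headers <- grep("^#", lines, value = TRUE)
    src <- sub("^#\\s*source:\\s*", "",
        grep("^#\\s*source:", headers, value = TRUE))
    tab <- utils::read.table(text = lines[!grepl("^#|^\\s*$", lines)],
        col.names = c("edge", "cdf"))
    new("ReferenceHistogram", binEdges = tab$edge, cdf = tab$cdf,
        sourceId = if (length(src)) src[1] else "file reference")
}

#' @rdname readReferenceHistogram
#' @export
writeReferenceHistogram <- function(ref, path) {
    stopifnot(is(ref, "ReferenceHistogram"))
    n <- length(ref@cdf)
    dl <- c(TRUE, diff(ref@cdf) != 0)
    dr <- c(diff(ref@cdf) != 0, TRUE)
    keep <- dl | dr
    keep[c(1L, n)] <- TRUE
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        yaml::write_yaml(list(source_id = ref@sourceId,
            bin_edges = ref@binEdges[keep], cdf = ref@cdf[keep]),
            path, precision = 12L)
    } else {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(sprintf("# source: %s", ref@sourceId), con)
        writeLines("# columns: bin_edge cdf", con)
        writeLines(sprintf("%.6g %.12g", ref@binEdges[keep],
            ref@cdf[keep]), con)
    }
    invisible(path)
}
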