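#' Construct pipeline parameters
#'
#' Creates a validated [PipelineParams-class] object.  The defaults
#' follow standard cortical/trabecular CT practice: 200 HU selects most
#' compact bone, 400 HU selects high-confidence seed regions, and the
#' acceptance range for region growing is open above so dense cortical
#' bone is never excluded.
#'
#' @param tBone lower threshold, HU.
#' @param tSeed seed threshold, HU; must exceed `tBone`.
#' @param boxN odd box-filter side length, voxels.
#' @param acceptLow,acceptHigh acceptance range for growing, HU.
#' @param mergeRadiusMM physical bone-part merge radius, mm.
#' @param airThreshold body/air separation threshold, HU.
#' @return a [PipelineParams-class].
#' @examples
#' pipelineParams()
#' pipelineParams(tBone = 250, tSeed = 500)
#' @export
pipelineParams <- function(tBone = 200, tSeed = 400, boxN = 9L,
                           acceptLow = 150, acceptHigh = Inf,
                           mergeRadiusMM = 3, airThreshold = -500) {
    new("PipelineParams", tBone = as.numeric(tBone),
        tSeed = as.numeric(tSeed), boxN = as.integer(boxN),
        acceptLow = as.numeric(acceptLow),
        acceptHigh = as.numeric(acceptHigh),
        mergeRadiusMM = as.numeric(mergeRadiusMM),
        airThreshold = as.numeric(airThreshold))
}

#' Dual-threshold segmentation
#'
#' Thresholds a CT volume at the two levels of `params`: the bone mask
#' (`voxel >= tBone`) selects most of the compact bone, and the seed
#' mask (`voxel >= tSeed`, with `tSeed > tBone`) selects the
#' high-confidence seed regions for [regionGrow()].  The seed mask is a
#' subset of the bone mask by construction.  Empty masks are legal.
#'
#' @param vol a [CTVolume-class].
#' @param params a [PipelineParams-class].
#' @return a list with [BinaryMask-class] elements `bone` and `seed`.
#' @examples
#' vol <- CTVolume(array(c(100, 200, 300), c(3, 1, 1)))
#' m <- thresholdSegment(vol, pipelineParams(tBone = 150, tSeed = 250))
#' sum(voxelData(m$bone)); sum(voxelData(m$seed))
#' @export
thresholdSegment <- function(vol, params = pipelineParams()) {
    stopifnot(is(vol, "CTVolume"), is(params, "PipelineParams"))
    validObject(params)
    list(bone = BinaryMask(vol@voxels >= params@tBone,
            geometryFrom = vol),
        seed = BinaryMask(vol@voxels >= params@tSeed,
            geometryFrom = vol))
}

#' Local-maximum mask
#'
#' A copy of the volume is averaged with an `boxN x boxN x boxN` box
#' filter; the mask is 1 exactly where the original intensity is
#' strictly greater than the box-averaged intensity (ties give 0).  At
#' the volume border the mean is taken over the part of the box inside
#' the volume (shrinking window), which avoids the spurious border
#' maxima that zero padding would create.  The mask is invariant under
#' adding a constant to all intensities.
#'
#' @param vol a [CTVolume-class].
#' @param boxN odd integer >= 3; box side length in voxels (default 9).
#' @return a [BinaryMask-class].
#' @examples
#' a <- array(0, c(7, 7, 7)); a[4, 4, 4] <- 1000
#' m <- localMaximumMask(CTVolume(a), boxN = 3)
#' voxelData(m)[4, 4, 4]
#' @export
localMaximumMask <- function(vol, boxN = 9L) {
    stopifnot(is(vol, "CTVolume"))
    boxN <- as.integer(boxN)
    if (length(boxN) != 1L || is.na(boxN) || boxN < 3L ||
        boxN %% 2L == 0L)
        stop("boxN must be an odd integer >= 3", call. = FALSE)
    avg <- .boxMean(vol@voxels, boxN)
    BinaryMask(vol@voxels > avg, geometryFrom = vol)
}

#' Seeded 3D region growing
#'
#' Grows the seed regions through 26-connected neighbourhoods.  A voxel
#' is added when it is reachable from a seed through voxels that satisfy
#' both criteria: (a) the voxel is a local maximum (its intensity
#' exceeds its box-neighbourhood mean, see [localMaximumMask()]) and
#' (b) its intensity lies inside the acceptance range
#' `[acceptLow, acceptHigh]`.  Both criteria are evaluated once in
#' advance, which makes growth a pure reachability problem: the result
#' is independent of the order in which seeds or neighbours are
#' processed.  Seed voxels are always included.
#'
#' @param vol a [CTVolume-class].
#' @param seedMask [BinaryMask-class] of seed voxels (from
#'   [thresholdSegment()]).
#' @param lmaxMask [BinaryMask-class] from [localMaximumMask()].
#' @param params a [PipelineParams-class] providing the acceptance
#'   range.
#' @return a [BinaryMask-class] of the grown region.
#' @examples
#' a <- array(500, c(3, 3, 3))
#' vol <- CTVolume(a)
#' seeds <- array(FALSE, dim(a)); seeds[2, 2, 2] <- TRUE
#' lmax <- BinaryMask(array(TRUE, dim(a)), geometryFrom = vol)
#' g <- regionGrow(vol, BinaryMask(seeds, geometryFrom = vol), lmax)
#' sum(voxelData(g))
#' @export
regionGrow <- function(vol, seedMask, lmaxMask,
                       params = pipelineParams()) {
    stopifnot(is(vol, "CTVolume"), is(seedMask, "BinaryMask"),
        is(lmaxMask, "BinaryMask"), is(params, "PipelineParams"))
    .checkAligned(vol, seedMask, "volume and seed mask")
    .checkAligned(vol, lmaxMask, "volume and local-maximum mask")
    if (!any(seedMask@voxels)) {
        warning("empty seed mask: nothing to grow", call. = FALSE)
        return(BinaryMask(array(FALSE, dim(vol@voxels)),
            geometryFrom = vol))
    }
    admissible <- lmaxMask@voxels & vol@voxels >= params@acceptLow &
        vol@voxels <= params@acceptHigh
    grown <- .flood_from_seeds(as.vector(admissible),
        as.vector(seedMask@voxels), dim(vol@voxels), .connOffsets(26L))
    BinaryMask(array(grown, dim(vol@voxels)), geometryFrom = vol)
}

#' Combine region-growing and threshold results
#'
#' Voxelwise union of the grown region and the bone threshold mask.
#'
#' @param grown,boneMask aligned [BinaryMask-class] objects.
#' @return a [BinaryMask-class]; superset of both inputs.
#' @examples
#' a <- BinaryMask(array(c(TRUE, FALSE), c(2, 1, 1)))
#' b <- BinaryMask(array(c(FALSE, TRUE), c(2, 1, 1)))
#' sum(voxelData(combineMasks(a, b)))
#' @export
combineMasks <- function(grown, boneMask) {
    stopifnot(is(grown, "BinaryMask"), is(boneMask, "BinaryMask"))
    .checkAligned(grown, boneMask, "masks")
    BinaryMask(grown@voxels | boneMask@voxels, geometryFrom = grown)
}
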