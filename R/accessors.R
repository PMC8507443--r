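#' Access voxel data and geometry of image volumes
#'
#' `voxelData()` returns the raw 3D array (`[x, y, z]` index order),
#' `voxelSpacing()` the voxel size in mm, `voxelOrigin()` the world
#' coordinate of the first voxel centre and `voxelDirection()` the 3x3
#' direction-cosine matrix.
#'
#' @param x a [CTVolume-class], [BinaryMask-class] or
#'   [LabelVolume-class].
#' @return `voxelData()`: a 3D array; `voxelSpacing()`, `voxelOrigin()`:
#'   numeric(3); `voxelDirection()`: a 3x3 matrix.
#' @examples
#' vol <- CTVolume(array(0, c(4, 4, 4)), spacing = c(0.7, 0.7, 3))
#' dim(voxelData(vol))
#' voxelSpacing(vol)
#' @name voxelData
NULL

#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@voxels)

#' @rdname voxelData
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname voxelData
#' @export
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)

#' @rdname voxelData
#' @export
setMethod("voxelDirection", "ImageVolume", function(x) x@direction)

#' @rdname voxelData
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@voxels))

.showGeometry <- function(object) {
    d <- dim(object@voxels)
    cat(sprintf("  dimensions: %d x %d x %d voxels\n", d[1], d[2], d[3]))
    cat(sprintf("  spacing   : %.4g x %.4g x %.4g mm\n",
        object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  origin    : (%.4g, %.4g, %.4g) mm\n",
        object@origin[1], object@origin[2], object@origin[3]))
}

setMethod("show", "CTVolume", function(object) {
    cat("CTVolume (Hounsfield units)\n")
    .showGeometry(object)
    r <- range(object@voxels)
    cat(sprintf("  intensity : [%.4g, %.4g] HU\n", r[1], r[2]))
})

setMethod("show", "BinaryMask", function(object) {
    cat("BinaryMask\n")
    .showGeometry(object)
    cat(sprintf("  foreground: %d of %d voxels\n",
        sum(object@voxels), length(object@voxels)))
})

setMethod("show", "LabelVolume", function(object) {
    cat("LabelVolume (0 = background, 1 = compact bone, 2 = marrow)\n")
    .showGeometry(object)
    tab <- tabulate(object@voxels + 1L, nbins = 3L)
    cat(sprintf("  counts    : 0: %d, 1: %d, 2: %d\n",
        tab[1], tab[2], tab[3]))
})

setMethod("show", "ReferenceHistogram", function(object) {
    cat("ReferenceHistogram\n")
    cat(sprintf("  bins   : %d edges over [%.4g, %.4g] HU\n",
        length(object@binEdges), min(object@binEdges),
        max(object@binEdges)))
    cat(sprintf("  source : %s\n", object@sourceId))
})

setMethod("show", "PipelineParams", function(object) {
    cat("PipelineParams\n")
    cat(sprintf("  tBone: %g HU  tSeed: %g HU  boxN: %d\n",
        object@tBone, object@tSeed, object@boxN))
    cat(sprintf("  acceptance: [%g, %g] HU\n",
        object@acceptLow, object@acceptHigh))
    cat(sprintf("  mergeRadiusMM: %g  airThreshold: %g HU\n",
        object@mergeRadiusMM, object@airThreshold))
})

setMethod("show", "PhantomSpec", function(object) {
    cat("PhantomSpec\n")
    cat(sprintf("  shape: %s voxels, spacing: %s mm\n",
        paste(object@shape, collapse = " x "),
        paste(signif(object@spacing, 3), collapse = " x ")))
    cat(sprintf("  cortical: %g HU x %g, marrow: %g HU\n",
        object@corticalHU, object@osteoporosisFactor, object@marrowHU))
    cat(sprintf("  joint gap: %g mm, foramina: %d, seed: %d\n",
        object@jointGapMM, object@nForamina, object@seed))
})

#' Construct image volumes
#'
#' Constructors for the three voxel-grid classes.  `data` is coerced to
#' the class's storage type (numeric intensities, logical mask, integer
#' labels); geometry defaults to 1 mm isotropic spacing at the world
#' origin with an identity direction matrix.
#'
#' @param data a 3D array (logical for `BinaryMask`, integer codes
#'   {0, 1, 2} for `LabelVolume`, numeric HU for `CTVolume`).
#' @param spacing numeric(3), mm per voxel.
#' @param origin numeric(3), mm.
#' @param direction 3x3 direction-cosine matrix.
#' @param geometryFrom optional [ImageVolume-class] whose geometry is
#'   copied (overrides `spacing`, `origin`, `direction`).
#' @return an object of the corresponding class.
#' @examples
#' vol <- CTVolume(array(rnorm(64, sd = 10), c(4, 4, 4)))
#' msk <- BinaryMask(voxelData(vol) > 0, geometryFrom = vol)
#' sum(voxelData(msk))
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3), geometryFrom = NULL) {
    g <- .resolveGeometry(spacing, origin, direction, geometryFrom)
    storage.mode(data) <- "double"
    new("CTVolume", voxels = data, spacing = g$spacing, origin = g$origin,
        direction = g$direction)
}

#' @rdname CTVolume
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3), geometryFrom = NULL) {
    g <- .resolveGeometry(spacing, origin, direction, geometryFrom)
    storage.mode(data) <- "logical"
    new("BinaryMask", voxels = data, spacing = g$spacing,
        origin = g$origin, direction = g$direction)
}

#' @rdname CTVolume
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3), geometryFrom = NULL) {
    g <- .resolveGeometry(spacing, origin, direction, geometryFrom)
    storage.mode(data) <- "integer"
    new("LabelVolume", voxels = data, spacing = g$spacing,
        origin = g$origin, direction = g$direction)
}

.resolveGeometry <- function(spacing, origin, direction, geometryFrom) {
    if (!is.null(geometryFrom)) {
        stopifnot(is(geometryFrom, "ImageVolume"))
        list(spacing = geometryFrom@spacing, origin = geometryFrom@origin,
            direction = geometryFrom@direction)
    } else {
        list(spacing = as.numeric(spacing), origin = as.numeric(origin),
            direction = matrix(as.numeric(direction), 3, 3))
    }
}
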