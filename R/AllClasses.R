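#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib BoneSeg3D, .registration = TRUE
NULL

.validGeometry <- function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L)
        msg <- c(msg, "voxel data must have exactly 3 dimensions")
    if (any(d < 1L))
        msg <- c(msg, "every dimension must be at least 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values")
    if (!identical(dim(object@direction), c(3L, 3L)) ||
        any(!is.finite(object@direction)))
        msg <- c(msg, "direction must be a finite 3x3 matrix")
    msg
}

#' ImageVolume: shared geometry of voxel grids
#'
#' Virtual parent of [CTVolume-class], [BinaryMask-class] and
#' [LabelVolume-class].  Voxel data are stored as an R array indexed
#' `[x, y, z]` (the first array index is the fastest-varying, left-right
#' image axis); all readers convert on-disk layouts into this order.
#' `spacing` is the physical voxel size in mm along (x, y, z), `origin`
#' the world coordinate of the first voxel centre, and `direction` a 3x3
#' direction-cosine matrix.  Non-axis-aligned directions are carried
#' through unchanged; the package never resamples.
#'
#' @slot voxels three-dimensional array of voxel values.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), mm.
#' @slot direction 3x3 direction-cosine matrix.
#' @name ImageVolume-class
#' @aliases ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume",
    representation("VIRTUAL",
        voxels = "array",
        spacing = "numeric",
        origin = "numeric",
        direction = "matrix"),
    prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
        direction = diag(3)))

#' CTVolume: a CT image in Hounsfield units
#'
#' A 3D scalar CT volume.  Intensities are always in Hounsfield units
#' (HU); file readers apply any stored slope/intercept rescaling, so all
#' thresholds in [pipelineParams()] can be expressed in HU.
#'
#' @seealso [CTVolume()], [readVolume()], [generatePhantom()]
#' @name CTVolume-class
#' @aliases CTVolume-class
#' @exportClass CTVolume
setClass("CTVolume", contains = "ImageVolume",
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!is.numeric(object@voxels))
            msg <- c(msg, "CT intensities must be numeric")
        else if (any(!is.finite(object@voxels)))
            msg <- c(msg, "CT intensities must be finite")
        if (length(msg)) msg else TRUE
    })

#' BinaryMask: a boolean voxel grid aligned to a CTVolume
#'
#' Foreground (`TRUE`) marks candidate or selected voxels.  A mask always
#' carries the geometry of the volume it was derived from.
#'
#' @seealso [BinaryMask()], [thresholdSegment()], [regionGrow()]
#' @name BinaryMask-class
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ImageVolume",
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!is.logical(object@voxels))
            msg <- c(msg, "mask voxels must be logical")
        else if (anyNA(object@voxels))
            msg <- c(msg, "mask voxels must not contain NA")
        if (length(msg)) msg else TRUE
    })

#' LabelVolume: segmentation labels
#'
#' Integer voxel grid with the label codes 0 = background, 1 = compact
#' (cortical) bone and 2 = filled bone interior (trabecular bone / bone
#' marrow).  The union of labels 1 and 2 is the segmented bone region;
#' the two codes stay distinct because downstream material decomposition
#' assigns different compositions to cortical bone and marrow.
#'
#' @seealso [LabelVolume()], [fillInterior3D()], [runPipeline()]
#' @name LabelVolume-class
#' @exportClass LabelVolume
setClass("LabelVolume", contains = "ImageVolume",
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!is.integer(object@voxels))
            msg <- c(msg, "labels must be stored as integers")
        else if (!all(object@voxels %in% c(0L, 1L, 2L)))
            msg <- c(msg, "labels must be in {0, 1, 2}")
        if (length(msg)) msg else TRUE
    })

#' ReferenceHistogram: a reference CT intensity distribution
#'
#' Cumulative intensity distribution of a reference CT volume, used by
#' [matchHistogram()] to normalise scans acquired at different tube
#' voltages onto a common intensity scale.  `binEdges` are ascending HU
#' values and `cdf` the cumulative probability at each edge
#' (nondecreasing, ending at 1).
#'
#' @slot binEdges ascending numeric HU values.
#' @slot cdf nondecreasing numeric values in `[0, 1]`, last equal to 1.
#' @slot sourceId free-text description of the reference volume.
#' @seealso [referenceHistogram()], [readReferenceHistogram()]
#' @name ReferenceHistogram-class
#' @exportClass ReferenceHistogram
setClass("ReferenceHistogram",
    representation(binEdges = "numeric", cdf = "numeric",
        sourceId = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@binEdges) < 2L)
            msg <- c(msg, "need at least two bin edges")
        if (length(object@binEdges) != length(object@cdf))
            msg <- c(msg, "binEdges and cdf must have equal length")
        if (any(diff(object@binEdges) <= 0))
            msg <- c(msg, "binEdges must be strictly increasing")
        if (length(object@cdf)) {
            if (object@cdf[1L] < 0 || any(diff(object@cdf) < 0))
                msg <- c(msg, "cdf must be nondecreasing and start >= 0")
            if (abs(object@cdf[length(object@cdf)] - 1) > 1e-8)
                msg <- c(msg, "cdf must end at 1")
        }
        if (length(msg)) msg else TRUE
    })

#' PipelineParams: configuration of the segmentation pipeline
#'
#' Single source of configuration for all pipeline stages.  The two
#' thresholds implement dual-threshold segmentation: `tBone` (lower)
#' selects most of the compact bone, `tSeed` (strictly larger) selects
#' high-confidence seed regions for region growing.  `boxN` is the odd
#' side length, in voxels, of the box filter behind the local-maximum
#' criterion.  `acceptLow`/`acceptHigh` bound the HU acceptance range for
#' region growing, `mergeRadiusMM` the physical radius of the closing
#' that merges nearby bone parts before hole filling, and `airThreshold`
#' separates body from air/table during preprocessing.
#'
#' @slot tBone numeric, HU; lower threshold (default 200).
#' @slot tSeed numeric, HU; seed threshold, must exceed `tBone`
#'   (default 400).
#' @slot boxN odd integer >= 3; box-filter side in voxels (default 9).
#' @slot acceptLow,acceptHigh numeric, HU; acceptance range for region
#'   growing (defaults 150 and `Inf`: dense cortical bone is never
#'   excluded from above).
#' @slot mergeRadiusMM numeric, mm; bone-part merge radius (default 3).
#' @slot airThreshold numeric, HU; body/air cut (default -500).
#' @seealso [pipelineParams()], [runPipeline()]
#' @name PipelineParams-class
#' @exportClass PipelineParams
setClass("PipelineParams",
    representation(tBone = "numeric", tSeed = "numeric", boxN = "integer",
        acceptLow = "numeric", acceptHigh = "numeric",
        mergeRadiusMM = "numeric", airThreshold = "numeric"),
    validity = function(object) {
        msg <- character()
        one <- function(x) length(x) == 1L && !is.na(x)
        if (!one(object@tBone) || !one(object@tSeed))
            msg <- c(msg, "thresholds must be single non-missing values")
        else if (object@tSeed <= object@tBone)
            msg <- c(msg, "tSeed must be strictly larger than tBone")
        if (!one(object@boxN) || object@boxN < 3L ||
            object@boxN %% 2L == 0L)
            msg <- c(msg, "boxN must be an odd integer >= 3")
        if (!one(object@acceptLow) || !one(object@acceptHigh) ||
            object@acceptLow > object@acceptHigh)
            msg <- c(msg, "acceptLow must not exceed acceptHigh")
        if (!one(object@mergeRadiusMM) || object@mergeRadiusMM < 0)
            msg <- c(msg, "mergeRadiusMM must be >= 0")
        if (!one(object@airThreshold))
            msg <- c(msg, "airThreshold must be a single value")
        if (length(msg)) msg else TRUE
    })

#' PhantomSpec: parameters of the synthetic pelvic phantom
#'
#' Geometric and intensity parameters of the synthetic pelvic CT phantom
#' produced by [generatePhantom()], plus the RNG seed for the additive
#' noise.  See [generatePhantom()] for the anatomy that the parameters
#' control and [presetSpecs()] for ready-made configurations.
#'
#' @slot shape integer(3), voxels per axis (each >= 32).
#' @slot spacing numeric(3), mm per voxel.
#' @slot bodyHU,muscleHU,corticalHU,marrowHU,tableHU tissue intensities
#'   in HU.
#' @slot corticalThicknessMM cortical shell thickness of the femoral
#'   shaft, mm; thin-cortex regions (femoral head, pelvic ring,
#'   acetabulum) use half this value.
#' @slot nForamina number of cortical perforations on each femoral shaft.
#' @slot foramenRadiusMM radius of each perforation, mm.
#' @slot jointGapMM width of the joint space between femoral head and
#'   acetabular cup, mm.
#' @slot osteoporosisFactor multiplier in (0, 1] applied to the
#'   cortical intensity; values below 1 additionally impose regional
#'   mineral-density loss on the thin-cortex sites, emulating the
#'   reduced attenuation and structural degradation of osteoporotic
#'   bone.
#' @slot blurSigmaMM standard deviation of the Gaussian blur emulating
#'   the scanner's partial-volume effect, mm.
#' @slot noiseSDHU standard deviation of the additive Gaussian noise, HU.
#' @slot includeTable whether a detached patient-table slab is added.
#' @slot shaftOpen when `TRUE` the femoral shafts become open-ended tubes
#'   running through the whole axial extent (the "canal" fixture) and the
#'   femoral heads and acetabula are omitted.
#' @slot seed RNG seed for the noise.
#' @seealso [phantomSpec()], [presetSpecs()], [generatePhantom()]
#' @name PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(shape = "integer", spacing = "numeric",
        bodyHU = "numeric", muscleHU = "numeric", corticalHU = "numeric",
        marrowHU = "numeric", tableHU = "numeric",
        corticalThicknessMM = "numeric", nForamina = "integer",
        foramenRadiusMM = "numeric", jointGapMM = "numeric",
        osteoporosisFactor = "numeric", blurSigmaMM = "numeric",
        noiseSDHU = "numeric", includeTable = "logical",
        shaftOpen = "logical", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 32L))
            msg <- c(msg, "shape must be 3 integers, each >= 32")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 positive values")
        if (object@osteoporosisFactor <= 0 || object@osteoporosisFactor > 1)
            msg <- c(msg, "osteoporosisFactor must be in (0, 1]")
        if (object@corticalHU * object@osteoporosisFactor <= object@marrowHU)
            msg <- c(msg,
                "corticalHU * osteoporosisFactor must exceed marrowHU")
        if (object@marrowHU <= object@bodyHU)
            msg <- c(msg, "marrowHU must exceed bodyHU")
        if (object@corticalThicknessMM <= 0 || object@foramenRadiusMM <= 0)
            msg <- c(msg, "thicknesses and radii must be positive")
        if (object@nForamina < 0L)
            msg <- c(msg, "nForamina must be >= 0")
        if (object@jointGapMM < 0)
            msg <- c(msg, "jointGapMM must be >= 0")
        if (object@blurSigmaMM < 0 || object@noiseSDHU < 0)
            msg <- c(msg, "blurSigmaMM and noiseSDHU must be >= 0")
        if (length(msg)) msg else TRUE
    })
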