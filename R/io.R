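#' Read a CT volume from disk
#'
#' Reads a 3D scalar volume from NIfTI (`.nii`, `.nii.gz`), MetaImage
#' (`.mha`, `.mhd` + raw) or a directory holding one DICOM series.
#' Intensities are rescaled to Hounsfield units using the slope and
#' intercept stored in the file when present; DICOM slices are sorted by
#' their position along the slice normal regardless of file order on
#' disk.  Voxel data are returned in `[x, y, z]` index order.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"metaimage"`,
#'   `"dicom_dir"`; `"auto"` infers the format from the path.
#' @return a [CTVolume-class] with the geometry from the file header.
#' @examples
#' vol <- CTVolume(array(round(rnorm(512, 50, 20)), c(8, 8, 8)))
#' f <- file.path(tempdir(), "example.nii.gz")
#' writeVolume(vol, f)
#' vol2 <- readVolume(f)
#' all.equal(voxelData(vol), voxelData(vol2))
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage",
                                        "dicom_dir")) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(path)
    if (format == "dicom_dir") {
        if (!dir.exists(path))
            stop(sprintf("DICOM directory '%s' does not exist", path),
                call. = FALSE)
        parts <- .readDicomDir(path)
    } else {
        if (!file.exists(path) || dir.exists(path))
            stop(sprintf("file '%s' does not exist", path), call. = FALSE)
        parts <- switch(format,
            nifti = .readNifti(path),
            metaimage = .readMetaImage(path))
    }
    CTVolume(parts$data, spacing = parts$spacing, origin = parts$origin,
        direction = parts$direction)
}

#' Write a CT or label volume to disk
#'
#' CT volumes are written as 32-bit float, label volumes as an unsigned
#' integer type; geometry metadata (spacing, origin, direction) is
#' preserved.  Integer-valued HU data round-trip bit-exactly.
#'
#' @param vol a [CTVolume-class] or [LabelVolume-class].
#' @param path output path; the parent directory must exist.
#' @param format `"auto"` (from the extension), `"nifti"` or
#'   `"metaimage"`.
#' @return the path, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(vol, path, format = c("auto", "nifti",
                                              "metaimage")) {
    stopifnot(is(vol, "CTVolume") || is(vol, "LabelVolume"))
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(path, forWrite = TRUE)
    if (!dir.exists(dirname(path)))
        stop(sprintf("directory '%s' does not exist", dirname(path)),
            call. = FALSE)
    ok <- try(switch(format,
        nifti = .writeNifti(vol, path),
        metaimage = .writeMetaImage(vol, path)), silent = TRUE)
    if (inherits(ok, "try-error"))
        stop(sprintf("cannot write '%s': %s", path,
            attr(ok, "condition")$message), call. = FALSE)
    invisible(path)
}

.guessFormat <- function(path, forWrite = FALSE) {
    if (!forWrite && dir.exists(path)) return("dicom_dir")
    if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
    if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
        return("metaimage")
    if (forWrite)
        stop(sprintf(
            "cannot infer output format from '%s' (use .nii[.gz]/.mha/.mhd)",
            path), call. = FALSE)
    stop(sprintf("cannot infer format of '%s'", path), call. = FALSE)
}
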