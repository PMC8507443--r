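# NIfTI reading/writing via RNifti.  Geometry is carried in the sform:
# sform[1:3, 1:3] = direction %*% diag(spacing), sform[1:3, 4] = origin.

.readNifti <- function(path) {
    img <- RNifti::readNifti(path, internal = FALSE)
    arr <- as.array(img)
    arr <- array(as.double(arr), dim(arr))  # strip niftiImage attributes
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
        stop(sprintf("'%s' is not a 3D volume (found %d dimensions)",
            path, length(dim(arr))), call. = FALSE)
    hdr <- RNifti::niftiHeader(img)
    xf <- try(RNifti::xform(img), silent = TRUE)
    if (!inherits(xf, "try-error") && is.matrix(xf) &&
        all(dim(xf) >= c(3, 4)) && any(abs(xf[1:3, 1:3]) > 0)) {
        lin <- matrix(as.numeric(xf[1:3, 1:3]), 3, 3)
        spacing <- sqrt(colSums(lin^2))
        direction <- lin %*% diag(1 / spacing)
        origin <- as.numeric(xf[1:3, 4])
    } else {
        spacing <- abs(hdr$pixdim[2:4])
        spacing[spacing == 0] <- 1
        direction <- diag(3)
        origin <- c(0, 0, 0)
    }
    # slope/intercept rescaling to HU when present
    if (!is.null(hdr$scl_slope) && is.finite(hdr$scl_slope) &&
        hdr$scl_slope != 0 && hdr$scl_slope != 1 ||
        (!is.null(hdr$scl_inter) && is.finite(hdr$scl_inter) &&
         hdr$scl_inter != 0)) {
        slope <- if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0)
            hdr$scl_slope else 1
        arr <- arr * slope + hdr$scl_inter
    }
    storage.mode(arr) <- "double"
    list(data = arr, spacing = spacing, origin = origin,
        direction = direction)
}

.writeNifti <- function(vol, path) {
    isLabel <- is(vol, "LabelVolume")
    arr <- vol@voxels
    img <- RNifti::asNifti(arr,
        datatype = if (isLabel) "uint8" else "float")
    sf <- rbind(cbind(vol@direction %*% diag(vol@spacing), vol@origin),
        c(0, 0, 0, 1))
    sf <- structure(sf, code = 2L)
    img <- RNifti::`sform<-`(img, sf)
    RNifti::writeNifti(img, path,
        datatype = if (isLabel) "uint8" else "float")
    invisible(path)
}
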