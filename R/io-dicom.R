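# Minimal DICOM series reader for uncompressed single-frame CT slices
# (implicit and explicit VR little endian).  Only the tags needed to
# assemble a geometrically consistent HU volume are interpreted; all
# other elements, including sequences, are skipped structurally.

.dcmTagKey <- function(group, element) sprintf("%04X,%04X", group, element)

.dcmNeededTags <- c(
    "0008,0016",  # SOPClassUID (unused, kept for diagnostics)
    "0020,0032",  # ImagePositionPatient
    "0020,0037",  # ImageOrientationPatient
    "0028,0010",  # Rows
    "0028,0011",  # Columns
    "0028,0030",  # PixelSpacing
    "0028,0100",  # BitsAllocated
    "0028,0103",  # PixelRepresentation
    "0028,1052",  # RescaleIntercept
    "0028,1053",  # RescaleSlope
    "7FE0,0010")  # PixelData

.dcmU16 <- function(raw, pos) {
    as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.dcmU32 <- function(raw, pos) {
    as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
        65536 * as.numeric(raw[pos + 2L]) +
        16777216 * as.numeric(raw[pos + 3L])
}

# Skip an undefined-length sequence/item stream until the delimiter tag.
.dcmSkipUndefined <- function(raw, pos, stopElement) {
    n <- length(raw)
    depth <- 1L
    while (pos + 7 <= n + 1) {
        g <- .dcmU16(raw, pos); e <- .dcmU16(raw, pos + 2L)
        len <- .dcmU32(raw, pos + 4L)
        pos <- pos + 8L
        if (g == 0xFFFE && e == stopElement) {
            depth <- depth - 1L
            if (depth == 0L) return(pos)
        } else if (g == 0xFFFE && e == 0xE000 && len == 4294967295) {
            # nested undefined-length item: fall through, rely on
            # delimiters of the same kind
        } else if (len != 4294967295) {
            pos <- pos + len
        }
    }
    stop("DICOM parse error: unterminated undefined-length element",
        call. = FALSE)
}

.dcmExplicitLong <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR",
    "UT", "UN")

.dcmParseFile <- function(path) {
    raw <- readBin(path, "raw", n = file.size(path))
    n <- length(raw)
    pos <- 1L
    explicit <- TRUE
    if (n > 132 && rawToChar(raw[129:132]) == "DICM") {
        pos <- 133L
        # file meta group is always explicit little endian
        metaExplicit <- TRUE
        transfer <- "1.2.840.10008.1.2.1"
        # parse group 0002 to find the transfer syntax
        while (pos + 7 <= n) {
            g <- .dcmU16(raw, pos)
            if (g != 0x0002) break
            e <- .dcmU16(raw, pos + 2L)
            vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
            if (vr %in% .dcmExplicitLong) {
                len <- .dcmU32(raw, pos + 8L); body <- pos + 12L
            } else {
                len <- .dcmU16(raw, pos + 6L); body <- pos + 8L
            }
            if (e == 0x0010)
                transfer <- sub("\\s+$", "",
                    rawToChar(raw[body:(body + len - 1L)]))
            pos <- body + len
        }
        explicit <- switch(transfer,
            "1.2.840.10008.1.2" = FALSE,
            "1.2.840.10008.1.2.1" = TRUE,
            stop(sprintf(
                "unsupported DICOM transfer syntax '%s' in '%s'",
                transfer, path), call. = FALSE))
    }
    out <- list()
    while (pos + 7 <= n) {
        g <- .dcmU16(raw, pos); e <- .dcmU16(raw, pos + 2L)
        vr <- NULL
        if (explicit && g != 0xFFFE) {
            vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
            if (vr %in% .dcmExplicitLong) {
                len <- .dcmU32(raw, pos + 8L); body <- pos + 12L
            } else {
                len <- .dcmU16(raw, pos + 6L); body <- pos + 8L
            }
        } else {
            len <- .dcmU32(raw, pos + 4L); body <- pos + 8L
        }
        key <- .dcmTagKey(g, e)
        if (len == 4294967295) {
            pos <- .dcmSkipUndefined(raw, body, 0xE0DD)
            next
        }
        if (key %in% .dcmNeededTags) {
            bytes <- raw[body:(body + len - 1L)]
            out[[key]] <- list(vr = vr, bytes = bytes)
        }
        pos <- body + len
    }
    out
}

.dcmString <- function(el) {
    if (is.null(el)) return(NULL)
    bytes <- el$bytes[el$bytes != as.raw(0L)]  # strip padding nulls
    sub("\\s+$", "", rawToChar(bytes), perl = TRUE)
}

.dcmNumeric <- function(el) {
    s <- .dcmString(el)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcmUS <- function(el) {
    if (is.null(el)) return(NULL)
    readBin(el$bytes, "integer", n = length(el$bytes) %/% 2L, size = 2L,
        signed = FALSE, endian = "little")
}

.readDicomDir <- function(path) {
    files <- list.files(path, full.names = TRUE, no.. = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L)
        stop(sprintf("DICOM directory '%s' contains no files", path),
            call. = FALSE)
    slices <- lapply(files, function(f) {
        el <- .dcmParseFile(f)
        rows <- .dcmUS(el[["0028,0010"]])
        cols <- .dcmUS(el[["0028,0011"]])
        px <- el[["7FE0,0010"]]
        if (is.null(rows) || is.null(cols) || is.null(px))
            stop(sprintf("'%s' is not a usable DICOM image slice", f),
                call. = FALSE)
        bits <- .dcmUS(el[["0028,0100"]]) %||% 16L
        signed <- (.dcmUS(el[["0028,0103"]]) %||% 1L) == 1L
        slope <- (.dcmNumeric(el[["0028,1053"]]) %||% 1)[1]
        inter <- (.dcmNumeric(el[["0028,1052"]]) %||% 0)[1]
        vals <- if (bits == 16L)
            readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
        else if (bits == 8L)
            readBin(px$bytes, "integer", n = rows * cols, size = 1L,
                signed = signed)
        else stop(sprintf("'%s': unsupported BitsAllocated %d", f, bits),
            call. = FALSE)
        # pixel data are row-major: columns (x) vary fastest
        img <- matrix(vals * slope + inter, nrow = cols, ncol = rows)
        ipp <- .dcmNumeric(el[["0020,0032"]]) %||% c(0, 0, 0)
        iop <- .dcmNumeric(el[["0020,0037"]]) %||% c(1, 0, 0, 0, 1, 0)
        psp <- .dcmNumeric(el[["0028,0030"]]) %||% c(1, 1)
        list(img = img, ipp = ipp, iop = iop,
            spacingXY = c(psp[2], psp[1]), file = f)
    })
    dims <- vapply(slices, function(s) dim(s$img), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("inconsistent DICOM series: slice matrix sizes differ",
            call. = FALSE)
    spac <- vapply(slices, function(s) s$spacingXY, numeric(2))
    if (max(abs(spac - spac[, 1])) > 1e-4)
        stop("inconsistent DICOM series: in-plane pixel spacing differs",
            call. = FALSE)
    iops <- vapply(slices, function(s) s$iop, numeric(6))
    if (max(abs(iops - iops[, 1])) > 1e-4)
        stop("inconsistent DICOM series: image orientation differs",
            call. = FALSE)
    iop <- slices[[1]]$iop
    rowCos <- iop[1:3]; colCos <- iop[4:6]
    normal <- c(rowCos[2] * colCos[3] - rowCos[3] * colCos[2],
                rowCos[3] * colCos[1] - rowCos[1] * colCos[3],
                rowCos[1] * colCos[2] - rowCos[2] * colCos[1])
    zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
    ord <- order(zpos)
    slices <- slices[ord]; zpos <- zpos[ord]
    nz <- length(slices)
    if (nz > 1L) {
        dz <- diff(zpos)
        if (any(dz <= 0))
            stop("inconsistent DICOM series: duplicate slice positions",
                call. = FALSE)
        if (max(dz) - min(dz) > 1e-3 * mean(dz) + 1e-6)
            stop("inconsistent DICOM series: non-uniform slice spacing",
                call. = FALSE)
        zspacing <- mean(dz)
    } else zspacing <- 1
    arr <- array(0, c(dim(slices[[1]]$img), nz))
    for (i in seq_len(nz)) arr[, , i] <- slices[[i]]$img
    list(data = arr,
        spacing = c(slices[[1]]$spacingXY, zspacing),
        origin = slices[[1]]$ipp,
        direction = cbind(rowCos, colCos, normal, deparse.level = 0))
}
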