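# Minimal explicit-VR little-endian DICOM slice writer, used to build
# synthetic series fixtures on the fly.  Independent of the package's
# reader: bytes are assembled directly from the DICOM encoding rules.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
    endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
    endian = "little")

dcmElement <- function(group, element, vr, value) {
    if (vr %in% c("DS", "IS", "UI", "CS", "LO")) {
        bytes <- charToRaw(paste(value, collapse = "\\"))
        if (length(bytes) %% 2 == 1)
            bytes <- c(bytes, charToRaw(if (vr == "UI") "" else " "))
        if (vr == "UI" && length(bytes) %% 2 == 1)
            bytes <- c(bytes, as.raw(0))
    } else if (vr == "US") {
        bytes <- u16(value)
    } else if (vr == "OW") {
        bytes <- value  # already raw
    } else stop("unsupported VR in test writer")
    if (vr == "UI") {
        # pad with NUL, not space
        s <- paste(value, collapse = "\\")
        bytes <- charToRaw(s)
        if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(0))
    }
    header <- c(u16(group), u16(element))
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
        c(header, charToRaw(vr), as.raw(c(0, 0)), u32(length(bytes)),
            bytes)
    } else {
        c(header, charToRaw(vr), u16(length(bytes)), bytes)
    }
}

# one CT slice: `pixels` is a Rows x Cols integer matrix of stored
# values; HU = pixels * slope + intercept
writeDicomSlice <- function(path, pixels, ipp, pixelSpacing = c(1, 1),
                            iop = c(1, 0, 0, 0, 1, 0), slope = 1,
                            intercept = -1024) {
    rows <- nrow(pixels); cols <- ncol(pixels)
    pix <- writeBin(as.integer(t(pixels)), raw(), size = 2,
        endian = "little")
    meta <- c(
        dcmElement(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    body <- c(
        dcmElement(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
        dcmElement(0x0020, 0x0032, "DS", sprintf("%g", ipp)),
        dcmElement(0x0020, 0x0037, "DS", sprintf("%g", iop)),
        dcmElement(0x0028, 0x0010, "US", rows),
        dcmElement(0x0028, 0x0011, "US", cols),
        dcmElement(0x0028, 0x0030, "DS", sprintf("%g", pixelSpacing)),
        dcmElement(0x0028, 0x0100, "US", 16),
        dcmElement(0x0028, 0x0103, "US", 1),
        dcmElement(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
        dcmElement(0x0028, 0x1053, "DS", sprintf("%g", slope)),
        dcmElement(0x7FE0, 0x0010, "OW", pix))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(128), con)
    writeChar("DICM", con, eos = NULL)
    writeBin(meta, con)
    writeBin(body, con)
    invisible(path)
}

# write a small synthetic series; returns the directory and the HU
# volume it encodes (x = columns, y = rows, z = slice index)
writeDicomSeries <- function(dir, nx = 6, ny = 5, nz = 4,
                             spacing = c(0.8, 0.6, 2.5),
                             shuffleNames = FALSE,
                             mixedSpacing = FALSE) {
    dir.create(dir, showWarnings = FALSE)
    set.seed(7)
    hu <- array(sample(-200:800, nx * ny * nz, replace = TRUE),
        c(nx, ny, nz))
    ord <- if (shuffleNames) sample(nz) else seq_len(nz)
    for (i in seq_len(nz)) {
        stored <- t(hu[, , i]) + 1024  # Rows x Cols, intercept -1024
        sp <- if (mixedSpacing && i == 2) c(0.9, 0.7) else
            c(spacing[2], spacing[1])  # row spacing, col spacing
        writeDicomSlice(
            file.path(dir, sprintf("slice_%02d.dcm", ord[i])),
            stored, ipp = c(-10, 5, (i - 1) * spacing[3]),
            pixelSpacing = sp, intercept = -1024)
    }
    list(dir = dir, hu = hu, spacing = spacing)
}
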