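# MetaImage (.mha / .mhd + .raw) reader and writer.  The format is a
# plain-text key = value header followed by (or pointing at) raw voxel
# data; no R package in use here provides it, so it is implemented
# directly against the MetaIO header conventions.

.metaTypes <- list(
    MET_CHAR   = list(size = 1L, signed = TRUE,  what = "integer"),
    MET_UCHAR  = list(size = 1L, signed = FALSE, what = "integer"),
    MET_SHORT  = list(size = 2L, signed = TRUE,  what = "integer"),
    MET_USHORT = list(size = 2L, signed = FALSE, what = "integer"),
    MET_INT    = list(size = 4L, signed = TRUE,  what = "integer"),
    MET_UINT   = list(size = 4L, signed = FALSE, what = "integer"),
    MET_FLOAT  = list(size = 4L, signed = TRUE,  what = "double"),
    MET_DOUBLE = list(size = 8L, signed = TRUE,  what = "double"))

.readMetaImage <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    dataFile <- NULL
    repeat {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L)
            stop(sprintf("'%s': header ended without ElementDataFile",
                path), call. = FALSE)
        kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$",
            line))[[1]]
        if (length(kv) != 3L)
            stop(sprintf("'%s': malformed header line: %s", path, line),
                call. = FALSE)
        key <- kv[2]; val <- trimws(kv[3])
        hdr[[key]] <- val
        if (key == "ElementDataFile") { dataFile <- val; break }
    }
    ndims <- as.integer(hdr[["NDims"]] %||% "3")
    if (ndims != 3L)
        stop(sprintf("'%s': only 3D MetaImage volumes are supported", path),
            call. = FALSE)
    dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
    etype <- hdr[["ElementType"]] %||% "MET_SHORT"
    tinfo <- .metaTypes[[etype]]
    if (is.null(tinfo))
        stop(sprintf("'%s': unsupported ElementType %s", path, etype),
            call. = FALSE)
    n <- prod(dims)
    nbytes <- n * tinfo$size
    compressed <- tolower(hdr[["CompressedData"]] %||% "false") == "true"
    msb <- tolower(hdr[["BinaryDataByteOrderMSB"]] %||% "false") == "true"
    endian <- if (msb) "big" else "little"
    if (identical(toupper(dataFile), "LOCAL")) {
        raw <- readBin(con, "raw",
            n = if (compressed) file.size(path) else nbytes)
    } else {
        rawPath <- file.path(dirname(path), dataFile)
        if (!file.exists(rawPath))
            stop(sprintf("raw data file '%s' not found", rawPath),
                call. = FALSE)
        raw <- readBin(rawPath, "raw", n = file.size(rawPath))
    }
    if (compressed)
        raw <- memDecompress(raw, type = "gzip")
    if (length(raw) < nbytes)
        stop(sprintf("'%s': expected %d data bytes, found %d", path,
            nbytes, length(raw)), call. = FALSE)
    vals <- readBin(raw, tinfo$what, n = n, size = tinfo$size,
        signed = tinfo$signed, endian = endian)
    arr <- array(as.double(vals), dims)
    spacing <- as.numeric(strsplit(
        hdr[["ElementSpacing"]] %||% hdr[["ElementSize"]] %||% "1 1 1",
        "\\s+")[[1]])
    origin <- as.numeric(strsplit(
        hdr[["Offset"]] %||% hdr[["Position"]] %||% hdr[["Origin"]] %||%
            "0 0 0", "\\s+")[[1]])
    tm <- as.numeric(strsplit(
        hdr[["TransformMatrix"]] %||% "1 0 0 0 1 0 0 0 1", "\\s+")[[1]])
    # MetaIO stores the matrix row-major, one image axis per row
    direction <- t(matrix(tm, 3, 3))
    list(data = arr, spacing = spacing, origin = origin,
        direction = direction)
}

.writeMetaImage <- function(vol, path) {
    isLabel <- is(vol, "LabelVolume")
    etype <- if (isLabel) "MET_UCHAR" else "MET_FLOAT"
    tinfo <- .metaTypes[[etype]]
    d <- dim(vol@voxels)
    local <- grepl("\\.mha$", path, ignore.case = TRUE)
    dataFile <- if (local) "LOCAL" else
        paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE),
            ".raw")
    hdr <- c(
        "ObjectType = Image",
        "NDims = 3",
        "BinaryData = True",
        "BinaryDataByteOrderMSB = False",
        "CompressedData = False",
        sprintf("TransformMatrix = %s",
            paste(format(as.vector(t(vol@direction)), trim = TRUE),
                collapse = " ")),
        sprintf("Offset = %s",
            paste(format(vol@origin, trim = TRUE), collapse = " ")),
        sprintf("ElementSpacing = %s",
            paste(format(vol@spacing, trim = TRUE), collapse = " ")),
        sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
        sprintf("ElementType = %s", etype),
        sprintf("ElementDataFile = %s", dataFile))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    vals <- as.vector(vol@voxels)
    if (tinfo$what == "integer") vals <- as.integer(round(vals))
    if (local) {
        writeBin(vals, con, size = tinfo$size, endian = "little")
    } else {
        rawCon <- file(file.path(dirname(path), dataFile), "wb")
        writeBin(vals, rawCon, size = tinfo$size, endian = "little")
        close(rawCon)
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
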