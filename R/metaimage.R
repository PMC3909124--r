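# Minimal MetaImage (.mha/.mhd) reader/writer: plain-text header followed by
# (or pointing to) an uncompressed little-endian raw block. Covers the subset
# of the format produced by the common medical-image toolkits.

mha_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  if (file.info(path)$size == 0) stop("parse error: empty file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); data_local <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("parse error: missing ElementDataFile in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("parse error in MetaImage header line: ", line)
    key <- kv[2]; val <- trimws(kv[3])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_local <- identical(val, "LOCAL"); break }
  }
  for (k in c("DimSize", "ElementType", "ElementDataFile"))
    if (is.null(hdr[[k]])) stop("parse error: MetaImage header lacks ", k)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims))) stop("expected a 3D MetaImage")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- mha_types[[hdr$ElementType]]
  if (is.null(ty)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  n <- prod(dims)
  if (data_local) {
    raw <- readBin(con, what = ty$what, n = n, size = ty$size,
                   signed = ty$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, what = ty$what, n = n, size = ty$size,
                   signed = ty$signed, endian = "little")
  }
  if (length(raw) != n) stop("parse error: truncated MetaImage data block")
  volume3d(array(as.numeric(raw), dim = dims), spacing, origin)
}

write_metaimage <- function(v, path) {
  lower <- tolower(path)
  local <- grepl("\\.mha$", lower)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(v$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(v$spacing, scientific = FALSE),
                                           collapse = " ")),
           paste("Offset =", paste(format(v$origin, scientific = FALSE),
                                   collapse = " ")),
           "ElementType = MET_DOUBLE")
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    rcon <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(v$data), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}
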