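# Minimal MetaImage (.mha/.mhd) reader and writer.
#
# Supports the uncompressed subset used for CT interchange: binary
# little-endian payloads of type MET_UCHAR/MET_SHORT/MET_USHORT/MET_INT/
# MET_FLOAT/MET_DOUBLE, 3 dimensions, with ElementDataFile either LOCAL
# (.mha, payload appended to the header) or a sidecar .raw file (.mhd).

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header is ASCII lines "Key = Value" terminated by the ElementDataFile line
  nl <- which(raw == as.raw(10L))
  hdr <- character()
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    hdr <- c(hdr, line)
    start <- pos + 1L
    if (grepl("^ElementDataFile", line)) {
      data_offset <- pos
      break
    }
  }
  if (is.na(data_offset)) {
    stop("malformed MetaImage header: no ElementDataFile line", call. = FALSE)
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), character(1))
  names(vals) <- trimws(keys)
  vals <- trimws(vals)
  get3 <- function(key, default) {
    if (key %in% names(vals)) as.numeric(strsplit(vals[[key]], "\\s+")[[1]])
    else default
  }
  ndims <- as.integer(vals[["NDims"]])
  if (is.na(ndims) || ndims != 3L) {
    stop("non-3D payload in MetaImage file", call. = FALSE)
  }
  if (identical(tolower(vals["CompressedData"]), "true")) {
    stop("compressed MetaImage payloads are not supported", call. = FALSE)
  }
  dims <- as.integer(get3("DimSize", NA))
  spacing <- get3("ElementSpacing", rep(1, 3))
  origin <- get3("Offset", rep(0, 3))
  tm <- get3("TransformMatrix", as.numeric(diag(3)))
  type <- vals[["ElementType"]]
  tt <- met_types[[type]]
  if (is.null(tt)) {
    stop(sprintf("unsupported MetaImage element type '%s'", type),
         call. = FALSE)
  }
  n <- prod(dims)
  df <- vals[["ElementDataFile"]]
  payload <- if (identical(df, "LOCAL")) {
    raw[(data_offset + 1L):length(raw)]
  } else {
    rp <- file.path(dirname(path), df)
    if (!file.exists(rp)) {
      stop(sprintf("missing file: raw payload '%s'", rp), call. = FALSE)
    }
    readBin(rp, "raw", n = file.info(rp)$size)
  }
  vec <- readBin(payload, tt$what, n = n, size = tt$size, signed = tt$signed,
                 endian = "little")
  list(data = array(as.numeric(vec), dims), spacing = spacing,
       origin = origin, orientation = matrix(tm, 3, 3))
}

write_metaimage <- function(data, path, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), orientation = diag(3),
                            element_type = "MET_DOUBLE") {
  tt <- met_types[[element_type]]
  if (is.null(tt)) {
    stop(sprintf("unsupported MetaImage element type '%s'", element_type),
         call. = FALSE)
  }
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(tools::file_path_sans_ext(basename(path)), ".raw")
              else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(as.numeric(orientation), collapse = " ")),
    paste("Offset =", paste(origin, collapse = " ")),
    paste("ElementSpacing =", paste(spacing, collapse = " ")),
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", datafile)
  )
  vec <- as.vector(data)
  if (tt$what == "integer") vec <- as.integer(round(vec))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (mhd) {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(vec, rawcon, size = tt$size, endian = "little")
  } else {
    writeBin(vec, con, size = tt$size, endian = "little")
  }
  invisible(path)
}
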