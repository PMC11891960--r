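# Volume I/O: multipage TIFF (baseline, uncompressed) and MetaImage
# (.mha/.mhd). No TIFF package ships with the target R stack, so a minimal
# baseline codec is implemented here: the writer emits uncompressed 8-bit
# grayscale pages (one strip per page, little-endian); the reader accepts
# uncompressed 8- or 16-bit single-sample pages in either byte order with
# arbitrary strip layout, which covers files produced by this package and by
# common scientific writers in their default configuration.

#' Read a 3D volume from disk
#'
#' Dispatches on file extension: `.tif`/`.tiff` (multipage TIFF) or
#' `.mha`/`.mhd` (MetaImage). TIFF carries no physical spacing; it is taken
#' from a JSON sidecar `<path>.json` (written by [write_stack()]) or from the
#' `spacing_nm` argument. MetaImage stores spacing in its header
#' (`ElementSpacing`, in mm); an explicit `spacing_nm` overrides it.
#'
#' @param path file to read.
#' @param spacing_nm optional per-axis spacing in nm, order (z, y, x).
#' @return A [voxel_volume()]; shape (z = pages, y = rows, x = columns).
#' @export
read_stack <- function(path, spacing_nm = NULL) {
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff_pages(path)
    if (is.null(spacing_nm)) {
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        spacing_nm <- as.numeric(meta$spacing_nm)
      } else {
        stop_ctx("TIFF has no spacing metadata: supply `spacing_nm` or a ",
                 "sidecar ", basename(sidecar))
      }
    }
    data <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) data[z, , ] <- pages[[z]]
    voxel_volume(data, spacing_nm)
  } else if (ext %in% c("mha", "mhd")) {
    read_metaimage(path, spacing_nm)
  } else {
    stop_ctx("unsupported volume format: .", ext,
             " (expected .tif/.tiff/.mha/.mhd)")
  }
}

#' Write a 3D volume to disk
#'
#' TIFF output is uncompressed 8-bit grayscale (values must be integers in
#' 0..255) plus a JSON spacing sidecar `<path>.json`; MetaImage output
#' supports 8-bit, 16-bit and floating-point data. Write-then-read is
#' bit-identical for binary volumes in either format.
#'
#' @param volume a [voxel_volume()].
#' @param path output file; extension selects the format as in
#'   [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_pages(volume$data, path)
    jsonlite::write_json(
      list(spacing_nm = volume$spacing_nm, origin_vx = volume$origin_vx),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(volume, path)
  } else {
    stop_ctx("unsupported volume format: .", ext)
  }
  invisible(path)
}

## ---- TIFF ----------------------------------------------------------------

tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_tiff_values <- function(con, type, count, endian, base_pos) {
  size <- tiff_type_size[type]
  total <- size * count
  field <- readBin(con, "raw", 4L)
  if (total > 4L) {
    off <- readBin(field, "integer", 1L, size = 4L, endian = endian)
    cur <- seek(con, where = NA)
    seek(con, base_pos + off)
    raw <- readBin(con, "raw", total)
    seek(con, cur)
  } else {
    raw <- field[seq_len(total)]
  }
  if (type == 3L) {
    readBin(raw, "integer", count, size = 2L, signed = FALSE, endian = endian)
  } else if (type == 4L) {
    readBin(raw, "integer", count, size = 4L, endian = endian)
  } else if (type %in% c(1L, 2L, 6L, 7L)) {
    as.integer(readBin(raw, "integer", count, size = 1L, signed = FALSE))
  } else {
    rep(NA_integer_, count)
  }
}

# returns a list of integer matrices (rows = y, cols = x), one per page
read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  endian <- if (identical(as.integer(hdr[1:2]), c(73L, 73L))) "little"
            else if (identical(as.integer(hdr[1:2]), c(77L, 77L))) "big"
            else stop_ctx("not a TIFF file: ", path)
  magic <- readBin(hdr[3:4], "integer", 1L, size = 2L, endian = endian)
  if (magic == 43L) stop_ctx("BigTIFF is not supported: ", path)
  if (magic != 42L) stop_ctx("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                     endian = endian)
    tags <- list()
    for (k in seq_len(n_tag)) {
      tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                     endian = endian)
      type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                      endian = endian)
      count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      if (type >= 1L && type <= 12L) {
        tags[[as.character(tag)]] <-
          read_tiff_values(con, type, count, endian, 0)
      } else {
        readBin(con, "raw", 4L)
      }
    }
    ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h)) stop_ctx("TIFF page without dimensions")
    bits <- gt(258, 1L)[1]
    if (!bits %in% c(8L, 16L))
      stop_ctx("unsupported TIFF bit depth: ", bits)
    if (gt(259, 1L)[1] != 1L) stop_ctx("compressed TIFF is not supported")
    if (gt(277, 1L)[1] != 1L)
      stop_ctx("only single-sample (grayscale) TIFF is supported")
    offs <- gt(273); counts <- gt(279)
    if (is.null(offs)) stop_ctx("TIFF page without strip offsets")
    if (is.null(counts)) counts <- rep(w * h * bits / 8L, length(offs))
    raw <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      raw <- c(raw, readBin(con, "raw", counts[s]))
    }
    npix <- w * h
    vals <- if (bits == 8L) {
      as.integer(readBin(raw, "integer", npix, size = 1L, signed = FALSE))
    } else {
      readBin(raw, "integer", npix, size = 2L, signed = FALSE,
              endian = endian)
    }
    # TIFF stores rows sequentially (x fastest): fill a y-by-x matrix by row
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
  }
  if (!length(pages)) stop_ctx("TIFF with no pages: ", path)
  d <- vapply(pages, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    stop_ctx("TIFF pages differ in size")
  pages
}

write_tiff_pages <- function(data, path) {
  vals <- as.vector(data)
  if (any(vals != round(vals)) || any(vals < 0) || any(vals > 255))
    stop_ctx("TIFF writer supports integer data in 0..255; ",
             "use MetaImage (.mha) for other types")
  nz <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)  # II, 42
  page_bytes <- ny * nx
  ifd_size <- 2L + 9L * 12L + 4L
  # layout: [header(4) | first IFD offset(4) | page data ... | IFDs ...]
  data_start <- 8L
  ifd_start <- data_start + nz * page_bytes
  writeBin(as.integer(ifd_start), con, size = 4L, endian = "little")
  for (z in seq_len(nz)) {
    page <- data[z, , ]
    # row-major byte stream, x fastest
    writeBin(as.raw(as.vector(t(page))), con)
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte field
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (z in seq_len(nz)) {
    writeBin(9L, con, size = 2L, endian = "little")
    entry(256L, 4L, 1L, nx)                       # ImageWidth
    entry(257L, 4L, 1L, ny)                       # ImageLength
    entry(258L, 3L, 1L, 8L)                       # BitsPerSample
    entry(259L, 3L, 1L, 1L)                       # Compression: none
    entry(262L, 3L, 1L, 1L)                       # Photometric: min-is-black
    entry(273L, 4L, 1L, data_start + (z - 1L) * page_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                       # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)               # StripByteCounts
    nxt <- if (z < nz) ifd_start + z * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
  }
  invisible(path)
}

## ---- MetaImage -----------------------------------------------------------

metaimage_types <- c(MET_UCHAR = "uchar", MET_USHORT = "ushort",
                     MET_SHORT = "short", MET_FLOAT = "float",
                     MET_DOUBLE = "double")

write_metaimage <- function(volume, path) {
  data <- volume$data
  nz <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  vals <- as.vector(data)
  int_like <- is.integer(data) ||
    (all(is.finite(vals)) && all(vals == round(vals)))
  type <- if (int_like && all(vals >= 0) && all(vals <= 255)) "MET_UCHAR"
          else if (int_like && all(vals >= 0) && all(vals <= 65535)) "MET_USHORT"
          else "MET_DOUBLE"
  ext <- tolower(tools::file_ext(path))
  local_data <- ext == "mha"
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  spacing_mm <- volume$spacing_nm / 1e6  # MetaImage convention: mm
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", nx, ny, nz),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            spacing_mm[3], spacing_mm[2], spacing_mm[1]),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", if (local_data) "LOCAL" else raw_name)
  )
  # raw layout: x fastest, then y, then z
  perm <- as.vector(aperm(data, c(3L, 2L, 1L)))
  ser <- function(con) {
    if (type == "MET_UCHAR") writeBin(as.raw(perm), con)
    else if (type == "MET_USHORT")
      writeBin(as.integer(perm), con, size = 2L, endian = "little")
    else writeBin(as.numeric(perm), con, size = 8L, endian = "little")
  }
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    ser(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    ser(con)
  }
  invisible(path)
}

read_metaimage <- function(path, spacing_nm = NULL) {
  bytes <- readBin(path, "raw", file.size(path))
  # parse header line by line from the raw stream (readLines would read
  # ahead and swallow part of a LOCAL payload)
  hdr <- list()
  pos <- 1L
  nl <- as.raw(0x0a)
  repeat {
    if (pos > length(bytes)) stop_ctx("MetaImage header without ElementDataFile")
    eol <- pos
    while (eol <= length(bytes) && bytes[eol] != nl) eol <- eol + 1L
    line <- rawToChar(bytes[pos:(eol - 1L)])
    pos <- eol + 1L
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3")) stop_ctx("only 3D MetaImage is supported")
  dimsize <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])  # x y z
  type <- hdr$ElementType
  if (!type %in% names(metaimage_types))
    stop_ctx("unsupported MetaImage ElementType: ", type)
  msb <- identical(tolower(hdr$BinaryDataByteOrderMSB %||% "false"), "true")
  endian <- if (msb) "big" else "little"
  n <- prod(dimsize)
  read_vals <- function(payload) {
    switch(type,
      MET_UCHAR = as.integer(readBin(payload, "integer", n, size = 1L,
                                     signed = FALSE)),
      MET_USHORT = readBin(payload, "integer", n, size = 2L, signed = FALSE,
                           endian = endian),
      MET_SHORT = readBin(payload, "integer", n, size = 2L, signed = TRUE,
                          endian = endian),
      MET_FLOAT = readBin(payload, "numeric", n, size = 4L, endian = endian),
      MET_DOUBLE = readBin(payload, "numeric", n, size = 8L, endian = endian))
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- read_vals(bytes[pos:length(bytes)])
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop_ctx("missing raw file: ", raw_path)
    vals <- read_vals(readBin(raw_path, "raw", file.size(raw_path)))
  }
  if (length(vals) != n) stop_ctx("truncated MetaImage data")
  # raw is x-fastest; build (x,y,z) then permute to (z,y,x)
  arr <- aperm(array(vals, dim = dimsize), c(3L, 2L, 1L))
  if (is.null(spacing_nm)) {
    sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
    spacing_nm <- rev(sp) * 1e6  # mm -> nm, (x,y,z) -> (z,y,x)
  }
  voxel_volume(arr, spacing_nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
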