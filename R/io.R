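file_ext2 <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii.gz")
  sub(".*\\.", "", p)
}

#' Read a grayscale image
#'
#' Reads 2-D PNG/TIFF or 3-D NIfTI/MetaImage into a [scalar_image].
#' Voxel spacing and origin are taken from the header where the format
#' carries them (NIfTI pixdim, MetaImage ElementSpacing/Offset); PNG and
#' TIFF get unit spacing. PNG intensities are returned on the 0..255
#' scale; TIFF intensities as stored (integer samples as integers, float
#' samples as-is). Color inputs are rejected: the registration model is
#' grayscale, convert before loading.
#'
#' @param path file path; extension one of png, tif, tiff, nii, nii.gz,
#'   mha, mhd.
#' @return a [scalar_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- file_ext2(path)
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L)
        stop("PNG at ", path, " has ", dim(x)[3],
             " channels; only grayscale input is supported - convert to a ",
             "single-channel image first")
      scalar_image(round(x * 255, 9))
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(x)) == 3L)
        stop("TIFF at ", path, " has ", dim(x)[3],
             " channels; only grayscale input is supported")
      scalar_image(x * 1.0)
    },
    nii = ,
    nii.gz = {
      x <- RNifti::readNifti(path)
      arr <- as.array(x)
      d <- dim(arr)
      if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
        arr <- array(arr, d[1:3])
        d <- dim(arr)
      }
      if (length(d) > 3L)
        stop("NIfTI at ", path, " has ", length(d),
             " dimensions; expected a 2-D or 3-D scalar volume")
      scalar_image(arr, spacing = RNifti::pixdim(x)[seq_along(d)])
    },
    mha = ,
    mhd = read_metaimage(path),
    stop("unknown image extension '.", ext, "' for ", path,
         ": supported are png, tif, tiff, nii, nii.gz, mha, mhd"))
  img
}

#' Write an image, overlay or displacement field
#'
#' Dispatches on the payload class. [scalar_image]s go to PNG (8-bit,
#' values clamped to [0, 255] and rounded), TIFF (16-bit, values clamped
#' to [0, 65535] and rounded; lossless for integer-valued data), NIfTI or
#' MetaImage (both lossless doubles, spacing in the header).
#' `rgb_overlay`s go to 8-bit RGB PNG (3-D overlays as a per-slice PNG
#' series with `_slice###` inserted before the extension).
#' `dense_field`s go to NIfTI (components stacked on the last dimension,
#' in image-axis order) or, for 2-D fields, to a 32-bit float TIFF whose
#' samples are affinely mapped to [0, 1] with the `(lo, hi)` map written
#' to a `<path>.json` sidecar that [read_field()] consumes.
#'
#' @param x a [scalar_image], `rgb_overlay` or `dense_field`.
#' @param path output path; the extension selects the format.
#' @return the path(s) written, invisibly.
#' @export
write_image <- function(x, path) UseMethod("write_image")

#' @export
write_image.scalar_image <- function(x, path) {
  ext <- file_ext2(path)
  d <- dim(x$data)
  switch(ext,
    png = {
      if (length(d) != 2L) stop("PNG output is 2-D only: ", path)
      v <- pmin(pmax(round(x$data), 0), 255)
      png::writePNG(v / 255, path)
    },
    tif = ,
    tiff = {
      if (length(d) != 2L) stop("TIFF scalar output is 2-D only: ", path)
      v <- pmin(pmax(round(x$data), 0), 65535)
      tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
    },
    nii = ,
    nii.gz = {
      n <- RNifti::asNifti(x$data)
      RNifti::pixdim(n) <- x$spacing
      RNifti::writeNifti(n, path, datatype = "double")
    },
    mha = ,
    mhd = write_metaimage(x, path),
    stop("unsupported extension '.", ext, "' for a scalar image: ", path))
  invisible(path)
}

#' @export
write_image.rgb_overlay <- function(x, path) {
  if (file_ext2(path) != "png")
    stop("RGB overlays are written as PNG, got: ", path)
  d <- dim(x$g)
  quant <- function(v) pmin(pmax(round(v), 0), 255) / 255
  if (length(d) == 2L) {
    arr <- array(c(quant(x$r), quant(x$g), quant(x$b)), c(d, 3L))
    png::writePNG(arr, path)
    return(invisible(path))
  }
  # 3-D: one PNG per axial slice
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    pk <- sub("\\.png$", sprintf("_slice%03d.png", k), path, ignore.case = TRUE)
    arr <- array(c(quant(x$r[, , k]), quant(x$g[, , k]), quant(x$b[, , k])),
                 c(d[1:2], 3L))
    png::writePNG(arr, pk)
    paths[k] <- pk
  }
  invisible(paths)
}

#' @export
write_image.dense_field <- function(x, path) {
  ext <- file_ext2(path)
  d <- dim(x)
  nd <- length(d) - 1L
  if (ext %in% c("nii", "nii.gz")) {
    RNifti::writeNifti(RNifti::asNifti(unclass(x)), path, datatype = "double")
    return(invisible(path))
  }
  if (ext %in% c("tif", "tiff")) {
    if (nd != 2L) stop("TIFF field export is 2-D only; use NIfTI for 3-D fields")
    lo <- min(x)
    hi <- max(x)
    scale <- if (hi > lo) hi - lo else 1
    suppressWarnings(
      tiff::writeTIFF((unclass(x) - lo) / scale, path,
                      bits.per.sample = 32L, reduce = FALSE))
    jsonlite::write_json(list(format = "regrefine-field", lo = lo, hi = hi,
                              shape = d[seq_len(nd)], components = d[nd + 1L]),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(c(path, paste0(path, ".json"))))
  }
  stop("unsupported extension '.", ext, "' for a dense field: ", path)
}

#' Read a displacement field written by [write_image()]
#'
#' @param path a NIfTI path (components on the last dimension) or a 2-D
#'   float TIFF path with its `<path>.json` sidecar.
#' @return a `dense_field` array `c(shape, n_axes)`.
#' @export
read_field <- function(path) {
  ext <- file_ext2(path)
  if (ext %in% c("nii", "nii.gz")) {
    arr <- as.array(RNifti::readNifti(path))
    return(structure(arr, class = "dense_field"))
  }
  if (ext %in% c("tif", "tiff")) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("missing field sidecar ", side, " for ", path)
    meta <- jsonlite::fromJSON(side)
    arr <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE))
    scale <- if (meta$hi > meta$lo) meta$hi - meta$lo else 1
    return(structure(arr * scale + meta$lo, class = "dense_field"))
  }
  stop("unsupported field extension for ", path)
}

# ---- MetaImage (.mha/.mhd), uncompressed ---------------------------------

metaimage_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("corrupt MetaImage header (no ElementDataFile): ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("corrupt MetaImage header line in ", path, ": ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage is not supported: ", path)
  msb <- toupper(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||% "FALSE")
  endian <- if (msb == "TRUE") "big" else "little"
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  ty <- metaimage_types[[hdr$ElementType %||% "MET_FLOAT"]]
  if (is.null(ty)) stop("unsupported MetaImage ElementType ", hdr$ElementType,
                        " in ", path)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_data <- readBin(con, "raw", n = n * ty$size)
  } else {
    dpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(dpath)) stop("MetaImage data file not found: ", dpath)
    raw_data <- readBin(dpath, "raw", n = n * ty$size)
  }
  if (length(raw_data) < n * ty$size)
    stop("MetaImage data block in ", path, " is truncated")
  vals <- readBin(raw_data, ty$what, n = n, size = ty$size,
                  signed = ty$signed, endian = endian)
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, length(dims))
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  scalar_image(array(as.double(vals), dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(image, path) {
  stopifnot(inherits(image, "scalar_image"))
  d <- dim(image$data)
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", length(d)),
    paste0("DimSize = ", paste(d, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste0("ElementSpacing = ", paste(format(image$spacing, trim = TRUE), collapse = " ")),
    paste0("Offset = ", paste(format(image$origin, trim = TRUE), collapse = " ")),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  writeBin(as.vector(image$data), con, size = 8L, endian = "little")
  invisible(path)
}

# ---- Session JSON --------------------------------------------------------

#' Write a revision session to JSON
#'
#' Sessions serialize to a small versioned JSON document (diffable,
#' hand-editable): a header, the initial spacing, metadata, and the event
#' list in order.
#'
#' @param session a [revision_session()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "revision_session"))
  doc <- list(
    format = "regrefine-session",
    version = 1L,
    initial_spacing = I(session$initial_spacing),
    metadata = session$metadata,
    events = lapply(session$events, function(e) {
      if (e$kind == "refine") list(kind = "refine")
      else list(kind = "drag", level = e$level, index = I(e$index),
                content_motion = I(e$content_motion))
    }))
  # digits = I(17): full double precision, so replaying a written session
  # is bit-identical to replaying the in-memory one
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a revision session from JSON
#'
#' @param path path to a session file written by [write_session()].
#' @return a [revision_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("cannot read session: file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse session JSON at ", path, ": ",
                             conditionMessage(e)))
  if (!identical(doc$format, "regrefine-session"))
    stop(path, " is not a regrefine session file")
  events <- lapply(seq_along(doc$events), function(k) {
    e <- doc$events[[k]]
    if (identical(e$kind, "refine")) return(refine_event())
    if (identical(e$kind, "drag"))
      return(drag_event(e$level, unlist(e$index), unlist(e$content_motion)))
    stop("unknown event kind '", e$kind, "' at event ", k, " in ", path)
  })
  md <- doc$metadata
  if (is.null(md) || (is.list(md) && !length(md))) md <- list()
  revision_session(unlist(doc$initial_spacing), events, md)
}

#' Write an SSD trace as CSV
#'
#' @param trace the `trace` data.frame of a [replay()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
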