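#' Read and write volumetric images
#'
#' Volumes, vector fields and label masks are stored as NIfTI-1
#' (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd` + `.raw`) files; the
#' extension selects the format.  NIfTI goes through RNifti; MetaImage is a
#' plain text header plus little-endian raw block read and written directly.
#' Geometry (spacing, origin) round-trips exactly; integer-typed files
#' round-trip bit-exact.
#'
#' Vector fields are written as vector-pixel MetaImage
#' (`ElementNumberOfChannels = 3`) or as 5D NIfTI (`nx ny nz 1 3`); on read
#' both that layout and a plain 4D three-channel layout are accepted.
#' Component order is (LR, AP, SI) displacement in mm.
#'
#' Label masks carry a JSON sidecar `<path>.labels.json` mapping label
#' integers to structure names.
#'
#' @param path file path; extension one of `.nii`, `.nii.gz`, `.mha`, `.mhd`.
#' @param vol a [scalar_volume].
#' @param field a [vector_field].
#' @param mask a [label_mask].
#' @param datatype storage type for NIfTI/MetaImage scalar output:
#'   `"float"` (32-bit), `"double"`, or `"int16"`.
#' @return `read_volume()` a [scalar_volume]; `read_vector_field()` a
#'   [vector_field]; `read_label_mask()` a [label_mask]; writers return the
#'   path invisibly.
#' @examples
#' f <- tempfile(fileext = ".mha")
#' write_volume(scalar_volume(array(7, c(4, 4, 4))), f)
#' read_volume(f)
#' @export
read_volume <- function(path) {
  dat <- read_image_any(path)
  if (length(dim(dat$data)) != 3L)
    stop("format error: ", path, " is not a 3D scalar image (dims: ",
         paste(dim(dat$data), collapse = "x"), ")", call. = FALSE)
  scalar_volume(dat$data, dat$spacing, dat$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, c("scalar_volume", "label_mask")))
  write_image_any(vol$data, vol$spacing, vol$origin, path, datatype)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_vector_field <- function(path) {
  dat <- read_image_any(path)
  d <- dim(dat$data)
  if (length(d) == 5L && d[4] == 1L) {       # nx ny nz 1 3
    d <- d[c(1:3, 5)]
    dim(dat$data) <- d
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("format error: ", path, " does not hold a 3-component vector field ",
         "(dims: ", paste(dim(dat$data), collapse = "x"), ")", call. = FALSE)
  vector_field(dat$data[, , , 1], dat$data[, , , 2], dat$data[, , , 3],
               dat$spacing, dat$origin)
}

#' @rdname read_volume
#' @export
write_vector_field <- function(field, path, datatype = "float") {
  stopifnot(inherits(field, "vector_field"))
  sh <- grid_shape(field)
  ext <- file_ext_lower(path)
  arr <- array(c(field$dx, field$dy, field$dz), c(sh, 3))
  if (ext %in% c("mha", "mhd")) {
    write_metaimage(arr, field$spacing, field$origin, path, datatype,
                    channels = 3L)
  } else {
    dim(arr) <- c(sh, 1L, 3L)
    write_image_any(arr, field$spacing, field$origin, path, datatype)
  }
  invisible(path)
}

#' @rdname read_volume
#' @export
read_label_mask <- function(path) {
  vol <- read_volume(path)
  side <- paste0(path, ".labels.json")
  labs <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  label_mask(round(vol$data), labs, vol$spacing, vol$origin)
}

#' @rdname read_volume
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_image_any(mask$data, mask$spacing, mask$origin, path, "int16")
  jsonlite::write_json(mask$label_names, paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

file_ext_lower <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

read_image_any <- function(path) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
    sp <- c(sp, rep(1, 3 - length(sp)))
    xf <- RNifti::xform(img)
    or <- as.numeric(xf[1:3, 4])
    dat <- as.array(img)
    attributes(dat) <- list(dim = dim(dat))
    list(data = dat, spacing = abs(sp), origin = or)
  } else if (ext %in% c("mha", "mhd")) {
    read_metaimage(path)
  } else {
    stop("format error: unsupported extension '.", ext, "' for ", path,
         call. = FALSE)
  }
}

write_image_any <- function(arr, spacing, origin, path, datatype = "double") {
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    dt <- switch(datatype, float = "float", double = "double",
                 int16 = "int16",
                 stop("unsupported datatype: ", datatype, call. = FALSE))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
    qf <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
    attr(qf, "code") <- 2L
    RNifti::qform(img) <- qf
    RNifti::sform(img) <- qf
    RNifti::writeNifti(img, path, datatype = dt)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(arr, spacing, origin, path, datatype)
  } else {
    stop("format error: unsupported extension '.", ext, "' for ", path,
         call. = FALSE)
  }
  invisible(path)
}

# --- MetaImage backend (text header + little-endian raw) ------------------

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); nbytes_header <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line))
      stop("format error: ", path, ": header ended without ElementDataFile",
           call. = FALSE)
    nbytes_header <- nbytes_header + nchar(line, type = "bytes") + 1L
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% 3)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||%
                              paste(rep(1, ndims), collapse = " "),
                            "\\s+")[[1]])
  or <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||%
                              paste(rep(0, ndims), collapse = " "),
                            "\\s+")[[1]])
  nchan <- as.integer(hdr$ElementNumberOfChannels %||% 1)
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("format error: compressed MetaImage not supported: ", path,
         call. = FALSE)
  type <- met_types[[hdr$ElementType %||% "MET_FLOAT"]]
  if (is.null(type))
    stop("format error: unsupported pixel type ", hdr$ElementType, " in ",
         path, call. = FALSE)
  n <- prod(dims) * nchan
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    seek(con, nbytes_header)
    raw_con <- con
    vals <- readBin(raw_con, type$what, n = n, size = type$size,
                    signed = type$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    rc <- file(raw_path, "rb")
    on.exit(close(rc), add = TRUE)
    vals <- readBin(rc, type$what, n = n, size = type$size,
                    signed = type$signed, endian = "little")
  }
  if (length(vals) != n)
    stop("format error: ", path, ": expected ", n, " values, got ",
         length(vals), call. = FALSE)
  vals <- as.double(vals)
  if (nchan > 1L) {
    # interleaved channels -> channel-last array
    arr <- aperm(array(vals, c(nchan, dims)), c(seq_along(dims) + 1L, 1L))
    dim(arr) <- c(dims, nchan)
  } else {
    arr <- array(vals, dims)
  }
  list(data = arr,
       spacing = c(sp, rep(1, max(0, 3 - length(sp))))[1:3],
       origin = c(or, rep(0, max(0, 3 - length(or))))[1:3])
}

write_metaimage <- function(arr, spacing, origin, path, datatype = "double",
                            channels = 1L) {
  ext <- file_ext_lower(path)
  mt <- switch(datatype,
               float = "MET_FLOAT", double = "MET_DOUBLE",
               int16 = "MET_SHORT",
               stop("unsupported datatype: ", datatype, call. = FALSE))
  type <- met_types[[mt]]
  d <- dim(arr)
  if (channels > 1L) {
    stopifnot(length(d) == 4L, d[4] == channels)
    dims <- d[1:3]
    vals <- as.vector(aperm(arr, c(4, 1, 2, 3)))  # interleave channels
  } else {
    dims <- d
    vals <- as.vector(arr)
  }
  hdr <- c("ObjectType = Image",
           paste0("NDims = ", length(dims)),
           paste0("DimSize = ", paste(dims, collapse = " ")),
           paste0("ElementType = ", mt),
           paste0("ElementSpacing = ", paste(spacing, collapse = " ")),
           paste0("Offset = ", paste(origin, collapse = " ")),
           if (channels > 1L) paste0("ElementNumberOfChannels = ", channels),
           "CompressedData = False",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False")
  if (type$what == "integer") {
    vals <- as.integer(round(vals))
  } else if (type$size == 4L) {
    vals <- as.double(vals)
  }
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(vals, con, size = type$size, endian = "little")
  } else if (ext == "mhd") {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste0("ElementDataFile = ", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(vals, con, size = type$size, endian = "little")
  } else stop("unsupported MetaImage extension: ", ext, call. = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
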