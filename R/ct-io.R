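#' Read a CT volume from NIfTI-1 or MetaImage
#'
#' Voxel spacing is taken from the file header. Units are inferred from the
#' data unless given: volumes containing negative or non-integer values are
#' tagged `"HU"`, otherwise `"raw_grey"`.
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.mhd` or `.mha` file.
#' @param format `"auto"` (from the extension), `"nifti"` or `"metaimage"`.
#' @param units Optional explicit units tag overriding the inference.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage"),
                        units = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  parsed <- switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
        arr <- array(arr, dim(arr)[1:3])
      list(data = arr, spacing = abs(RNifti::pixdim(img))[1:3])
    },
    metaimage = read_metaimage(path)
  )
  arr <- parsed$data
  if (length(dim(arr)) != 3L) stop("volume must be 3-D", call. = FALSE)
  arr <- array(as.double(arr), dim(arr))   # plain double array, no header attrs
  if (any(parsed$spacing <= 0))
    stop("non-positive voxel spacing in header", call. = FALSE)
  if (is.null(units)) {
    units <- if (min(arr) < 0 || any(arr != round(arr))) "HU" else "raw_grey"
  }
  ct_volume(arr, parsed$spacing, units = units)
}

#' Write a CT volume to NIfTI-1 or MetaImage
#'
#' Raw grey volumes are stored as 32-bit integers; HU volumes as
#' double-precision floats so that negative values (air at -1000 HU) survive
#' a round trip exactly.
#'
#' @param vol A [ct_volume()].
#' @param path Output path; extension selects the format when `format = "auto"`.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "metaimage")) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory not writable: %s", dirname(path)), call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    dtype <- if (vol$units == "HU") "double" else "int32"
    RNifti::writeNifti(img, path, datatype = dtype)
  } else {
    etype <- if (vol$units == "HU") "MET_DOUBLE" else "MET_INT"
    write_metaimage(vol$data, vol$spacing, path, etype)
  }
  invisible(path)
}

#' Read a binary VOI mask
#' @param path Mask file (NIfTI or MetaImage); voxel values must be 0/1.
#' @inheritParams read_volume
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "metaimage")) {
  v <- read_volume(path, format, units = "raw_grey")
  voi_mask(v$data, v$spacing)
}

#' Write a binary VOI mask (8-bit)
#' @param mask A [voi_mask()].
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "metaimage")) {
  stopifnot(inherits(mask, "voi_mask"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(mask$data)
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    write_metaimage(mask$data, mask$spacing, path, "MET_UCHAR")
  }
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mhd|mha)$", low)) return("metaimage")
  stop(sprintf("cannot infer format from extension: %s", path), call. = FALSE)
}

# --- MetaImage (.mhd header + .raw, or single-file .mha) ------------------
# Minimal ITK-conformant subset: 3-D, uncompressed, little-endian. The first
# listed dimension varies fastest, which coincides with R's array layout.

mi_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

write_metaimage <- function(arr, spacing, path, element_type) {
  ti <- mi_types[[element_type]]
  stopifnot(!is.null(ti))
  local_file <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_file) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, scientific = FALSE),
                                         collapse = " ")),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", datafile)
  )
  vec <- as.vector(arr)
  if (ti$what == "integer") vec <- as.integer(round(vec))
  if (local_file) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(vec, con, size = ti$size, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    writeBin(vec, con, size = ti$size, endian = "little")
  }
  invisible(path)
}

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_all == as.raw(10L))
  hdr_lines <- character()
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw_all[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    start <- pos + 1L
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { data_offset <- start; break }
  }
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  names(vals) <- trimws(keys)
  get <- function(k) unname(vals[k])
  ndims <- as.integer(get("NDims"))
  if (!isTRUE(ndims == 3L)) stop("volume must be 3-D", call. = FALSE)
  dims <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(get("ElementSpacing") %||% "1 1 1"),
                                 "\\s+")[[1]])
  ti <- mi_types[[trimws(get("ElementType"))]]
  if (is.null(ti)) stop("unsupported MetaImage ElementType", call. = FALSE)
  if (isTRUE(tolower(trimws(get("CompressedData"))) == "true"))
    stop("compressed MetaImage not supported", call. = FALSE)
  n <- prod(dims)
  datafile <- trimws(get("ElementDataFile"))
  if (toupper(datafile) == "LOCAL") {
    payload <- raw_all[data_offset:length(raw_all)]
    vec <- readBin(payload, ti$what, n = n, size = ti$size,
                   signed = ti$signed, endian = "little")
  } else {
    vec <- readBin(file.path(dirname(path), datafile), ti$what, n = n,
                   size = ti$size, signed = ti$signed, endian = "little")
  }
  if (length(vec) != n) stop("MetaImage payload truncated", call. = FALSE)
  list(data = array(vec, dims), spacing = spacing)
}
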