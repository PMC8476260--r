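#' Read a 3-D volume from NIfTI-1 or MetaImage
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`,
#' `.mhd` + raw). The full physical geometry (spacing, origin, direction) is
#' populated from the header; intensities of integer-typed files are preserved
#' losslessly.
#'
#' @param path path to an existing image file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- image_format(path)
  if (fmt == "nifti") read_nifti_volume(path) else read_meta_volume(path)
}

image_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("meta")
  stop("unsupported image format (expected .nii, .nii.gz, .mha or .mhd): ",
       path, call. = FALSE)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path, internal = FALSE)),
                  error = function(e)
                    stop("unreadable NIfTI file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("only 3-D volumes are supported: ", path, call. = FALSE)
  x <- RNifti::xform(img)
  A <- unclass(x)[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(A^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in header: ", path, call. = FALSE)
  direction <- sweep(A, 2, spacing, `/`)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("non-orthonormal direction matrix in header: ", path, call. = FALSE)
  # re-orthonormalize against float32 header storage noise
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  volume(arr, spacing = spacing, origin = unclass(x)[1:3, 4],
         direction = direction)
}

#' Write a volume to NIfTI-1 or MetaImage
#'
#' @param vol a [volume()] or [labelmap()].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`).
#' @param datatype on-disk scalar type: `"double"`, `"float"`, `"int16"` or
#'   `"uint8"`. Label maps default to unsigned 8-bit.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         datatype = if (inherits(vol, "labelmap")) "uint8"
                                    else "double") {
  stopifnot(inherits(vol, "volume"))
  fmt <- image_format(path)
  if (fmt == "nifti") write_nifti_volume(vol, path, datatype)
  else write_meta_volume(vol, path, datatype)
  invisible(path)
}

write_nifti_volume <- function(vol, path, datatype) {
  m <- rbind(cbind(vol$direction %*% diag(vol$spacing, 3L), vol$origin),
             c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$voxels, datatype = datatype)
  img$pixdim <- c(1, vol$spacing, 0, 0, 0, 0)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

#' Read a binary label map
#'
#' Values must be exactly 0 or 1 (integers, or floats equal to integers);
#' anything else is a validation error — there is no silent thresholding.
#'
#' @param path path to the label image.
#' @return A [labelmap()].
#' @export
read_labelmap <- function(path) {
  vol <- read_volume(path)
  v <- vol$voxels
  if (max(abs(v - round(v))) > 0)
    stop("label file contains non-integer values: ", path, call. = FALSE)
  bad <- sort(unique(round(v[!(round(v) %in% c(0, 1))])))
  if (length(bad))
    stop("label file contains values other than 0/1 (",
         paste(utils::head(bad, 10), collapse = ", "), "): ", path,
         call. = FALSE)
  labelmap(round(v), spacing = vol$spacing, origin = vol$origin,
           direction = vol$direction)
}

#' @rdname write_volume
#' @export
write_labelmap <- function(vol, path) write_volume(vol, path, "uint8")

# ---- MetaImage (uncompressed) -------------------------------------------

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_meta_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line,
                               call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data is not supported: ", path, call. = FALSE)
  if ((hdr$NDims %||% "3") != "3")
    stop("only 3-D MetaImage volumes are supported: ", path, call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||%
                                   stop("missing ElementSpacing: ", path,
                                        call. = FALSE), "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1",
                            "\\s+")[[1]])
  direction <- matrix(tm, 3L, 3L, byrow = TRUE)
  ty <- meta_types[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(ty)) stop("unsupported MetaImage ElementType: ",
                        hdr$ElementType, call. = FALSE)
  endian <- if (toupper(hdr$ElementByteOrderMSB %||%
                          hdr$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE")
    "big" else "little"
  datafile <- hdr$ElementDataFile
  if (toupper(datafile) != "LOCAL") {
    close(con)
    on.exit()
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("MetaImage data file not found: ", rawpath, call. = FALSE)
    con <- file(rawpath, "rb")
    on.exit(close(con))
  }
  n <- prod(dims)
  v <- readBin(con, ty$what, n = n, size = ty$size, signed = ty$signed,
               endian = endian)
  if (length(v) != n) stop("truncated MetaImage data: ", path, call. = FALSE)
  volume(array(as.double(v), dim = dims), spacing = spacing, origin = origin,
         direction = direction)
}

write_meta_volume <- function(vol, path, datatype) {
  ty <- switch(datatype,
               uint8 = "MET_UCHAR", int16 = "MET_SHORT",
               float = "MET_FLOAT", double = "MET_DOUBLE",
               stop("unsupported MetaImage datatype: ", datatype,
                    call. = FALSE))
  if (!grepl("\\.mha$", tolower(path)))
    stop("MetaImage writing supports single-file .mha only", call. = FALSE)
  d <- dim(vol$voxels)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =",
                 paste(format(as.vector(t(vol$direction)), digits = 17),
                       collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", ty),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  v <- as.vector(vol$voxels)
  sz <- switch(ty, MET_UCHAR = 1L, MET_SHORT = 2L, MET_FLOAT = 4L,
               MET_DOUBLE = 8L)
  if (ty %in% c("MET_UCHAR", "MET_SHORT"))
    writeBin(as.integer(round(v)), con, size = sz, endian = "little")
  else
    writeBin(as.double(v), con, size = sz, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
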