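#' Read and write volumes as NIfTI
#'
#' Volumes are held in LPS mm coordinates internally (the DICOM convention);
#' NIfTI stores an RAS+ affine, so the x and y axes are negated in the
#' on-disk transform. Only axis-aligned geometries are supported.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns an [image_volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  grid <- vol$grid
  data <- if (inherits(vol, "binary_mask")) array(as.integer(vol$data), dim = dim(vol$data)) else vol$data
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$spacing
  aff <- rbind(c(-grid$spacing[1], 0, 0, -grid$origin[1]),
               c(0, -grid$spacing[2], 0, -grid$origin[2]),
               c(0, 0, grid$spacing[3], grid$origin[3]),
               c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  origin <- c(-aff[1, 4], -aff[2, 4], aff[3, 4])
  data <- array(as.numeric(img), dim = dim(img))
  image_volume(volume_grid(dim(data), spacing, origin), data)
}

#' Read and write volumes as MetaImage (.mhd/.raw)
#'
#' MetaImage uses LPS mm natively, so geometry round-trips unchanged.
#' `element_type` selects the raw encoding: `"MET_SHORT"` (int16, CT),
#' `"MET_UCHAR"` (masks) or `"MET_DOUBLE"` (lossless).
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output `.mhd` path; the `.raw` file is written alongside.
#' @param element_type MetaImage element type string.
#' @return `write_volume_mhd()` returns `path` invisibly;
#'   `read_volume_mhd()` returns an [image_volume()] (use [binary_mask()]
#'   to reinterpret masks).
#' @export
write_volume_mhd <- function(vol, path,
                             element_type = if (inherits(vol, "binary_mask")) "MET_UCHAR" else "MET_DOUBLE") {
  grid <- vol$grid
  data <- if (inherits(vol, "binary_mask")) as.integer(vol$data) else as.vector(vol$data)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(grid$shape, collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  switch(element_type,
    MET_UCHAR = writeBin(as.raw(data), con),
    MET_SHORT = writeBin(as.integer(round(data)), con, size = 2, endian = "little"),
    MET_FLOAT = writeBin(as.numeric(data), con, size = 4, endian = "little"),
    MET_DOUBLE = writeBin(as.numeric(data), con, size = 8, endian = "little"),
    abort(paste("unsupported element type:", element_type),
          class = "bronchoplan_parameter_error")
  )
  invisible(path)
}

#' @rdname write_volume_mhd
#' @export
read_volume_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  getv <- function(k) vals[match(k, keys)]
  shape <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing"), "\\s+")[[1]])
  off <- getv("Offset")
  origin <- if (is.na(off)) c(0, 0, 0) else as.numeric(strsplit(off, "\\s+")[[1]])
  etype <- getv("ElementType")
  raw_path <- file.path(dirname(path), getv("ElementDataFile"))
  n <- prod(shape)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- switch(etype,
    MET_UCHAR = as.numeric(readBin(con, "raw", n = n)),
    MET_CHAR = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, endian = "little"),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    abort(paste("unsupported element type:", etype),
          class = "bronchoplan_input_error")
  )
  image_volume(volume_grid(shape, spacing, origin), array(data, dim = shape))
}

#' Read a volume by file type
#'
#' Dispatches on the path: a directory is read as a DICOM series
#' ([import_dicom()]), `.mhd` as MetaImage, `.nii`/`.nii.gz` as NIfTI.
#'
#' @param path File or DICOM directory path.
#' @param ... Passed on to the format reader.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, ...) {
  if (dir.exists(path)) return(import_dicom(path, ...))
  if (grepl("\\.mhd$", path)) return(read_volume_mhd(path))
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_volume_nifti(path))
  abort(paste("unrecognised volume format:", path),
        class = "bronchoplan_input_error")
}
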