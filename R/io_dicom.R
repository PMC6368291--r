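# Minimal DICOM support: uncompressed CT slice series in the explicit-VR
# little-endian transfer syntax, enough to emit test series and to import a
# folder of such slices with correct geometry. Values are parsed generically
# by VR; only the tags the volume geometry needs are interpreted.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.9000"

# pad to even length; `pad = "nul"` pads with a NUL byte (UI values)
dcm_pad <- function(s, pad = " ") {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) {
    r <- c(r, if (identical(pad, "nul")) as.raw(0L) else charToRaw(pad))
  }
  r
}

uint16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dcm_element <- function(group, elem, vr, value_raw) {
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  len <- length(value_raw)
  c(uint16le(group), uint16le(elem), charToRaw(vr),
    if (long_vr) c(as.raw(c(0, 0)), uint32le(len)) else uint16le(len),
    value_raw)
}

dcm_str <- function(group, elem, vr, value, pad = " ") {
  dcm_element(group, elem, vr, dcm_pad(as.character(value), pad))
}

dcm_us <- function(group, elem, value) {
  dcm_element(group, elem, "US", uint16le(value))
}

#' Write a volume as a DICOM CT slice series
#'
#' Emits one uncompressed explicit-VR little-endian CT file per axial slice,
#' with geometry (pixel spacing, image position/orientation) taken from the
#' volume grid in LPS mm. Intensities are stored as signed 16-bit HU
#' (rescale slope 1, intercept 0). Intended for generating self-contained
#' test series; it writes only the attribute subset [import_dicom()] reads.
#'
#' @param vol An [image_volume()].
#' @param dir Output directory (created if needed).
#' @param series_description Series description string.
#' @param series_number Integer distinguishing series in one folder (also
#'   seeds the generated series UID, so output is deterministic).
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(vol, dir, series_description = "CT",
                               series_number = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- vol$grid
  series_uid <- paste0(UID_ROOT, ".", series_number, ".",
                       sum(utf8ToInt(series_description)))
  for (k in seq_len(grid$shape[3])) {
    slice <- vol$data[, , k]
    ipp <- index_to_world(grid, c(1, 1, k))[1L, ]
    px <- as.integer(round(pmin(pmax(slice, -32768), 32767)))
    pix_raw <- writeBin(px, raw(), size = 2, endian = "little")
    sop_uid <- paste0(series_uid, ".", k)
    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", SOP_CT, pad = "nul"),
      dcm_str(0x0008, 0x0018, "UI", sop_uid, pad = "nul"),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0008, 0x103E, "LO", series_description),
      dcm_str(0x0020, 0x000E, "UI", series_uid, pad = "nul"),
      dcm_str(0x0020, 0x0011, "IS", series_number),
      dcm_str(0x0020, 0x0013, "IS", k),
      dcm_str(0x0020, 0x0032, "DS",
              paste(format(ipp, digits = 12), collapse = "\\")),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us(0x0028, 0x0002, 1),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, grid$shape[2]),   # Rows (y)
      dcm_us(0x0028, 0x0011, grid$shape[1]),   # Columns (x)
      dcm_str(0x0028, 0x0030, "DS",
              paste(format(grid$spacing[c(2, 1)], digits = 12), collapse = "\\")),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 1),
      dcm_str(0x0028, 0x1052, "DS", "0"),
      dcm_str(0x0028, 0x1053, "DS", "1"),
      dcm_str(0x0018, 0x0050, "DS", format(grid$spacing[3], digits = 12)),
      dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
    )
    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_str(0x0002, 0x0002, "UI", SOP_CT, pad = "nul"),
      dcm_str(0x0002, 0x0003, "UI", sop_uid, pad = "nul"),
      dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE, pad = "nul"),
      dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"), pad = "nul")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32le(length(meta_body))),
              meta_body)
    out <- c(raw(128), charToRaw("DICM"), meta, ds)
    writeBin(out, file.path(dir, sprintf("series%d_slice%04d.dcm",
                                         series_number, k)))
  }
  invisible(dir)
}

read_u16 <- function(r, at) {
  as.integer(r[at]) + 256L * as.integer(r[at + 1L])
}

read_u32 <- function(r, at) {
  as.numeric(r[at]) + 256 * as.numeric(r[at + 1L]) +
    65536 * as.numeric(r[at + 2L]) + 16777216 * as.numeric(r[at + 3L])
}

# Parse one explicit-VR-LE DICOM file; returns a named list keyed
# "gggg,eeee" with raw values, plus decoded convenience fields.
parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM") return(NULL)
  pos <- 133L
  out <- list()
  while (pos + 7L <= length(r)) {
    group <- read_u16(r, pos)
    elem <- read_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- read_u32(r, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- read_u16(r, pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 4294967295 || vstart + len - 1L > length(r)) break
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, value = if (len > 0) r[vstart:(vstart + len - 1L)] else raw())
    pos <- vstart + as.integer(len)
  }
  out
}

dcm_text <- function(el) {
  if (is.null(el)) return(NA_character_)
  v <- el$value
  # strip trailing space/NUL padding at the byte level (UI pads with NUL)
  while (length(v) && (v[length(v)] == as.raw(0L) || v[length(v)] == as.raw(32L))) {
    v <- v[-length(v)]
  }
  rawToChar(v)
}

dcm_numbers <- function(el) {
  if (is.null(el)) return(numeric())
  as.numeric(strsplit(dcm_text(el), "\\\\")[[1]])
}

dcm_u16val <- function(el) {
  if (is.null(el)) return(NA_integer_)
  read_u16(el$value, 1L)
}

#' List DICOM series in a folder
#'
#' @param folder Directory containing DICOM files (searched non-recursively).
#' @return A tibble with `series_uid`, `description`, `n_slices`.
#' @export
list_dicom_series <- function(folder) {
  files <- list.files(folder, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- purrr::compact(lapply(files, function(f) {
    p <- tryCatch(parse_dicom_file(f), error = function(e) NULL)
    if (is.null(p) || is.null(p[["0020,000e"]])) return(NULL)
    list(file = f, uid = dcm_text(p[["0020,000e"]]),
         desc = dcm_text(p[["0008,103e"]]), parsed = p)
  }))
  if (length(parsed) == 0L) {
    abort("no DICOM series found in folder.", class = "bronchoplan_input_error")
  }
  uids <- vapply(parsed, function(p) p$uid, "")
  tb <- tibble::tibble(series_uid = uids,
                       description = vapply(parsed, function(p) p$desc, ""))
  out <- dplyr::summarise(dplyr::group_by(tb, .data$series_uid, .data$description),
                          n_slices = dplyr::n(), .groups = "drop")
  attr(out, "parsed") <- parsed
  out
}

#' Import a DICOM CT series as an image volume
#'
#' Lists the series contained in `folder` and loads the selected one with
#' geometry (spacing, origin) taken from the DICOM attributes: pixel spacing
#' from PixelSpacing, slice spacing from successive ImagePositionPatient z
#' values (SliceThickness for single-slice series), origin from the first
#' slice's position. Supports uncompressed explicit-VR little-endian files
#' with axis-aligned orientation.
#'
#' @param folder Directory containing the DICOM files.
#' @param series_selector Integer index into the series listing, or a string
#'   matched against series descriptions and UIDs. With several series and
#'   no selector, or an ambiguous selector, the error lists the candidates.
#' @return An [image_volume()] in LPS mm.
#' @export
import_dicom <- function(folder, series_selector = NULL) {
  listing <- list_dicom_series(folder)
  parsed <- attr(listing, "parsed")
  pick <- if (is.null(series_selector)) {
    if (nrow(listing) > 1L) {
      abort(paste0("folder contains ", nrow(listing), " series; pass ",
                   "`series_selector`. Available: ",
                   paste(listing$description, collapse = ", ")),
            class = "bronchoplan_input_error")
    }
    1L
  } else if (is.numeric(series_selector)) {
    if (series_selector < 1 || series_selector > nrow(listing)) {
      abort(paste0("series index out of range; available: ",
                   paste(seq_len(nrow(listing)), listing$description,
                         collapse = ", ")),
            class = "bronchoplan_input_error")
    }
    as.integer(series_selector)
  } else {
    hit <- which(grepl(series_selector, listing$description, fixed = TRUE) |
                   grepl(series_selector, listing$series_uid, fixed = TRUE))
    if (length(hit) != 1L) {
      abort(paste0("selector matches ", length(hit), " series; available: ",
                   paste(listing$description, collapse = ", ")),
            class = "bronchoplan_input_error")
    }
    hit
  }
  uid <- listing$series_uid[pick]
  slices <- Filter(function(p) p$uid == uid, parsed)
  geo <- lapply(slices, function(s) {
    p <- s$parsed
    list(ipp = dcm_numbers(p[["0020,0032"]]),
         rows = dcm_u16val(p[["0028,0010"]]),
         cols = dcm_u16val(p[["0028,0011"]]),
         ps = dcm_numbers(p[["0028,0030"]]),
         slope = dcm_numbers(p[["0028,1053"]]) %||0% 1,
         intercept = dcm_numbers(p[["0028,1052"]]) %||0% 0,
         thick = dcm_numbers(p[["0018,0050"]]) %||0% 1,
         pix = p[["7fe0,0010"]]$value)
  })
  ord <- order(vapply(geo, function(g) g$ipp[3], numeric(1)))
  geo <- geo[ord]
  rows <- geo[[1]]$rows
  cols <- geo[[1]]$cols
  nz <- length(geo)
  dz <- if (nz > 1) geo[[2]]$ipp[3] - geo[[1]]$ipp[3] else geo[[1]]$thick
  spacing <- c(geo[[1]]$ps[2], geo[[1]]$ps[1], dz)  # PixelSpacing is row\col
  origin <- geo[[1]]$ipp
  data <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    v <- readBin(geo[[k]]$pix, "integer", n = rows * cols, size = 2,
                 endian = "little")
    data[, , k] <- geo[[k]]$slope * v + geo[[k]]$intercept
  }
  image_volume(volume_grid(c(cols, rows, nz), spacing, origin), data)
}

`%||0%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a[1]
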