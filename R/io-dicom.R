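#' Minimal DICOM I/O for single-frame CT slices
#'
#' A deliberately small single-frame CT DICOM codec: uncompressed
#' little-endian transfer syntaxes only (explicit VR `1.2.840.10008.1.2.1`
#' and implicit VR `1.2.840.10008.1.2`), single-frame grayscale pixel data.
#' On read, stored values are converted to HU with the mandatory rescale
#' slope/intercept; files missing those attributes are rejected by name.
#' Vendors encode the VMI energy of a slice inconsistently, so the energy
#' label is extracted by a configurable rule: a filename regex (default,
#' first capture group in keV) or an arbitrary data-element tag.
#'
#' Enhanced/multi-frame DICOM, compressed transfer syntaxes and sequences
#' with undefined length are out of scope.
#'
#' @param dir directory containing `.dcm`/`.DCM` files of identical shape.
#' @param energy_rule either `list(type = "filename", pattern = <regex>)`
#'   with one numeric capture group, or `list(type = "tag", group = <int>,
#'   element = <int>)` naming a data element whose string value parses as
#'   keV.
#' @return `read_dicom_series()`: a [vmi_series()] sorted by energy.
#' @export
read_dicom_series <- function(dir,
                              energy_rule = list(type = "filename",
                                                 pattern = "([0-9]+(?:\\.[0-9]+)?)\\s*[kK][eE]?[vV]")) {
  files <- list.files(dir, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_slice)
  energies <- vapply(seq_along(files), function(i) {
    e <- extract_energy(files[i], slices[[i]], energy_rule)
    if (is.na(e))
      stop("cannot parse VMI energy for file: ", files[i], call. = FALSE)
    e
  }, 0)
  d1 <- dim(slices[[1]]$pixels)
  for (i in seq_along(slices))
    if (!identical(dim(slices[[i]]$pixels), d1))
      stop("inconsistent matrix sizes across series (", files[i], ")",
           call. = FALSE)
  ord <- order(energies)
  vmi_series(Map(function(s, e) {
    ct_image(s$pixels, spacing = s$spacing, energy_kev = e, provenance = "vmi")
  }, slices[ord], energies[ord]), energies_kev = energies[ord])
}

extract_energy <- function(path, slice, rule) {
  if (identical(rule$type, "filename")) {
    m <- regmatches(basename(path), regexec(rule$pattern, basename(path)))[[1]]
    if (length(m) >= 2) return(suppressWarnings(as.numeric(m[2])))
    return(NA_real_)
  }
  if (identical(rule$type, "tag")) {
    key <- sprintf("%04X,%04X", rule$group, rule$element)
    v <- slice$elements[[key]]
    if (is.null(v)) return(NA_real_)
    m <- regmatches(v, regexpr("[0-9]+(\\.[0-9]+)?", v))
    if (!length(m)) return(NA_real_)
    return(suppressWarnings(as.numeric(m)))
  }
  stop("unknown energy rule type: ", rule$type, call. = FALSE)
}

dicom_vr_dict <- c(
  "0008,0060" = "CS", "0018,0060" = "DS", "0020,4000" = "LT",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW"
)

# Read one single-frame CT slice; returns pixels (HU), spacing, and the raw
# string elements encountered (for tag-based energy rules).
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 180 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  elements <- list()
  explicit <- TRUE        # file meta group is always explicit VR
  ts <- NULL
  rows <- cols <- bits <- NULL
  pixrep <- 0L
  slope <- intercept <- NULL
  spacing <- c(1, 1)
  pixels_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    key <- sprintf("%04X,%04X", grp, ele)
    if (grp != 2L && !is.null(ts)) {
      # first dataset element: switch VR mode per transfer syntax
      explicit <- ts != "1.2.840.10008.1.2"
      ts <- NULL
    }
    if (explicit || grp == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- dicom_vr_dict[key]
      if (is.na(vr)) vr <- "UN"
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length element not supported (", key, ") in ", path,
           call. = FALSE)
    body <- pos + hdr
    if (body + len - 1L > length(raw))
      stop("truncated DICOM element ", key, " in ", path, call. = FALSE)
    val_raw <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    if (key == "0002,0010") ts <- sub("\\s+$", "", rawToChar(val_raw))
    else if (key == "0028,0010") rows <- u16(body)
    else if (key == "0028,0011") cols <- u16(body)
    else if (key == "0028,0100") bits <- u16(body)
    else if (key == "0028,0103") pixrep <- u16(body)
    else if (key == "0028,0030") {
      sp <- as.numeric(strsplit(rawToChar(val_raw), "\\\\")[[1]])
      if (length(sp) == 2 && all(is.finite(sp))) spacing <- sp
    }
    else if (key == "0028,1052") intercept <- as.numeric(rawToChar(val_raw))
    else if (key == "0028,1053") slope <- as.numeric(rawToChar(val_raw))
    else if (key == "7FE0,0010") pixels_raw <- val_raw
    else if (vr %in% c("CS", "DS", "IS", "LO", "SH", "UI", "LT", "PN", "ST"))
      elements[[key]] <- sub("\\s+$", "", rawToChar(val_raw))
    pos <- body + len
    if (!is.null(pixels_raw)) break
  }
  if (is.null(rows) || is.null(cols) || is.null(pixels_raw))
    stop("missing Rows/Columns/PixelData in ", path, call. = FALSE)
  if (is.null(slope) || is.null(intercept))
    stop("missing RescaleSlope/RescaleIntercept in ", path, call. = FALSE)
  if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit pixel data supported: ", path, call. = FALSE)
  stored <- readBin(pixels_raw, "integer", rows * cols, size = 2,
                    signed = pixrep == 1L, endian = "little")
  if (length(stored) < rows * cols)
    stop("pixel data shorter than Rows*Columns in ", path, call. = FALSE)
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)   # DICOM pixel data is row-major
  list(pixels = hu, spacing = spacing, elements = elements)
}

#' @rdname read_dicom_series
#' @param img a [ct_image()] to write (HU values; stored as signed 16-bit
#'   with slope 1 / intercept -1024, clamping HU outside the storable range,
#'   as scanners do for extreme metal values).
#' @param path output file path.
#' @param comments free-text written to ImageComments (0020,4000).
#' @return `write_dicom_slice()` returns `path` invisibly.
#' @export
write_dicom_slice <- function(img, path, comments = NULL) {
  stopifnot(inherits(img, "ct_image"))
  intercept <- -1024; slope <- 1
  stored <- round((t(img$pixels) - intercept) / slope)  # row-major order
  stored <- pmin(pmax(stored, -32768), 32767)
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  elem_short <- function(grp, ele, vr, val_raw) {
    if (length(val_raw) %% 2 == 1) val_raw <- c(val_raw, as.raw(if (vr == "UI") 0 else 32))
    c(u16raw(grp), u16raw(ele), charToRaw(vr), u16raw(length(val_raw)), val_raw)
  }
  elem_long <- function(grp, ele, vr, val_raw) {
    c(u16raw(grp), u16raw(ele), charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(val_raw), raw(), size = 4, endian = "little"), val_raw)
  }
  s <- charToRaw
  meta <- c(
    elem_long(2, 1, "OB", as.raw(c(0, 1))),
    elem_short(2, 2, "UI", s("1.2.840.10008.5.1.4.1.1.2")),
    elem_short(2, 3, "UI", s(paste0("2.25.1", gsub("[^0-9]", "",
      sprintf("%.0f", abs(sum(img$pixels)) %% 1e12))))),
    elem_short(2, 16, "UI", s("1.2.840.10008.1.2.1"))
  )
  ds_txt <- function(x) s(format(x, trim = TRUE))
  body <- c(
    elem_short(8, 96, "CS", s("CT")),
    if (!is.null(comments)) elem_short(32, 16384, "LT", s(comments)),
    elem_short(40, 2, "US", u16raw(1)),
    elem_short(40, 4, "CS", s("MONOCHROME2")),
    elem_short(40, 16, "US", u16raw(nrow(img$pixels))),
    elem_short(40, 17, "US", u16raw(ncol(img$pixels))),
    elem_short(40, 48, "DS", s(paste(format(img$spacing, trim = TRUE), collapse = "\\"))),
    elem_short(40, 256, "US", u16raw(16)),
    elem_short(40, 257, "US", u16raw(16)),
    elem_short(40, 258, "US", u16raw(15)),
    elem_short(40, 259, "US", u16raw(1)),
    elem_short(40, 4178, "DS", ds_txt(intercept)),
    elem_short(40, 4179, "DS", ds_txt(slope)),
    elem_long(32736, 16, "OW",
              writeBin(as.integer(as.vector(stored)), raw(), size = 2,
                       endian = "little"))
  )
  glen <- elem_short(2, 0, "UL", writeBin(length(meta), raw(), size = 4,
                                          endian = "little"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(s("DICM"), con)
  writeBin(c(glen, meta, body), con)
  invisible(path)
}
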