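#' Array-container files for CT images and VMI series
#'
#' A small self-describing binary container used by the CLI and tests to
#' move slices and series between pipeline stages losslessly: a magic tag
#' and format version, a JSON header (shape, spacing in mm, energies in
#' keV, provenance), then pixel data as little-endian doubles. Round trips
#' are bit-faithful for pixels and exact for all metadata.
#'
#' @param object a [ct_image()] or [vmi_series()].
#' @param path file path to write to / read from.
#' @return `write_array_container()` returns `path` invisibly;
#'   `read_array_container()` returns the stored `ct_image` or `vmi_series`.
#' @examples
#' f <- tempfile(fileext = ".vmic")
#' img <- ct_image(matrix(rnorm(16), 4, 4), energy_kev = 70)
#' write_array_container(img, f)
#' identical(read_array_container(f)$pixels, img$pixels)
#' @export
write_array_container <- function(object, path) {
  if (inherits(object, "ct_image")) {
    header <- list(kind = "ct_image", dims = dim(object$pixels),
                   spacing = object$spacing, energy_kev = object$energy_kev,
                   provenance = object$provenance)
    payload <- list(as.vector(object$pixels))
  } else if (inherits(object, "vmi_series")) {
    header <- list(kind = "vmi_series", dims = dim(object$images[[1]]$pixels),
                   spacing = object$images[[1]]$spacing,
                   energies_kev = object$energies_kev,
                   provenance = vapply(object$images, `[[`, "", "provenance"))
    payload <- lapply(object$images, function(im) as.vector(im$pixels))
  } else {
    stop("object must be a ct_image or vmi_series", call. = FALSE)
  }
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VMIC"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(length(hjson), con, size = 4, endian = "little")
  writeBin(hjson, con)
  for (p in payload) writeBin(p, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_array_container
#' @export
read_array_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "VMIC"))
    stop("not an array-container file (bad magic): ", path, call. = FALSE)
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, 1L))
    stop("unsupported container version ", version, call. = FALSE)
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(hlen) || hlen <= 0 || hlen > 1e6)
    stop("corrupt container header: ", path, call. = FALSE)
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) stop("truncated container: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(rawToChar(hraw))
  dims <- as.integer(header$dims)
  npx <- prod(dims)
  read_img <- function(energy, prov) {
    v <- readBin(con, "double", npx, size = 8, endian = "little")
    if (length(v) < npx) stop("truncated pixel data: ", path, call. = FALSE)
    ct_image(matrix(v, dims[1], dims[2]), spacing = header$spacing,
             energy_kev = energy, provenance = prov)
  }
  if (identical(header$kind, "ct_image")) {
    read_img(header$energy_kev, header$provenance)
  } else if (identical(header$kind, "vmi_series")) {
    en <- as.numeric(header$energies_kev)
    prov <- rep_len(header$provenance, length(en))
    vmi_series(Map(read_img, en, prov), energies_kev = en)
  } else {
    stop("unknown container kind: ", header$kind, call. = FALSE)
  }
}
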