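#' CT image and VMI series containers
#'
#' A `ct_image` is a single 2D CT slice: a numeric matrix of CT numbers in
#' Hounsfield units (HU), pixel spacing in mm, an optional monochromatic
#' energy label in keV, and a free-text provenance tag. A `vmi_series` is an
#' ordered set of co-registered `ct_image` slices at strictly increasing
#' energies, as produced by a spectral CT system (virtual monochromatic
#' images, VMIs).
#'
#' Pixel indexing is row-major with row 1 at the top; row = y, column = x.
#' References in scanner documentation to e.g. the "200th row" are 1-based
#' and map directly to R's row index.
#'
#' @param pixels numeric matrix of CT numbers (HU); must be finite.
#' @param spacing numeric length-2 vector, (row, col) pixel size in mm.
#' @param energy_kev optional scalar energy label in keV.
#' @param provenance free-text tag, e.g. `"vmi"`, `"artifact"`, `"corrected"`.
#' @return `ct_image()` returns an object of class `ct_image`.
#' @examples
#' img <- ct_image(matrix(0, 8, 8), spacing = c(1, 1), energy_kev = 70)
#' img
#' @export
ct_image <- function(pixels, spacing = c(1, 1), energy_kev = NULL,
                     provenance = "vmi") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` contains non-finite values (NaN/Inf)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (length(spacing) != 2 || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be two strictly positive values (mm)", call. = FALSE)
  if (!is.null(energy_kev)) {
    energy_kev <- as.numeric(energy_kev)
    stopifnot(length(energy_kev) == 1, is.finite(energy_kev))
  }
  structure(
    list(pixels = unname(pixels), spacing = spacing,
         energy_kev = energy_kev, provenance = as.character(provenance)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  en <- if (is.null(x$energy_kev)) "unlabelled" else sprintf("%g keV", x$energy_kev)
  cat(sprintf("<ct_image> %d x %d px, %.3g x %.3g mm, %s [%s]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              en, x$provenance))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @rdname ct_image
#' @param images list of `ct_image` objects sharing shape and spacing.
#' @param energies_kev strictly increasing energies in `[40, 200]` keV, one
#'   per image; if `NULL`, taken from the images' own labels.
#' @return `vmi_series()` returns an object of class `vmi_series`.
#' @export
vmi_series <- function(images, energies_kev = NULL) {
  if (!length(images) || !all(vapply(images, inherits, TRUE, "ct_image")))
    stop("`images` must be a non-empty list of ct_image objects", call. = FALSE)
  if (is.null(energies_kev))
    energies_kev <- vapply(images, function(im) {
      if (is.null(im$energy_kev)) NA_real_ else im$energy_kev
    }, 0)
  energies_kev <- as.numeric(energies_kev)
  if (anyNA(energies_kev) || length(energies_kev) != length(images))
    stop("every image needs an energy label", call. = FALSE)
  if (is.unsorted(energies_kev, strictly = TRUE)) {
    ord <- order(energies_kev)
    images <- images[ord]
    energies_kev <- energies_kev[ord]
    if (is.unsorted(energies_kev, strictly = TRUE))
      stop("energies must be strictly increasing (duplicates present)",
           call. = FALSE)
  }
  if (any(energies_kev < 40 | energies_kev > 200))
    stop("VMI energies must lie in [40, 200] keV", call. = FALSE)
  ref <- images[[1]]
  for (im in images) {
    if (!identical(dim(im$pixels), dim(ref$pixels)))
      stop("all images in a series must share the same shape", call. = FALSE)
    if (max(abs(im$spacing - ref$spacing)) > 1e-9)
      stop("all images in a series must share the same spacing", call. = FALSE)
  }
  images <- Map(function(im, e) { im$energy_kev <- e; im }, images, energies_kev)
  structure(list(images = images, energies_kev = energies_kev),
            class = "vmi_series")
}

#' @export
print.vmi_series <- function(x, ...) {
  d <- dim(x$images[[1]]$pixels)
  cat(sprintf("<vmi_series> %d energies (%s keV), %d x %d px\n",
              length(x$energies_kev),
              paste(x$energies_kev, collapse = ", "), d[1], d[2]))
  invisible(x)
}

#' @export
length.vmi_series <- function(x) length(x$images)

#' Extract one slice of a VMI series by energy
#'
#' @param series a `vmi_series`.
#' @param energy_kev energy label of the wanted slice.
#' @return the matching `ct_image`.
#' @export
series_at <- function(series, energy_kev) {
  stopifnot(inherits(series, "vmi_series"))
  i <- match(energy_kev, series$energies_kev)
  if (is.na(i))
    stop(sprintf("no slice at %g keV (have: %s)", energy_kev,
                 paste(series$energies_kev, collapse = ", ")), call. = FALSE)
  series$images[[i]]
}

same_grid <- function(a, b) {
  identical(dim(a$pixels), dim(b$pixels)) &&
    max(abs(a$spacing - b$spacing)) <= 1e-9
}

#' Water/bone material basis image pair
#'
#' Co-registered basis-density images from two-material decomposition:
#' `water` and `bone` are matrices in g/cm^3 on a shared grid. Negative bone
#' values are permitted — solid-water phantom materials and soft tissue are
#' not pure water, and their bone component is legitimately negative; no
#' clipping is applied anywhere.
#'
#' @param water,bone numeric matrices (g/cm^3), same shape.
#' @param spacing pixel size in mm, (row, col).
#' @return an object of class `mbi_pair`.
#' @export
mbi_pair <- function(water, bone, spacing = c(1, 1)) {
  if (!identical(dim(water), dim(bone)))
    stop("water and bone basis images must share shape", call. = FALSE)
  if (!all(is.finite(water)) || !all(is.finite(bone)))
    stop("basis images must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  stopifnot(length(spacing) == 2, all(spacing > 0))
  structure(list(water = unname(water), bone = unname(bone), spacing = spacing),
            class = "mbi_pair")
}

#' @export
print.mbi_pair <- function(x, ...) {
  cat(sprintf("<mbi_pair> %d x %d px; water [%.3f, %.3f], bone [%.3f, %.3f] g/cm^3\n",
              nrow(x$water), ncol(x$water), min(x$water), max(x$water),
              min(x$bone), max(x$bone)))
  invisible(x)
}
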