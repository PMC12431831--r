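#' Metal segmentation by HU thresholding
#'
#' Separates metal components from tissue by thresholding CT numbers:
#' titanium and other implant metals sit far above 3000 HU in VMIs while
#' cortical bone stays below ~2000 HU, so the default 2500 HU cleanly
#' splits them. Isolated specks below `min_area_px` connected pixels are
#' discarded as noise.
#'
#' @param ct a [ct_image()].
#' @param threshold_hu threshold in HU; must exceed 1000 (below that, bone
#'   and contrast would be swept into the metal mask).
#' @param min_area_px smallest connected component kept, in pixels.
#' @return binary integer matrix (1 = metal). An empty mask is legal and
#'   signals "no metal found"; the pipeline then skips correction.
#' @export
segment_metal <- function(ct, threshold_hu = 2500, min_area_px = 9) {
  stopifnot(inherits(ct, "ct_image"))
  if (threshold_hu <= 1000)
    stop("`threshold_hu` must exceed 1000 HU", call. = FALSE)
  mask <- ct$pixels >= threshold_hu
  if (any(mask) && min_area_px > 1) {
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Preliminary sinogram-interpolation MAR
#'
#' Coarse interpolation-based metal artifact correction in the lineage of
#' the classic sinogram-completion methods: forward-project the image and
#' the metal mask, replace detector bins shadowed by metal with 1D linear
#' interpolation from the nearest unshadowed bins (per angle), reconstruct
#' by ramp-filtered back projection, and re-insert the original metal
#' pixels. It is intentionally rough: its purpose is to expose where the
#' prominent artifacts are (via the difference from the input), not to
#' produce a diagnostic image.
#'
#' @param ct square [ct_image()].
#' @param metal binary metal mask (non-empty).
#' @param n_angles projection angles over `[0, 180)`.
#' @param cap_hu ceiling applied to pixel values before forward projection
#'   (scanner images are stored 12-bit-clipped near 3071 HU; capping keeps
#'   the ramp-filter side lobes of the metal trace from polluting the
#'   extracted artifact image when the input carries unclipped synthetic
#'   metal values).
#' @param window reconstruction filter window (see [fbp_reconstruct()]);
#'   the apodized default keeps filter ripple from the enormous metal
#'   trace out of the extracted artifact image.
#' @return a [ct_image()] with provenance `"preliminary_mar"`.
#' @export
preliminary_mar <- function(ct, metal, n_angles = 180, cap_hu = 3071,
                            window = "hann") {
  stopifnot(inherits(ct, "ct_image"))
  if (nrow(ct$pixels) != ncol(ct$pixels))
    stop("preliminary MAR needs a square image (pad first)", call. = FALSE)
  if (!any(metal > 0))
    stop("empty metal mask: nothing to correct", call. = FALSE)
  if (!identical(dim(metal), dim(ct$pixels)))
    stop("metal mask shape mismatch", call. = FALSE)
  sino <- radon_transform(pmin(ct$pixels, cap_hu), n_angles = n_angles)
  msino <- radon_transform(metal + 0, n_angles = n_angles,
                           n_bins = ncol(sino$values))
  vals <- sino$values
  shadow <- msino$values > 1e-6
  for (a in seq_len(nrow(vals))) {
    bad <- which(shadow[a, ])
    if (!length(bad)) next
    good <- which(!shadow[a, ])
    if (length(good) < 2) next
    vals[a, bad] <- stats::approx(good, vals[a, good], xout = bad,
                                  rule = 2)$y
  }
  # reconstruct the modification, not the whole sinogram: FBP is linear, so
  # image - FBP(original - interpolated) equals FBP(interpolated sinogram)
  # analytically, but the forward/inverse roundtrip error cancels exactly
  # outside the metal shadow instead of polluting the artifact image
  sino$values <- sino$values - vals
  rec <- ct$pixels - fbp_reconstruct(sino, n = nrow(ct$pixels),
                                     window = window)
  rec[metal > 0] <- ct$pixels[metal > 0]
  ct_image(rec, spacing = ct$spacing, energy_kev = ct$energy_kev,
           provenance = "preliminary_mar")
}

#' Artifact image extraction
#'
#' The artifact image is the input VMI minus its preliminary-MAR-corrected
#' version, with metal pixels forced to zero: what remains is the streak
#' and shading content attributable to the metal.
#'
#' @param ct input [ct_image()].
#' @param corrected its preliminary-MAR correction (same grid).
#' @param metal binary metal mask.
#' @return a [ct_image()] with provenance `"artifact"`.
#' @export
artifact_image <- function(ct, corrected, metal) {
  stopifnot(inherits(ct, "ct_image"), inherits(corrected, "ct_image"))
  if (!same_grid(ct, corrected))
    stop("input and corrected images must share a grid", call. = FALSE)
  diffr <- ct$pixels - corrected$pixels
  diffr[metal > 0] <- 0
  ct_image(diffr, spacing = ct$spacing, energy_kev = ct$energy_kev,
           provenance = "artifact")
}

#' Total-variation artifact cost
#'
#' Sums the isotropic forward-difference gradient magnitude
#' `sqrt((f(x+1,y) - f(x,y))^2 + (f(x,y+1) - f(x,y))^2)` over all pixels
#' whose two forward neighbours exist (the last row and column carry no
#' term). With `exclude` set, a pixel contributes only if it and both
#' forward neighbours lie outside the excluded mask — used to keep the
#' enormous metal-edge gradients out of the artifact score.
#'
#' @param img a [ct_image()] or numeric matrix, at least 2x2.
#' @param exclude optional binary mask of pixels to leave out (e.g. metal).
#' @return scalar cost (HU per pixel step, summed).
#' @export
tv_cost <- function(img, exclude = NULL) {
  m <- if (inherits(img, "ct_image")) img$pixels else img
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  nr <- nrow(m); nc <- ncol(m)
  core <- m[-nr, -nc, drop = FALSE]
  dd <- m[-1, -nc, drop = FALSE] - core   # next row
  dr <- m[-nr, -1, drop = FALSE] - core   # next column
  g <- sqrt(dd^2 + dr^2)
  if (!is.null(exclude)) {
    stopifnot(identical(dim(exclude), dim(m)))
    e <- exclude > 0
    valid <- !e[-nr, -nc, drop = FALSE] & !e[-1, -nc, drop = FALSE] &
      !e[-nr, -1, drop = FALSE]
    g <- g[valid]
  }
  sum(g)
}

#' Normalized TV cost curve across a VMI series
#'
#' Scores each artifact image with [tv_cost()] (metal excluded) and
#' normalizes by the maximum, so the worst image scores exactly 1 and all
#' scores lie in (0, 1]. The curve is the quantitative instrument for
#' picking the optimal (least-artifact) and worst (most-artifact) energy.
#'
#' @param artifact_images list of >= 2 [ct_image()]s (artifact images).
#' @param energies_kev energies aligned with the images.
#' @param exclude optional shared exclusion mask (metal).
#' @return an object of class `cost_curve`: a data.frame with columns
#'   `index`, `energy_kev`, `cost`, `cost_norm`.
#' @export
cost_curve <- function(artifact_images, energies_kev, exclude = NULL) {
  if (length(artifact_images) < 2)
    stop("need at least two artifact images", call. = FALSE)
  stopifnot(length(energies_kev) == length(artifact_images))
  costs <- vapply(artifact_images, tv_cost, 0, exclude = exclude)
  df <- data.frame(index = seq_along(costs), energy_kev = energies_kev,
                   cost = costs, cost_norm = costs / max(costs))
  class(df) <- c("cost_curve", "data.frame")
  df
}

#' @rdname cost_curve
#' @param curve a `cost_curve`.
#' @return `select_optimal()` / `select_worst()` return the energy (keV)
#'   with the minimal / maximal normalized cost. Ties resolve to the higher
#'   energy for the optimum (high energies carry intrinsically fewer
#'   artifacts) and the lower energy for the worst.
#' @export
select_optimal <- function(curve) {
  stopifnot(inherits(curve, "cost_curve"))
  if (nrow(curve) < 2) stop("cost curve has fewer than 2 entries", call. = FALSE)
  cand <- curve$energy_kev[curve$cost_norm == min(curve$cost_norm)]
  max(cand)
}

#' @rdname cost_curve
#' @export
select_worst <- function(curve) {
  stopifnot(inherits(curve, "cost_curve"))
  if (nrow(curve) < 2) stop("cost curve has fewer than 2 entries", call. = FALSE)
  cand <- curve$energy_kev[curve$cost_norm == max(curve$cost_norm)]
  min(cand)
}

#' Sorting-and-thresholding segmentation (STS) mask
#'
#' Row-wise artifact flagging on an artifact image: within each row, the
#' pixels inside the body support are sorted, their median taken, and
#' bounds set at median +/- `delta_hu`; pixels outside the bounds are
#' flagged as artifact. A local (per-row) criterion is used because no
#' single global threshold separates artifact from anatomy across
#' datasets. The raw flags are then cleaned up by binary dilation with a
#' disc of radius `dilation_px` followed by erosion with a disc of radius
#' `erosion_px`. Rows with fewer than 3 support pixels are skipped (their
#' median is meaningless).
#'
#' @param artifact artifact [ct_image()] (or matrix).
#' @param support binary body-support mask on the same grid.
#' @param delta_hu half-width of the row acceptance band, HU (> 0).
#' @param erosion_px erosion disc radius in pixels (4 for the coarse STS1
#'   pass, 1 for the fine STS2 pass).
#' @param dilation_px dilation disc radius in pixels.
#' @param morphology set `FALSE` to return the raw pre-morphology flags.
#' @return binary integer matrix of flagged artifact pixels.
#' @export
sts_mask <- function(artifact, support, delta_hu = 10, erosion_px = 1,
                     dilation_px = 2, morphology = TRUE) {
  m <- if (inherits(artifact, "ct_image")) artifact$pixels else artifact
  stopifnot(identical(dim(support), dim(m)), delta_hu > 0)
  if (!any(support > 0)) stop("empty support mask", call. = FALSE)
  flags <- matrix(0L, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    in_row <- which(support[r, ] > 0)
    if (length(in_row) < 3) next
    v <- m[r, in_row]
    med <- stats::median(v)
    out <- v < med - delta_hu | v > med + delta_hu
    flags[r, in_row[out]] <- 1L
  }
  if (!morphology) return(flags)
  apply_morphology(flags, dilation_px, erosion_px)
}

apply_morphology <- function(mask, dilation_px, erosion_px) {
  out <- mask > 0
  if (dilation_px > 0)
    out <- EBImage::dilate(out, EBImage::makeBrush(2L * dilation_px + 1L, "disc"))
  if (erosion_px > 0)
    out <- EBImage::erode(out, EBImage::makeBrush(2L * erosion_px + 1L, "disc"))
  m <- matrix(as.integer(out > 0), nrow(mask), ncol(mask))
  m
}

#' Binary mask set for regional correction
#'
#' Bundles the four co-registered masks the regional model needs: the
#' artifact mask `f_M1`, the artifact-free mask `f_M0`, the metal mask,
#' and the body support. Within the support and off metal the two masks
#' are exact complements (`f_M0 = 1 - f_M1`); metal belongs to neither.
#'
#' @param artifact,artifact_free,metal,support binary matrices, one grid.
#' @param meta optional list of diagnostics carried along.
#' @return object of class `mask_set`.
#' @export
mask_set <- function(artifact, artifact_free, metal, support, meta = list()) {
  dims <- dim(artifact)
  for (m in list(artifact_free, metal, support))
    if (!identical(dim(m), dims)) stop("mask shapes differ", call. = FALSE)
  a <- artifact > 0; f <- artifact_free > 0; mt <- metal > 0; s <- support > 0
  if (any(a & mt) || any(f & mt))
    stop("metal must be disjoint from both artifact masks", call. = FALSE)
  if (any(a & !s))
    stop("artifact mask must lie within the support", call. = FALSE)
  if (!all((a | f | mt) == s) || any(a & f))
    stop("artifact, artifact-free and metal masks must partition the support",
         call. = FALSE)
  structure(list(artifact = matrix(as.integer(a), dims[1], dims[2]),
                 artifact_free = matrix(as.integer(f), dims[1], dims[2]),
                 metal = matrix(as.integer(mt), dims[1], dims[2]),
                 support = matrix(as.integer(s), dims[1], dims[2]),
                 meta = meta),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> support %d px | artifact %d | artifact-free %d | metal %d\n",
              sum(x$support), sum(x$artifact), sum(x$artifact_free), sum(x$metal)))
  invisible(x)
}

#' Build the artifact / artifact-free mask set for a VMI series
#'
#' Full mask-generation workflow: segment metal and the body support on the
#' optimal VMI, extract artifact images at the selected energies through
#' preliminary MAR, rank them with the normalized TV cost curve, then run
#' STS twice — the coarse pass (STS1, 4-pixel erosion) on the worst-energy
#' artifact image, where artifacts are strongest, and the fine pass (STS2,
#' 1-pixel erosion) on the optimal-energy artifact image, to sharpen the
#' artifact-free complement. The artifact mask `f_M1` is the union of the
#' two passes clipped to the support and stripped of metal.
#'
#' @param series a [vmi_series()] with at least two of the configured
#'   selected energies.
#' @param table an [atten_table()] (reserved for configs that re-synthesize
#'   intermediate energies).
#' @param cfg a [rmar_config()].
#' @return a [mask_set()] whose `meta` records the cost curve, optimal and
#'   worst energies, and the artifact images used.
#' @export
build_masks <- function(series, table = atten_table(), cfg = rmar_config()) {
  stopifnot(inherits(series, "vmi_series"))
  sel <- intersect(cfg$selected_energies, series$energies_kev)
  if (length(sel) < 2)
    stop("need >= 2 of the selected energies in the series", call. = FALSE)
  # provisional metal mask from the highest selected energy (thresholding is
  # energy-insensitive for implant metals), refined on the optimal VMI below
  metal <- segment_metal(series_at(series, max(sel)),
                         threshold_hu = cfg$metal_threshold_hu,
                         min_area_px = cfg$metal_min_area_px)
  if (!any(metal > 0))
    stop("no metal found in series", call. = FALSE)
  arts <- lapply(sel, function(e) {
    vmi <- series_at(series, e)
    artifact_image(vmi, preliminary_mar(vmi, metal, n_angles = cfg$n_angles),
                   metal)
  })
  curve <- cost_curve(arts, sel, exclude = metal)
  opt <- select_optimal(curve)
  worst <- select_worst(curve)
  vmi0 <- series_at(series, opt)
  metal <- segment_metal(vmi0, threshold_hu = cfg$metal_threshold_hu,
                         min_area_px = cfg$metal_min_area_px)
  support <- support_mask(vmi0, threshold_hu = cfg$support_threshold_hu)
  sts1 <- sts_mask(arts[[match(worst, sel)]], support,
                   delta_hu = cfg$sts_delta_hu,
                   erosion_px = cfg$sts1_erosion_px,
                   dilation_px = cfg$dilation_px)
  sts2 <- sts_mask(arts[[match(opt, sel)]], support,
                   delta_hu = cfg$sts_delta_hu,
                   erosion_px = cfg$sts2_erosion_px,
                   dilation_px = cfg$dilation_px)
  f_m1 <- (sts1 | sts2) & support > 0 & !(metal > 0)
  f_m0 <- support > 0 & !(metal > 0) & !f_m1
  mask_set(f_m1, f_m0, metal, support,
           meta = list(curve = curve, optimal_kev = opt, worst_kev = worst,
                       artifact_images = stats::setNames(arts, sel)))
}

#' Body support mask
#'
#' Pixels above `threshold_hu` (default -500 HU, well above air) with holes
#' filled; restricting STS to the support keeps air from dominating the
#' row medians.
#'
#' @param ct a [ct_image()].
#' @param threshold_hu lower HU bound for "inside the object".
#' @return binary integer matrix.
#' @export
support_mask <- function(ct, threshold_hu = -500) {
  stopifnot(inherits(ct, "ct_image"))
  m <- ct$pixels > threshold_hu
  filled <- EBImage::fillHull(m)
  out <- matrix(as.integer(filled > 0), nrow(m), ncol(m))
  out
}

#' Write a cost curve as CSV
#'
#' @param curve a `cost_curve`.
#' @param path output CSV path (columns index, energy_kev, C, C_norm).
#' @return `path`, invisibly.
#' @export
write_cost_curve <- function(curve, path) {
  df <- data.frame(index = curve$index, energy_kev = curve$energy_kev,
                   C = curve$cost, C_norm = curve$cost_norm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask > 0) + 0), path, type = "png")
  invisible(path)
}
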