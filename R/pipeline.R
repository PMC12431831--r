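#' Pipeline configuration
#'
#' Collects every tunable of the regional MAR pipeline with the defaults
#' used throughout: decomposition energy pair (70, 140) keV — the extremes
#' of the usual clinical VMI set; the selected cost-curve energies 70, 80,
#' 100, 120, 140 keV; STS band half-width 10 HU; STS1/STS2 erosion radii
#' 4 and 1 px with a 2 px dilation; metal threshold 2500 HU; bone
#' exclusion at 150 HU; 180 projection angles; support threshold -500 HU.
#'
#' @param decomp_energies length-2 energies (keV) for basis decomposition.
#' @param selected_energies energies scored by the TV cost curve.
#' @param metal_threshold_hu metal segmentation threshold (> 1000 HU).
#' @param metal_min_area_px minimum metal component area, px.
#' @param sts_delta_hu STS acceptance band half-width, HU.
#' @param sts1_erosion_px,sts2_erosion_px erosion disc radii of the coarse
#'   and fine STS passes, px.
#' @param dilation_px dilation disc radius of both STS passes, px.
#' @param bone_exclude_hu HU ceiling for model-fitting pixels.
#' @param n_angles projection angles for preliminary MAR.
#' @param support_threshold_hu HU floor of the body-support mask.
#' @param output_energies energies (keV) of the corrected series; `NULL`
#'   means all input energies.
#' @param seed integer seed for any sampling the pipeline performs.
#' @return a list of class `rmar_config`.
#' @export
rmar_config <- function(decomp_energies = c(70, 140),
                        selected_energies = c(70, 80, 100, 120, 140),
                        metal_threshold_hu = 2500,
                        metal_min_area_px = 9,
                        sts_delta_hu = 10,
                        sts1_erosion_px = 4,
                        sts2_erosion_px = 1,
                        dilation_px = 2,
                        bone_exclude_hu = 150,
                        n_angles = 180,
                        support_threshold_hu = -500,
                        output_energies = NULL,
                        seed = 1) {
  stopifnot(length(decomp_energies) == 2, decomp_energies[1] != decomp_energies[2],
            metal_threshold_hu > 1000, sts_delta_hu > 0,
            sts1_erosion_px >= 0, sts2_erosion_px >= 0, dilation_px >= 0,
            n_angles >= 2)
  structure(list(decomp_energies = decomp_energies,
                 selected_energies = selected_energies,
                 metal_threshold_hu = metal_threshold_hu,
                 metal_min_area_px = metal_min_area_px,
                 sts_delta_hu = sts_delta_hu,
                 sts1_erosion_px = sts1_erosion_px,
                 sts2_erosion_px = sts2_erosion_px,
                 dilation_px = dilation_px,
                 bone_exclude_hu = bone_exclude_hu,
                 n_angles = n_angles,
                 support_threshold_hu = support_threshold_hu,
                 output_energies = output_energies,
                 seed = seed),
            class = "rmar_config")
}

#' Run the regional model-based MAR pipeline
#'
#' End-to-end correction of a VMI series: (1) decompose the configured
#' energy pair into water/bone basis images; (2) locate artifacts —
#' preliminary MAR at the selected energies, artifact images, normalized
#' TV cost curve, optimal and worst energy; (3) build the artifact /
#' artifact-free mask set; (4-5) fit the regional quadratic mapping from
#' the optimal VMI's CT numbers to each basis on artifact-free pixels
#' (bone excluded); (6-7) map artifact-region pixels through the models
#' and assemble the improved basis images; (8) synthesize the corrected
#' series at the output energies. Corrected slices keep the input pixel
#' values everywhere outside the artifact mask, and metal pixels are
#' copied from the input unchanged, so the correction is strictly local.
#'
#' A series with no detectable metal is returned unchanged with the
#' `no_metal` flag set — implant-free series are valid inputs, not errors.
#' The pipeline is deterministic given its configuration.
#'
#' @param series input [vmi_series()] containing the decomposition pair.
#' @param cfg an [rmar_config()].
#' @param table an [atten_table()].
#' @return an object of class `rmar_result`: `series` (corrected),
#'   `input_series`, `mbi_original`, `mbi_improved`, `masks`, `curve`,
#'   `models` (water/bone), `optimal_kev`, `worst_kev`, `no_metal`,
#'   `report` (structured log of every stage).
#' @export
run_rmar <- function(series, cfg = rmar_config(), table = atten_table()) {
  stopifnot(inherits(series, "vmi_series"), inherits(cfg, "rmar_config"))
  if (!all(cfg$decomp_energies %in% series$energies_kev))
    stop("series lacks the decomposition energies (",
         paste(cfg$decomp_energies, collapse = ", "), " keV)", call. = FALSE)
  out_e <- if (is.null(cfg$output_energies)) series$energies_kev else
    cfg$output_energies
  # stage 1: material decomposition
  mbi0 <- decompose_mbi(series_at(series, cfg$decomp_energies[1]),
                        series_at(series, cfg$decomp_energies[2]), table)
  # no-metal short circuit: graceful no-op
  probe <- segment_metal(series_at(series, max(series$energies_kev)),
                         threshold_hu = cfg$metal_threshold_hu,
                         min_area_px = cfg$metal_min_area_px)
  if (!any(probe > 0)) {
    return(structure(list(series = series, input_series = series,
                          mbi_original = mbi0, mbi_improved = mbi0,
                          masks = NULL, curve = NULL, models = NULL,
                          optimal_kev = NA_real_, worst_kev = NA_real_,
                          no_metal = TRUE,
                          report = list(no_metal = TRUE, config = cfg)),
                     class = "rmar_result"))
  }
  # stages 2-3: cost curve, optimal/worst energy, mask set
  masks <- build_masks(series, table, cfg)
  vmi0 <- series_at(series, masks$meta$optimal_kev)
  # stages 4-5: regional models on artifact-free pixels
  model_w <- fit_mapping(vmi0, mbi0$water, masks,
                         bone_exclude_hu = cfg$bone_exclude_hu, target = "water")
  model_b <- fit_mapping(vmi0, mbi0$bone, masks,
                         bone_exclude_hu = cfg$bone_exclude_hu, target = "bone")
  # stages 6-7: correct the basis images inside the artifact mask
  mbi_imp <- correct_mbis(mbi0, masks, model_w, model_b, vmi0)
  # stage 8: corrected series, strictly local to the artifact mask
  sel <- masks$artifact > 0
  corrected <- lapply(out_e, function(e) {
    base <- if (e %in% series$energies_kev) series_at(series, e) else
      synthesize_vmi(mbi0, e, table)
    repl <- synthesize_vmi(mbi_imp, e, table)
    px <- base$pixels
    px[sel] <- repl$pixels[sel]
    ct_image(px, spacing = base$spacing, energy_kev = e,
             provenance = "corrected")
  })
  corrected <- vmi_series(corrected, out_e)
  report <- list(
    no_metal = FALSE,
    optimal_kev = masks$meta$optimal_kev,
    worst_kev = masks$meta$worst_kev,
    cost_curve = data.frame(energy_kev = masks$meta$curve$energy_kev,
                            C = masks$meta$curve$cost,
                            C_norm = masks$meta$curve$cost_norm),
    mask_areas_px = c(support = sum(masks$support), metal = sum(masks$metal),
                      artifact = sum(masks$artifact),
                      artifact_free = sum(masks$artifact_free)),
    fit = list(water = unclass(model_w), bone = unclass(model_b)),
    output_energies = out_e,
    config = cfg)
  structure(list(series = corrected, input_series = series,
                 mbi_original = mbi0, mbi_improved = mbi_imp,
                 masks = masks, curve = masks$meta$curve,
                 models = list(water = model_w, bone = model_b),
                 optimal_kev = masks$meta$optimal_kev,
                 worst_kev = masks$meta$worst_kev,
                 no_metal = FALSE, report = report),
            class = "rmar_result")
}

#' @export
print.rmar_result <- function(x, ...) {
  if (x$no_metal) {
    cat("<rmar_result> no metal found: input returned unchanged\n")
    return(invisible(x))
  }
  cat(sprintf("<rmar_result> optimal %g keV, worst %g keV\n",
              x$optimal_kev, x$worst_kev))
  cat(sprintf("  artifact mask %d px (%.1f%% of support), metal %d px\n",
              sum(x$masks$artifact),
              100 * sum(x$masks$artifact) / sum(x$masks$support),
              sum(x$masks$metal)))
  invisible(x)
}

roi_pixel_mask <- function(img, roi) {
  n_r <- nrow(img$pixels); n_c <- ncol(img$pixels)
  if (!is.null(roi$rect_px)) {
    m <- matrix(FALSE, n_r, n_c)
    m[roi$rect_px[1]:roi$rect_px[2], roi$rect_px[3]:roi$rect_px[4]] <- TRUE
    return(m)
  }
  if (!is.null(roi$center_mm)) {
    cx_px <- roi$center_mm[1] / img$spacing[2] + n_c / 2 + 0.5
    cy_px <- roi$center_mm[2] / img$spacing[1] + n_r / 2 + 0.5
    r_px <- roi$radius_mm / img$spacing[1]
  } else {
    cx_px <- roi$center_px[1]; cy_px <- roi$center_px[2]
    r_px <- roi$radius_px
  }
  rows <- matrix(seq_len(n_r), n_r, n_c)
  cols <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  (cols - cx_px)^2 + (rows - cy_px)^2 <= r_px^2
}

#' Mean CT-number deviation in a region of interest
#'
#' Computes `delta_ct = mean(CT in ROI) - ref_hu`: the mean CT number of
#' the ROI minus a reference value. Smaller magnitude means a more
#' accurate correction. The ROI is a circle given either in mm
#' (`center_mm`/`radius_mm`, origin at image centre, x = columns) or in
#' pixels (`center_px` as (col, row) / `radius_px`), or a pixel rectangle
#' `rect_px = c(row0, row1, col0, col1)`.
#'
#' @param img a [ct_image()].
#' @param roi ROI specification (list, see above).
#' @param ref_hu reference CT number, HU.
#' @return one-row data.frame of class `roi_stats`: `mean_hu`, `ref_hu`,
#'   `delta_ct`, `n_px`.
#' @export
delta_ct <- function(img, roi, ref_hu) {
  stopifnot(inherits(img, "ct_image"))
  m <- roi_pixel_mask(img, roi)
  if (!any(m)) stop("ROI contains no pixels inside the image", call. = FALSE)
  mean_hu <- mean(img$pixels[m])
  out <- data.frame(mean_hu = mean_hu, ref_hu = ref_hu,
                    delta_ct = mean_hu - ref_hu, n_px = sum(m))
  class(out) <- c("roi_stats", "data.frame")
  out
}

#' Line profile through a CT image
#'
#' Samples the image with bilinear interpolation at `n_samples` evenly
#' spaced points along the segment from `p0` to `p1`, returning distances
#' in mm (via the pixel spacing) and CT numbers in HU. Endpoints are given
#' in mm (`_mm`, origin at image centre) or pixels (`(row, col)`).
#'
#' @param img a [ct_image()].
#' @param p0,p1 endpoints: `c(row, col)` in pixels, or with `unit = "mm"`,
#'   `c(x, y)` in mm from the image centre.
#' @param n_samples number of samples along the segment.
#' @param unit `"px"` or `"mm"`.
#' @return data.frame with `distance_mm` and `hu`.
#' @export
line_profile <- function(img, p0, p1, n_samples = 200, unit = c("px", "mm")) {
  stopifnot(inherits(img, "ct_image"), n_samples >= 2)
  unit <- match.arg(unit)
  n_r <- nrow(img$pixels); n_c <- ncol(img$pixels)
  if (unit == "mm") {
    to_px <- function(p) c(p[2] / img$spacing[1] + n_r / 2 + 0.5,
                           p[1] / img$spacing[2] + n_c / 2 + 0.5)
    p0 <- to_px(p0); p1 <- to_px(p1)
  }
  if (any(c(p0, p1) < 1) || p0[1] > n_r || p1[1] > n_r ||
      p0[2] > n_c || p1[2] > n_c)
    stop("profile endpoints must lie inside the image", call. = FALSE)
  t <- seq(0, 1, length.out = n_samples)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(pmax(floor(rr), 1), n_r - 1); c0 <- pmin(pmax(floor(cc), 1), n_c - 1)
  fr <- rr - r0; fc <- cc - c0
  m <- img$pixels
  hu <- (1 - fr) * ((1 - fc) * m[cbind(r0, c0)] + fc * m[cbind(r0, c0 + 1)]) +
    fr * ((1 - fc) * m[cbind(r0 + 1, c0)] + fc * m[cbind(r0 + 1, c0 + 1)])
  dmm <- sqrt(((rr - p0[1]) * img$spacing[1])^2 +
                ((cc - p0[2]) * img$spacing[2])^2)
  data.frame(distance_mm = dmm, hu = hu)
}

#' Write a structured pipeline report
#'
#' Emits a JSON summary (energies chosen, mask areas, fit diagnostics,
#' configuration) plus the cost curve as CSV into a directory, for
#' reproducibility and test assertions.
#'
#' @param result an `rmar_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "rmar_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$report
  rep$config <- unclass(rep$config)
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  if (!result$no_metal)
    write_cost_curve(result$curve, file.path(dir, "cost_curve.csv"))
  invisible(dir)
}
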