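#' Regional quadratic mapping between VMI CT numbers and a material basis
#'
#' In artifact-free pixels, the CT number of the optimal VMI and each
#' material basis density are tightly related; a quadratic polynomial
#' `basis = a0 + a1 HU + a2 HU^2` fitted by ordinary least squares captures
#' that relationship robustly. The fitted model is then evaluated on
#' artifact-region pixels to predict what their basis densities should
#' have been. Evaluation outside the HU range seen during fitting is
#' clamped to the range endpoints: quadratics extrapolate violently, and
#' extreme streak values must not be allowed to blow up the correction.
#'
#' @param vmi0 the optimal VMI, a [ct_image()].
#' @param basis matrix of basis densities (g/cm^3) on the same grid.
#' @param masks a [mask_set()]; fitting uses the artifact-free mask.
#' @param bone_exclude_hu pixels with `vmi0` HU above this are excluded
#'   from fitting (bone and residual metal must not shape the soft-tissue
#'   mapping; at >= 100 keV soft tissue stays below ~100 HU while bone
#'   exceeds 200 HU, hence the 150 HU default).
#' @param target `"water"` or `"bone"` — which basis this model predicts.
#' @return an object of class `mapping_model` with fields `coefficients`
#'   (a0, a1, a2), `target`, `hu_domain`, `n_fit`, `residual_rms`.
#' @export
fit_mapping <- function(vmi0, basis, masks, bone_exclude_hu = 150,
                        target = "water") {
  stopifnot(inherits(vmi0, "ct_image"), inherits(masks, "mask_set"))
  if (!identical(dim(basis), dim(vmi0$pixels)))
    stop("basis grid mismatch", call. = FALSE)
  target <- match.arg(target, c("water", "bone"))
  sel <- masks$artifact_free > 0 & vmi0$pixels <= bone_exclude_hu
  hu <- vmi0$pixels[sel]
  y <- basis[sel]
  n <- length(hu)
  if (n < 100)
    stop(sprintf("only %d artifact-free pixels: refusing to fit (need >= 100)", n),
         call. = FALSE)
  # centred/scaled design for conditioning; coefficients mapped back below
  mu <- mean(hu); s <- stats::sd(hu)
  if (!is.finite(s) || s < 1e-6)
    stop("rank-deficient fit: VMI values in the fitting region are constant",
         call. = FALSE)
  z <- (hu - mu) / s
  X <- cbind(1, z, z^2)
  qr_x <- qr(X)
  if (qr_x$rank < 3)
    stop("rank-deficient quadratic design", call. = FALSE)
  b <- qr.coef(qr_x, y)
  # back-transform: y = b1 + b2 z + b3 z^2, z = (h - mu)/s
  a2 <- b[3] / s^2
  a1 <- b[2] / s - 2 * b[3] * mu / s^2
  a0 <- b[1] - b[2] * mu / s + b[3] * mu^2 / s^2
  res <- y - (a0 + a1 * hu + a2 * hu^2)
  structure(list(coefficients = c(a0 = unname(a0), a1 = unname(a1), a2 = unname(a2)),
                 target = target,
                 hu_domain = range(hu),
                 n_fit = n,
                 residual_rms = sqrt(mean(res^2))),
            class = "mapping_model")
}

#' @export
print.mapping_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<mapping_model:%s> basis = %.4g %+.4g HU %+.4g HU^2\n",
              x$target, co[1], co[2], co[3]))
  cat(sprintf("  fitted on %d px, HU domain [%.1f, %.1f], residual RMS %.4g g/cm^3\n",
              x$n_fit, x$hu_domain[1], x$hu_domain[2], x$residual_rms))
  invisible(x)
}

#' @rdname fit_mapping
#' @param model a fitted `mapping_model`.
#' @param hu numeric vector of VMI CT numbers to map.
#' @return `apply_mapping()` returns predicted basis densities (g/cm^3),
#'   with inputs clamped to the fitted HU domain.
#' @export
apply_mapping <- function(model, hu) {
  stopifnot(inherits(model, "mapping_model"))
  h <- pmin(pmax(hu, model$hu_domain[1]), model$hu_domain[2])
  co <- model$coefficients
  co[1] + co[2] * h + co[3] * h^2
}

#' Serialize / restore a mapping model
#'
#' Writes the coefficients, HU domain and fit diagnostics as a small JSON
#' text file so a correction is reproducible without refitting.
#'
#' @param model a `mapping_model`.
#' @param path JSON file path.
#' @return `write_mapping_model()` returns `path` invisibly;
#'   `read_mapping_model()` returns the restored model.
#' @export
write_mapping_model <- function(model, path) {
  stopifnot(inherits(model, "mapping_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping_model
#' @export
read_mapping_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(coefficients = stats::setNames(as.numeric(x$coefficients),
                                                c("a0", "a1", "a2")),
                 target = x$target, hu_domain = as.numeric(x$hu_domain),
                 n_fit = as.integer(x$n_fit),
                 residual_rms = as.numeric(x$residual_rms)),
            class = "mapping_model")
}

#' Correct the artifact regions of the material basis images
#'
#' Assembles the improved basis images: each basis keeps its original
#' values on artifact-free pixels, on bone-excluded pixels (excluded only
#' from fitting, not flagged as artifact), on metal, and outside the body
#' support; on artifact-mask pixels the value is replaced by the regional
#' model evaluated at the optimal VMI's CT number. Changes therefore occur
#' only inside the artifact mask — the correction can never introduce
#' structure elsewhere.
#'
#' @param mbi input [mbi_pair()].
#' @param masks a [mask_set()].
#' @param model_w,model_b fitted `mapping_model`s for water and bone.
#' @param vmi0 the optimal VMI used for fitting.
#' @return the improved [mbi_pair()].
#' @export
correct_mbis <- function(mbi, masks, model_w, model_b, vmi0) {
  stopifnot(inherits(mbi, "mbi_pair"), inherits(masks, "mask_set"),
            inherits(vmi0, "ct_image"))
  if (!identical(dim(mbi$water), dim(vmi0$pixels)) ||
      !identical(dim(mbi$water), dim(masks$artifact)))
    stop("MBI / VMI / mask grids differ", call. = FALSE)
  sel <- masks$artifact > 0
  water <- mbi$water
  bone <- mbi$bone
  if (any(sel)) {
    hu <- vmi0$pixels[sel]
    water[sel] <- apply_mapping(model_w, hu)
    bone[sel] <- apply_mapping(model_b, hu)
  }
  mbi_pair(water, bone, spacing = mbi$spacing)
}
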