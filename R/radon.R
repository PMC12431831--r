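#' Parallel-beam projection and filtered back projection
#'
#' `radon_transform` forward-projects a square image over angles uniformly
#' spaced on `[0, 180)` degrees, returning a sinogram (rows = angles,
#' columns = detector bins, bin spacing = one pixel side). `fbp_reconstruct`
#' inverts a sinogram by ramp-filtered (Ram-Lak) back projection. These are
#' the classic building blocks of interpolation-based metal artifact
#' reduction; the pair is deliberately plain — parallel geometry, bilinear
#' sampling — because the preliminary correction it serves only needs to
#' localise artifacts, not reconstruct diagnostically.
#'
#' Sinogram values are Riemann sums with one-pixel steps, so multiplying by
#' the pixel size converts them into physical line integrals.
#'
#' @param img numeric square matrix (pad non-square images first).
#' @param n_angles number of projection angles over `[0, 180)`.
#' @param n_bins number of detector bins; default covers the image diagonal.
#' @return `radon_transform()`: a list with `values` (n_angles x n_bins
#'   matrix), `angles_deg`, and `bin_spacing` (pixels).
#' @examples
#' disc <- make_phantom(phantom_spec(fov_mm = 64, n_px = 64, primitives = list(
#'   list(shape = "disc", center_mm = c(0, 0), radius_mm = 20,
#'        material = "water", density = 1))))
#' sino <- radon_transform(disc$density, n_angles = 30)
#' rec <- fbp_reconstruct(sino, n = 64)
#' @export
radon_transform <- function(img, n_angles = 180, n_bins = NULL) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img), n_angles >= 2)
  if (is.null(n_bins)) n_bins <- 2L * ceiling(sqrt(2) * nrow(img) / 2) + 1L
  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  list(values = cpp_radon(img, angles, as.integer(n_bins)),
       angles_deg = angles * 180 / pi,
       bin_spacing = 1)
}

# Ram-Lak spatial-domain filter kernel, circularly arranged for an FFT
# convolution of length L (bin spacing tau = 1 pixel).
ramlak_kernel_fft <- function(L) {
  h <- numeric(L)
  h[1] <- 0.25
  k <- seq_len(L %/% 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2)
  h[L + 1 - odd] <- -1 / (pi^2 * odd^2)
  Re(stats::fft(h))
}

#' @rdname radon_transform
#' @param sino a sinogram as returned by `radon_transform()` (or a list with
#'   `values` and `angles_deg`).
#' @param n output image side in pixels.
#' @param window `"ramp"` (pure Ram-Lak, sharpest) or `"hann"`
#'   (Hann-apodized ramp, as scanner reconstruction kernels use to damp
#'   high-frequency streak ripple and noise).
#' @return `fbp_reconstruct()`: an n x n numeric matrix.
#' @export
fbp_reconstruct <- function(sino, n, window = c("ramp", "hann")) {
  window <- match.arg(window)
  values <- sino$values
  angles <- sino$angles_deg * pi / 180
  na <- nrow(values); nb <- ncol(values)
  if (na < 90)
    warning("fewer than 90 angles: reconstruction will be badly undersampled")
  L <- 2L^ceiling(log2(2L * nb))
  H <- ramlak_kernel_fft(L)
  if (window == "hann") {
    f <- c(seq(0, L / 2), seq(L / 2 - 1, 1)) / (L / 2)  # |freq|, cycles/sample*2
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  padded <- matrix(0, L, na)
  padded[seq_len(nb), ] <- t(values)
  filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / L
  q <- t(filt[seq_len(nb), , drop = FALSE])
  bp <- cpp_backproject(q, angles, as.integer(n))
  bp * (pi / na)   # quadrature over [0, pi) with unit bin spacing
}
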