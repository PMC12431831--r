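#' Simulate a dual-layer spectral-CT VMI series with metal artifacts
#'
#' Generates a co-registered pair of VMI series for a digital phantom: an
#' artifact-bearing series and the artifact-free ground truth. The ground
#' truth is the exact monochromatic synthesis from the phantom's true
#' basis images (the same code path the pipeline uses, so it is clean by
#' construction).
#'
#' In `"physics"` mode the artifact series comes from a full polychromatic
#' measurement model: per detector layer, transmitted intensity is the
#' spectrum-weighted sum of `exp(-sum_m mu_m(E) * pathlength_m)` over the
#' energy grid; optional Poisson noise at `photons` counts per bin models
#' photon starvation behind metal (intensities are floored at 0.1 detected
#' photons before the log, so starved rays produce severe but bounded
#' streaks). As on real scanners, each layer then passes through a water
#' beam-hardening calibration: the measured log-signal is mapped through
#' the layer's inverted pure-water response onto the monochromatic water
#' line integral at the layer's mean energy. Pure-water objects therefore
#' reconstruct essentially exactly, while metal — whose attenuation falls
#' much more steeply with energy than water's — is under-corrected and
#' leaves the classic residual hardening and starvation streaks. Each
#' corrected layer sinogram is reconstructed by filtered back projection
#' and treated as a pseudo-monochromatic image at the layer's mean energy;
#' two-point decomposition of the layer pair yields basis images carrying
#' those streaks, and the VMI series synthesized from them shows
#' energy-dependent artifacts — strongest at low keV, exactly as on
#' scanners.
#'
#' `"fast"` mode skips projection physics: it adds to the ground truth an
#' analytic streak field anchored at the metal rods whose amplitude scales
#' as `(m_Ti(E)/m_Ti(140))^gamma`, for cheap unit tests.
#'
#' @param phantom result of [make_phantom()].
#' @param spectra a [spectrum_model()].
#' @param energies_kev VMI energies to synthesize (within table span).
#' @param mode `"physics"` or `"fast"`.
#' @param seed integer seed; the simulation is deterministic given it.
#' @param photons photon count per detector bin (physics mode).
#' @param noise logical; Poisson counting noise on detected intensities.
#' @param n_angles projection angles (physics mode).
#' @param gamma energy-scaling exponent of the fast-mode streak field.
#' @param streak_amp_hu fast-mode streak amplitude at 140 keV, HU.
#' @param hu_cap storage ceiling of the artifact series in HU, emulating
#'   the 12-bit clipped CT number scale of scanner exports.
#' @param table an [atten_table()].
#' @return list: `series` (artifact-bearing [vmi_series()]), `truth`
#'   (ground-truth series), `mbi_true`, `metal`, `layer_images`
#'   (physics mode), `meta` (layer mean energies, starvation counts).
#' @export
simulate_series <- function(phantom, spectra = spectrum_model(),
                            energies_kev = c(70, 80, 100, 120, 140),
                            mode = c("physics", "fast"), seed = 1,
                            photons = 2e5, noise = TRUE, n_angles = 180,
                            gamma = 1.5, streak_amp_hu = 12, hu_cap = 3071,
                            table = atten_table()) {
  mode <- match.arg(mode)
  span <- atten_span(table)
  stopifnot(all(energies_kev >= span[1] & energies_kev <= span[2]))
  truth <- synthesize_series(phantom$mbi_true, energies_kev, table)
  if (mode == "fast") {
    series <- fast_artifact_series(phantom, energies_kev, seed, gamma,
                                   streak_amp_hu, hu_cap, table)
    return(list(series = series, truth = truth, mbi_true = phantom$mbi_true,
                metal = phantom$metal, layer_images = NULL,
                meta = list(mode = "fast")))
  }
  px_cm <- phantom$spacing_mm[1] / 10
  mats <- names(phantom$per_material)
  nb <- 2L * ceiling(sqrt(2) * phantom$spec$n_px / 2) + 1L
  paths <- lapply(mats, function(m)
    radon_transform(phantom$per_material[[m]], n_angles = n_angles,
                    n_bins = nb)$values * px_cm)
  names(paths) <- mats
  e <- spectra$energy_kev
  mu <- lapply(mats, function(m) mass_atten(table, m, e))  # cm^2/g grid
  names(mu) <- mats
  layer_int <- function(w) {
    total <- matrix(0, n_angles, nb)
    for (i in seq_along(e)) {
      if (w[i] < 1e-12) next
      expo <- matrix(0, n_angles, nb)
      for (m in mats) expo <- expo + mu[[m]][i] * paths[[m]]
      total <- total + w[i] * exp(-expo)
    }
    total
  }
  i_low <- layer_int(spectra$w_low)
  i_high <- layer_int(spectra$w_high)
  n_starved <- 0L
  if (noise) {
    res <- with_local_seed(seed, {
      add_noise <- function(ii) {
        counts <- stats::rpois(length(ii), lambda = photons * as.vector(ii))
        matrix(counts, nrow(ii), ncol(ii)) / photons
      }
      list(low = add_noise(i_low), high = add_noise(i_high))
    })
    i_low <- res$low; i_high <- res$high
  }
  floor_i <- 0.1 / photons
  n_starved <- sum(i_low < floor_i) + sum(i_high < floor_i)
  i_low <- pmax(i_low, floor_i)
  i_high <- pmax(i_high, floor_i)
  # water beam-hardening calibration: invert the layer's pure-water
  # polychromatic response, then relinearise at the layer mean energy
  water_linearize <- function(log_sino, w, mean_e) {
    t_cm <- seq(0, 60, by = 0.25)
    l_poly <- vapply(t_cm, function(t)
      -log(sum(w * exp(-mass_atten(table, "water", e) * table$rho_w * t))), 0)
    t_hat <- stats::approx(l_poly, t_cm, xout = pmin(as.vector(log_sino),
                                                     max(l_poly)),
                           rule = 2)$y +
      pmax(as.vector(log_sino) - max(l_poly), 0) /
      (mass_atten(table, "water", spectra$kvp) * table$rho_w)
    matrix(mass_atten(table, "water", mean_e) * table$rho_w * t_hat,
           nrow(log_sino), ncol(log_sino))
  }
  recon_layer <- function(ii, w, mean_e) {
    lin <- water_linearize(-log(ii), w, mean_e)
    sino <- list(values = lin,
                 angles_deg = seq(0, 180, length.out = n_angles + 1)[1:n_angles],
                 bin_spacing = 1)
    mu_hat <- fbp_reconstruct(sino, n = phantom$spec$n_px,
                              window = "hann") / px_cm
    mu_w <- mass_atten(table, "water", mean_e) * table$rho_w
    ct_image(1000 * (mu_hat - mu_w) / mu_w, spacing = phantom$spacing_mm,
             energy_kev = mean_e, provenance = "layer_recon")
  }
  lo_img <- recon_layer(i_low, spectra$w_low, spectra$mean_low)
  hi_img <- recon_layer(i_high, spectra$w_high, spectra$mean_high)
  mbi_hat <- decompose_mbi(lo_img, hi_img, table)
  series <- synthesize_series(mbi_hat, energies_kev, table)
  # emulate scanner 12-bit storage: CT numbers clip at the scale ceiling
  series$images <- lapply(series$images, function(im) {
    im$pixels <- pmin(im$pixels, hu_cap); im
  })
  list(series = series, truth = truth, mbi_true = phantom$mbi_true,
       metal = phantom$metal, layer_images = list(low = lo_img, high = hi_img),
       meta = list(mode = "physics", mean_low = spectra$mean_low,
                   mean_high = spectra$mean_high, n_starved = n_starved,
                   photons = photons))
}

# Analytic streak field for fast mode: bright/dark fans radiating from each
# rod plus a corridor between rod pairs, scaled by the titanium attenuation
# ratio so low-keV slices carry stronger artifacts.
fast_artifact_series <- function(phantom, energies_kev, seed, gamma,
                                 streak_amp_hu, hu_cap, table) {
  n <- phantom$spec$n_px
  px <- phantom$spacing_mm[1]
  coord <- (seq_len(n) - 0.5) * px - phantom$spec$fov_mm / 2
  y <- matrix(coord, n, n); x <- matrix(coord, n, n, byrow = TRUE)
  rods <- Filter(function(p) p$material == "titanium",
                 phantom$spec$primitives)
  field <- matrix(0, n, n)
  phase <- with_local_seed(seed, stats::runif(max(length(rods), 1), 0, 2 * pi))
  for (i in seq_along(rods)) {
    cc <- rods[[i]]$center_mm
    dx <- x - cc[1]; dy <- y - cc[2]
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    field <- field + sin(16 * ang + phase[i]) * exp(-d / 60)
  }
  if (length(rods) >= 2) {
    a <- rods[[1]]$center_mm; b <- rods[[2]]$center_mm
    ab <- b - a; len <- sqrt(sum(ab^2))
    t_par <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len^2
    perp <- abs((x - a[1]) * (-ab[2]) + (y - a[2]) * ab[1]) / len
    field <- field - 1.5 * exp(-(perp / 6)^2) * (t_par > 0 & t_par < 1)
  }
  support <- phantom$mbi_true$water > 0.5
  m140 <- mass_atten(table, "titanium", 140)
  imgs <- lapply(energies_kev, function(e) {
    amp <- streak_amp_hu * (mass_atten(table, "titanium", e) / m140)^gamma
    base <- synthesize_vmi(phantom$mbi_true, e, table)
    base$pixels <- base$pixels + amp * field * support
    base$pixels[phantom$metal > 0] <-
      min(1000 * (mass_atten(table, "titanium", e) * 4.506 /
                    mass_atten(table, "water", e) - 1), hu_cap)
    base
  })
  vmi_series(imgs, energies_kev)
}

#' Regions of interest between the metal rods
#'
#' Places three circular ROIs in the inter-rod artifact zone: one at the
#' midpoint of the two rods and one to each side of it along the
#' perpendicular bisector of the rod axis. Rays traversing both rods are
#' the most heavily hardened and starved, and their back-projected deficit
#' concentrates in exactly this midplane band, so these ROIs sample the
#' strongest streak shading. For a single rod the ROIs sit on a ring
#' around it.
#'
#' @param spec a [phantom_spec()] containing titanium primitives.
#' @param radius_mm ROI radius.
#' @param offset_mm distance of the two flanking ROIs from the midpoint.
#' @return list of `list(center_mm, radius_mm)`.
#' @export
phantom_rois <- function(spec, radius_mm = 7, offset_mm = 16) {
  rods <- Filter(function(p) p$material == "titanium", spec$primitives)
  if (length(rods) >= 2) {
    a <- rods[[1]]$center_mm; b <- rods[[2]]$center_mm
    mid <- (a + b) / 2
    u <- (b - a) / sqrt(sum((b - a)^2))
    perp <- c(-u[2], u[1])
    lapply(list(mid, mid + offset_mm * perp, mid - offset_mm * perp),
           function(cc) list(center_mm = cc, radius_mm = radius_mm))
  } else if (length(rods) == 1) {
    cc <- rods[[1]]$center_mm
    off <- rods[[1]]$radius_mm + 2 * radius_mm
    lapply(list(c(off, 0), c(-off, 0), c(0, off)),
           function(d) list(center_mm = cc + d, radius_mm = radius_mm))
  } else {
    lapply(list(c(0, 0), c(-30, 0), c(30, 0)),
           function(cc) list(center_mm = cc, radius_mm = radius_mm))
  }
}

#' Randomized two-rod phantom specification
#'
#' Draws a random variant of the two-rod solid-water phantom: the rod pair
#' is rotated to a random orientation, its half-separation drawn uniformly
#' from 30-45 mm (around the reference layout's 40 mm), and the pair's
#' midpoint offset up to 12 mm from the phantom centre. Used to exercise
#' the pipeline across implant layouts while keeping the inter-rod streak
#' zone — the structure the evaluation ROIs sample — present in every
#' variant.
#'
#' @param seed integer seed (the spec is deterministic given it).
#' @param n_px image side, pixels.
#' @return a [phantom_spec()].
#' @export
random_rod_phantom_spec <- function(seed, n_px = 256) {
  with_local_seed(seed, {
    theta <- stats::runif(1, 0, 2 * pi)
    half_sep <- stats::runif(1, 30, 45)
    mid <- stats::runif(2, -12, 12)
    u <- c(cos(theta), sin(theta))
    default_phantom_spec(n_px = n_px,
                         rod_centers_mm = rbind(mid - half_sep * u,
                                                mid + half_sep * u))
  })
}

#' Data-driven artifact ROI placement
#'
#' Emulates how a reader places evaluation ROIs "in the artifact": given a
#' simulation with ground truth, the uncorrected low-energy slice is
#' compared against the truth, the signed deviation is averaged over a
#' sliding disc, and the `k` strongest non-overlapping disc positions
#' (well inside the phantom, away from metal) are returned. ROI selection
#' uses only the uncorrected image, so a subsequent correction is judged
#' on ground the selection never saw.
#'
#' @param sim result of [simulate_series()].
#' @param energy_kev slice used for placement (default the lowest energy).
#' @param k number of ROIs.
#' @param radius_mm ROI radius.
#' @param margin_mm keep-out distance from metal and from the support edge.
#' @return list of `list(center_mm, radius_mm)`, strongest first.
#' @export
artifact_rois <- function(sim, energy_kev = NULL, k = 3, radius_mm = 7,
                          margin_mm = 12) {
  if (is.null(energy_kev)) energy_kev <- min(sim$series$energies_kev)
  img <- series_at(sim$series, energy_kev)
  delta <- img$pixels - series_at(sim$truth, energy_kev)$pixels
  n <- nrow(delta)
  px <- img$spacing[1]
  r_px <- radius_mm / px
  disc <- EBImage::makeBrush(2L * ceiling(r_px) + 1L, "disc")
  disc <- disc / sum(disc)
  mean_map <- EBImage::filter2(delta, disc)
  # candidate centres: inside the water region, away from metal and edges
  support <- sim$mbi_true$water > 0.5
  dil <- EBImage::makeBrush(2L * ceiling((radius_mm + margin_mm) / px) + 1L,
                            "disc")
  ok <- EBImage::erode(support, dil) & !EBImage::dilate(sim$metal > 0, dil)
  score <- abs(mean_map)
  score[!ok] <- -Inf
  centers <- list()
  for (i in seq_len(k)) {
    j <- which.max(score)
    rc <- c((j - 1) %% n + 1, (j - 1) %/% n + 1)  # (row, col)
    centers[[i]] <- rc
    # suppress a 2-radius neighbourhood so ROIs do not overlap
    rows <- pmax(1, rc[1] - ceiling(2 * r_px)):pmin(n, rc[1] + ceiling(2 * r_px))
    cols <- pmax(1, rc[2] - ceiling(2 * r_px)):pmin(n, rc[2] + ceiling(2 * r_px))
    score[rows, cols] <- -Inf
  }
  fov <- n * px
  lapply(centers, function(rc)
    list(center_mm = c((rc[2] - 0.5) * px - fov / 2,
                       (rc[1] - 0.5) * px - fov / 2),
         radius_mm = radius_mm))
}

#' Bundled simulation fixtures
#'
#' Three ready-made test cases: (a) `paper_phantom` — the default two-rod
#' solid-water phantom; (b) `no_metal` — the same phantom without rods, a
#' control on which the pipeline must be a no-op; (c) `two_implant` — an
#' asymmetric two-implant layout. Each carries the phantom, evaluation
#' ROIs, and the endpoints of a line profile crossing the artifact
#' corridor.
#'
#' @param n_px image side in pixels.
#' @return named list of fixtures: `phantom`, `rois`, `profile`
#'   (`p0_mm`, `p1_mm`), `ref_hu` (true solid-water CT number).
#' @export
default_fixtures <- function(n_px = 256) {
  solid_hu <- 1000 * 1.015 - 1000   # water basis 1.015, bone 0: 15 HU at all E
  fix <- function(spec) {
    ph <- make_phantom(spec)
    list(phantom = ph, rois = phantom_rois(spec),
         profile = list(p0_mm = c(-80, 0), p1_mm = c(80, 0)),
         ref_hu = solid_hu)
  }
  list(
    paper_phantom = fix(default_phantom_spec(n_px = n_px)),
    no_metal = fix(phantom_spec(n_px = n_px, primitives = list(
      list(shape = "disc", center_mm = c(0, 0), radius_mm = 100,
           material = "water", density = 1.015)))),
    two_implant = fix(phantom_spec(n_px = n_px, primitives = list(
      list(shape = "disc", center_mm = c(0, 0), radius_mm = 100,
           material = "water", density = 1.015),
      list(shape = "disc", center_mm = c(-45, -25), radius_mm = 5,
           material = "titanium", density = 4.506),
      list(shape = "disc", center_mm = c(35, 30), radius_mm = 4,
           material = "titanium", density = 4.506))))
  )
}
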