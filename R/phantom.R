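#' Digital phantom specification
#'
#' Describes a 2D test phantom as a background material plus a painter's
#' list of disc primitives (later primitives overwrite earlier ones).
#' Coordinates are in mm with the origin at the image centre, x to the
#' right (columns) and y downward (rows).
#'
#' The default phantom mirrors a standard MAR test object: a 200 mm
#' diameter solid-water cylinder holding two 10 mm titanium rods placed
#' symmetrically about the centre. Solid water is modelled at
#' 1.015 g/cm^3 — slightly denser than water, which is exactly what makes
#' the decomposed bone basis of real solid-water phantoms come out
#' (slightly) negative; titanium at 4.506 g/cm^3.
#'
#' @param fov_mm field of view (square), mm.
#' @param n_px image side, pixels.
#' @param primitives list of `list(shape = "disc", center_mm = c(x, y),
#'   radius_mm, material, density)`; material is one of `"water"`,
#'   `"bone"`, `"titanium"` (water here means water-equivalent).
#' @param background background material (default `"air"`, density 0).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm = 350, n_px = 256, primitives = list(),
                         background = "air") {
  for (p in primitives) {
    stopifnot(identical(p$shape, "disc"), length(p$center_mm) == 2,
              p$radius_mm > 0, p$density > 0)
    if (sqrt(sum(p$center_mm^2)) + p$radius_mm > fov_mm / 2)
      stop("primitive extends outside the field of view", call. = FALSE)
  }
  structure(list(fov_mm = fov_mm, n_px = as.integer(n_px),
                 primitives = primitives, background = background),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param rod_centers_mm 2x2 matrix (rows = rods) of titanium rod centres.
#' @param rod_radius_mm titanium rod radius, mm (10 mm diameter rods).
#' @param solid_water_density solid-water density, g/cm^3.
#' @return `default_phantom_spec()` returns the two-rod solid-water
#'   phantom spec.
#' @export
default_phantom_spec <- function(n_px = 256, fov_mm = 350,
                                 rod_centers_mm = rbind(c(-40, 0), c(40, 0)),
                                 rod_radius_mm = 5,
                                 solid_water_density = 1.015) {
  prims <- list(list(shape = "disc", center_mm = c(0, 0), radius_mm = 100,
                     material = "water", density = solid_water_density))
  for (i in seq_len(nrow(rod_centers_mm)))
    prims[[length(prims) + 1]] <-
      list(shape = "disc", center_mm = rod_centers_mm[i, ],
           radius_mm = rod_radius_mm, material = "titanium", density = 4.506)
  phantom_spec(fov_mm = fov_mm, n_px = n_px, primitives = prims)
}

# Supersampled rasterisation: per-material coverage-weighted density maps.
rasterize_spec <- function(spec, ss = 4L) {
  n <- spec$n_px
  nss <- n * ss
  px_mm <- spec$fov_mm / n
  # supersample pixel centre coordinates in mm (x = columns, y = rows)
  coord <- (seq_len(nss) - 0.5) * (spec$fov_mm / nss) - spec$fov_mm / 2
  ymat <- matrix(coord, nss, nss)        # rows = y
  xmat <- matrix(coord, nss, nss, byrow = TRUE)
  dens_big <- matrix(0, nss, nss)
  mat_big <- matrix("air", nss, nss)
  if (identical(spec$background, "water")) {
    dens_big[] <- 1.0; mat_big[] <- "water"
  }
  for (p in spec$primitives) {
    inside <- (xmat - p$center_mm[1])^2 + (ymat - p$center_mm[2])^2 <=
      p$radius_mm^2
    dens_big[inside] <- p$density
    mat_big[inside] <- p$material
  }
  idx <- rep(seq_len(n), each = ss)
  shrink <- function(m) rowsum(t(rowsum(m, idx)), idx) / ss^2
  mats <- unique(c("water", as.vector(mat_big)))
  mats <- setdiff(mats, "air")
  per_material <- lapply(mats, function(mm)
    unname(shrink((mat_big == mm) * dens_big)))
  names(per_material) <- mats
  labels_cov <- lapply(c("air", mats), function(mm)
    unname(shrink((mat_big == mm) * 1)))
  lab_idx <- apply(simplify2array(labels_cov), c(1, 2), which.max)
  labels <- matrix(c("air", mats)[lab_idx], n, n)
  list(per_material = per_material, labels = labels,
       density = Reduce(`+`, per_material), px_mm = px_mm)
}

#' Rasterize a phantom specification
#'
#' Paints the primitives onto the pixel grid with area-weighted
#' anti-aliasing (4x supersampling), and derives the ground-truth material
#' basis images: water-equivalent materials contribute their density to
#' the water basis and bone to the bone basis. Metal pixels are flagged in
#' a separate mask, and the ground-truth maps replace metal with the
#' material it displaced (for the default phantom: solid water), mirroring
#' the reference scan of a phantom with all-water insertions.
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (material name per pixel), `density`
#'   (g/cm^3), `per_material` (coverage-weighted density per material),
#'   `mbi_true` (ground-truth [mbi_pair()]), `metal` (binary mask),
#'   `spacing_mm`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ras <- rasterize_spec(spec)
  metal <- matrix(as.integer(ras$labels == "titanium"), spec$n_px, spec$n_px)
  # ground truth: same spec with metal primitives removed
  truth_spec <- spec
  truth_spec$primitives <- Filter(function(p) p$material != "titanium",
                                  spec$primitives)
  tras <- rasterize_spec(truth_spec)
  water_true <- if (is.null(tras$per_material$water))
    matrix(0, spec$n_px, spec$n_px) else tras$per_material$water
  bone_true <- if (is.null(tras$per_material$bone))
    matrix(0, spec$n_px, spec$n_px) else tras$per_material$bone
  list(labels = ras$labels, density = ras$density,
       per_material = ras$per_material,
       mbi_true = mbi_pair(water_true, bone_true,
                           spacing = c(ras$px_mm, ras$px_mm)),
       metal = metal, spacing_mm = c(ras$px_mm, ras$px_mm), spec = spec)
}

#' Dual-layer detection spectrum model
#'
#' A simple parametric stand-in for a dual-layer spectral detector at a
#' given tube potential: a filtered bremsstrahlung fluence shape is split
#' into a low-energy (superficial-layer) and a high-energy (deep-layer)
#' detection weight curve on a 1 keV grid. The split uses a smooth
#' depth-absorption model — the top layer preferentially absorbs
#' low-energy photons — so the low layer's mean energy always sits below
#' the high layer's. `sharpness` narrows both effective spectra around
#' their means; the default keeps residual water beam hardening small
#' while leaving the steep titanium attenuation to generate realistic
#' metal artifacts.
#'
#' @param kvp tube potential, kV (spectrum endpoint).
#' @param e_min lowest modelled energy, keV.
#' @param filtration_cm water-equivalent pre-filtration, cm.
#' @param split_kev energy at which the two layers detect equally.
#' @param split_order steepness of the layer split (larger = sharper
#'   separation of the layer spectra, hence wider-apart effective
#'   energies; the default gives effective energies near 55 and 105 keV,
#'   so the clinical 70-140 keV VMI range brackets neither layer).
#' @return object of class `spectrum_model`: `energy_kev`, `w_low`,
#'   `w_high` (each summing to 1), `mean_low`, `mean_high`, `kvp`.
#' @export
spectrum_model <- function(kvp = 140, e_min = 20, filtration_cm = 4,
                           split_kev = 90, split_order = 10) {
  stopifnot(kvp > e_min, split_order > 0)
  tab <- atten_table()
  e <- seq(e_min, kvp, by = 1)
  fluence <- pmax(kvp - e, 0) / e                       # bremsstrahlung shape
  filt <- exp(-mass_atten(tab, "water", pmin(e, 200)) * filtration_cm)
  base <- fluence * filt
  p_low <- 1 / (1 + (e / split_kev)^split_order)        # top-layer absorption
  w_low <- base * p_low
  w_high <- base * (1 - p_low)
  w_low <- w_low / sum(w_low)
  w_high <- w_high / sum(w_high)
  ml <- sum(w_low * e); mh <- sum(w_high * e)
  stopifnot(ml < mh)
  structure(list(energy_kev = e, w_low = w_low, w_high = w_high,
                 mean_low = ml, mean_high = mh, kvp = kvp),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> %g kV, %g-%g keV; layer means %.1f / %.1f keV\n",
              x$kvp, min(x$energy_kev), max(x$energy_kev),
              x$mean_low, x$mean_high))
  invisible(x)
}

# Run code with a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
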