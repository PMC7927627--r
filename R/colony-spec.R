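#' Marker channel model for the synthetic colony generator
#'
#' Describes how one immunofluorescence channel is painted. `zone_intensities`
#' gives the *nuclear* mean intensity of the marker in each radial fate zone
#' (ordered as `zone_labels` in the colony spec); the cytosolic intensity of
#' the same zone is `zone_intensities / nuc_cyt_ratio`, so `nuc_cyt_ratio` is
#' always nuclear:cytoplasmic. Nuclear markers therefore use ratios > 1,
#' cytoplasmic markers ratios < 1, and `both` a ratio of 1.
#'
#' @param localization one of `"nuclear"`, `"cytoplasmic"`, `"both"`.
#' @param nuc_cyt_ratio nuclear:cytoplasmic intensity ratio (> 0).
#' @param zone_intensities nuclear mean intensity per fate zone.
#' @return a `marker_model` list.
#' @export
marker_model <- function(localization = c("nuclear", "cytoplasmic", "both"),
                         nuc_cyt_ratio = 3, zone_intensities) {
  localization <- match.arg(localization)
  if (!is.numeric(zone_intensities) || any(zone_intensities < 0))
    stopf("zone_intensities must be nonnegative")
  if (!is_scalar_num(nuc_cyt_ratio) || nuc_cyt_ratio <= 0)
    stopf("nuc_cyt_ratio must be > 0")
  structure(list(localization = localization, nuc_cyt_ratio = nuc_cyt_ratio,
                 zone_intensities = as.numeric(zone_intensities)),
            class = "marker_model")
}

#' Noise model for rendered fluorescence images
#'
#' The standard fluorescence noise stack, each term independently switchable:
#' shot noise `Poisson(photon_gain * signal) / photon_gain` (disabled when
#' `photon_gain = 0`), additive `background_level`, Gaussian read noise of
#' standard deviation `gaussian_sd`, and a linear left-to-right illumination
#' gradient of amplitude `illumination_gradient_fraction` about unity.
#'
#' @param background_level additive offset (counts).
#' @param photon_gain photons per count; 0 disables shot noise.
#' @param gaussian_sd read-noise standard deviation (counts).
#' @param illumination_gradient_fraction relative gradient amplitude in `[0, 1)`.
#' @return a `noise_model` list.
#' @export
noise_model <- function(background_level = 10, photon_gain = 0.5,
                        gaussian_sd = 5, illumination_gradient_fraction = 0.1) {
  stopifnot(background_level >= 0, photon_gain >= 0, gaussian_sd >= 0,
            illumination_gradient_fraction >= 0,
            illumination_gradient_fraction < 1)
  structure(list(background_level = background_level,
                 photon_gain = photon_gain, gaussian_sd = gaussian_sd,
                 illumination_gradient_fraction = illumination_gradient_fraction),
            class = "noise_model")
}

#' Noise-free rendering
#' @return a [noise_model()] with every term switched off.
#' @export
noise_off <- function() noise_model(0, 0, 0, 0)

#' Noise at a stated signal-to-noise ratio
#'
#' SNR is defined as nuclear signal amplitude over Gaussian read-noise sd;
#' shot noise and gradient are left off so the SNR is exact. The default
#' background sits three noise standard deviations above zero, as camera
#' offsets do, so that negative excursions are not clipped at zero (which
#' would bias the non-zero-pixel averaging convention in dim regions).
#'
#' @param snr target signal-to-noise ratio.
#' @param amplitude nuclear signal amplitude the SNR refers to.
#' @param background_level additive background; default `3 * amplitude/snr`.
#' @export
noise_snr <- function(snr, amplitude = 150,
                      background_level = 3 * amplitude / snr) {
  noise_model(background_level = background_level, photon_gain = 0,
              gaussian_sd = amplitude / snr,
              illumination_gradient_fraction = 0)
}

default_marker_models <- function() {
  list(
    T     = marker_model("nuclear", 3, c(150, 15, 15)),
    SOX17 = marker_model("nuclear", 3, c(15, 150, 15)),
    SOX2  = marker_model("nuclear", 3, c(15, 15, 150)))
}

#' Specification of a synthetic micropatterned colony
#'
#' Defines the study conditions the generator emulates: colony geometry
#' (default a circle of area equal to a 1000 µm diameter circle), seeding
#' density 4444 cells/mm², radial fate zones measured from the colony edge
#' (defaults: a T+ mesoendoderm band within 50 µm, a SOX17+ endoderm band at
#' 50–100 µm, SOX2+ prospective neuroepithelium inside), nuclear geometry,
#' marker localization models, an optional circumferential prospective
#' folding axis with oriented linear cables, and the noise stack.
#'
#' @param shape colony outline: circle, square, triangle, rectangle, annulus.
#' @param equivalent_diameter diameter (µm) of the equal-area circle; > 0.
#' @param cell_density nuclei per mm²; >= 0.
#' @param pixel_size µm per pixel (default 0.624, so a 5 px disk is 3.12 µm).
#' @param zone_boundaries strictly increasing distances from the colony edge
#'   (µm) delimiting fate zones; must stay below `equivalent_diameter / 2`.
#' @param zone_labels one fate label per zone (`length(zone_boundaries) + 1`).
#' @param nuc_radius_mean,nuc_radius_sd nuclear radius distribution (µm).
#' @param touching_fraction fraction of nuclei placed as touching pairs
#'   (centroid separation 1.2 x radius) in `[0, 1]`.
#' @param marker_models named list of [marker_model()]s, one image channel each.
#' @param folding_axis_offset distance of the prospective folding axis from
#'   the colony edge (µm); used when `cable_spec` is given.
#' @param cable_spec `NULL`, or a list with `n_cables`, `length_range` (µm),
#'   `angles` (degrees relative to the folding-axis tangent, sampled
#'   uniformly from this vector), `angle_jitter_sd` (degrees), `band_um`
#'   (radial scatter of cable midpoints about the axis, so distinct cables
#'   do not collinearly merge) and optionally `intensity`, `width_px`,
#'   `channel`.
#' @param noise a [noise_model()].
#' @param annulus_inner_fraction inner/outer radius for `shape = "annulus"`.
#' @param margin_um background margin around the colony in the rendered image.
#' @param dapi_amplitude peak amplitude of rendered nuclei in the DAPI channel.
#' @param seed integer RNG seed; the generator is deterministic given the spec.
#' @return a validated `colony_spec` object.
#' @examples
#' spec <- colony_spec(equivalent_diameter = 240, cell_density = 4444, seed = 1)
#' @export
colony_spec <- function(shape = c("circle", "square", "triangle", "rectangle",
                                  "annulus"),
                        equivalent_diameter = 1000,
                        cell_density = 4444,
                        pixel_size = 0.624,
                        zone_boundaries = c(50, 100),
                        zone_labels = c("T", "SOX17", "SOX2"),
                        nuc_radius_mean = 3.5,
                        nuc_radius_sd = 0.35,
                        touching_fraction = 0,
                        marker_models = default_marker_models(),
                        folding_axis_offset = 200,
                        cable_spec = NULL,
                        noise = noise_model(),
                        annulus_inner_fraction = 0.5,
                        margin_um = 40,
                        dapi_amplitude = 150,
                        seed = 1L) {
  shape <- match.arg(shape)
  if (!is_scalar_num(equivalent_diameter) || equivalent_diameter <= 0)
    stopf("equivalent_diameter must be > 0")
  if (!is_scalar_num(cell_density) || cell_density < 0)
    stopf("cell_density must be >= 0")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0")
  if (length(zone_boundaries)) {
    if (any(diff(zone_boundaries) <= 0) || any(zone_boundaries <= 0))
      stopf("zone_boundaries must be strictly increasing and positive")
    if (any(zone_boundaries >= equivalent_diameter / 2))
      stopf("zone_boundaries must lie below equivalent_diameter / 2")
  }
  if (length(zone_labels) != length(zone_boundaries) + 1L)
    stopf("need %d zone_labels for %d zone_boundaries",
          length(zone_boundaries) + 1L, length(zone_boundaries))
  if (touching_fraction < 0 || touching_fraction > 1)
    stopf("touching_fraction must be in [0, 1]")
  if (nuc_radius_mean <= 0) stopf("nuc_radius_mean must be > 0")
  if (!is.list(marker_models) ||
      (length(marker_models) && is.null(names(marker_models))))
    stopf("marker_models must be a named list of marker_model objects")
  for (nm in names(marker_models)) {
    mm <- marker_models[[nm]]
    if (!inherits(mm, "marker_model"))
      stopf("marker_models[['%s']] is not a marker_model", nm)
    if (length(mm$zone_intensities) != length(zone_labels))
      stopf("marker '%s' needs %d zone intensities", nm, length(zone_labels))
  }
  if (!inherits(noise, "noise_model")) stopf("noise must be a noise_model")
  if (!is.null(cable_spec)) {
    cable_spec <- utils::modifyList(
      list(n_cables = 50L, length_range = c(15, 30), angles = 90,
           angle_jitter_sd = 0, intensity = 200, width_px = 2,
           band_um = 40, channel = "ppMLC"), cable_spec)
    if (folding_axis_offset <= 0 ||
        folding_axis_offset >= equivalent_diameter / 2)
      stopf("folding_axis_offset must lie inside the colony")
  }
  structure(list(shape = shape, equivalent_diameter = equivalent_diameter,
                 cell_density = cell_density, pixel_size = pixel_size,
                 zone_boundaries = as.numeric(zone_boundaries),
                 zone_labels = as.character(zone_labels),
                 nuc_radius_mean = nuc_radius_mean,
                 nuc_radius_sd = nuc_radius_sd,
                 touching_fraction = touching_fraction,
                 marker_models = marker_models,
                 folding_axis_offset = folding_axis_offset,
                 cable_spec = cable_spec, noise = noise,
                 annulus_inner_fraction = annulus_inner_fraction,
                 margin_um = margin_um, dapi_amplitude = dapi_amplitude,
                 seed = as.integer(seed)),
            class = "colony_spec")
}

#' @export
print.colony_spec <- function(x, ...) {
  cat(sprintf("<colony_spec> %s, equivalent diameter %g µm, %g cells/mm²\n",
              x$shape, x$equivalent_diameter, x$cell_density))
  cat(sprintf("zones from edge: %s -> %s\n",
              paste(x$zone_boundaries, collapse = "/"),
              paste(x$zone_labels, collapse = ", ")))
  cat(sprintf("markers: %s; seed %d\n",
              paste(names(x$marker_models), collapse = ", "), x$seed))
  invisible(x)
}
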