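#' Specification of a synthetic tissue cross-section
#'
#' Describes a 2D side view (x-z plane) of a folding epithelial layer the way
#' optical cross-sections through the tissue hinge are quantified: a flat
#' basal and apical surface bounding one cell layer, columnar cells drawn as
#' trapezoids whose basal:apical width ratio is `wedge_ratio` inside the
#' hinge region and 1 outside, elongated nuclei with region-specific aspect
#' ratios, and mitotic (PH3+) nuclei placed apically with probability
#' `ph3_apical_bias`.
#'
#' @param width lateral extent of the section (µm).
#' @param layer_thickness apical-basal cell height (µm).
#' @param basal_margin background below/above the layer (µm).
#' @param pixel_size µm per pixel.
#' @param n_cells number of cells across the section.
#' @param hinge_range x-range of the hinge as fractions of `width`.
#' @param wedge_ratio basal:apical cell width in the hinge (1 = no wedging).
#' @param aspect_hinge,aspect_flank mean nuclear aspect ratio (major/minor)
#'   inside and outside the hinge.
#' @param aspect_jitter_sd multiplicative jitter (sd, mean 1) on aspect ratios.
#' @param nuc_minor_radius nuclear minor semi-axis (µm).
#' @param ph3_fraction fraction of PH3+ (mitotic) nuclei.
#' @param ph3_apical_bias probability that a PH3+ nucleus sits apically.
#' @param noise a [noise_model()].
#' @param dapi_amplitude peak nuclear amplitude in the DAPI channel.
#' @param seed integer RNG seed.
#' @return a `cross_section_spec` object.
#' @export
cross_section_spec <- function(width = 300, layer_thickness = 50,
                               basal_margin = 15, pixel_size = 0.624,
                               n_cells = 30, hinge_range = c(1 / 3, 2 / 3),
                               wedge_ratio = 1, aspect_hinge = 2.5,
                               aspect_flank = 1.2, aspect_jitter_sd = 0.05,
                               nuc_minor_radius = 2.5, ph3_fraction = 0.15,
                               ph3_apical_bias = 0.8, noise = noise_model(),
                               dapi_amplitude = 150, seed = 1L) {
  stopifnot(width > 0, layer_thickness > 0, basal_margin >= 0, pixel_size > 0,
            n_cells >= 1, wedge_ratio > 0, aspect_hinge >= 1,
            aspect_flank >= 1, nuc_minor_radius > 0,
            ph3_fraction >= 0, ph3_fraction <= 1,
            ph3_apical_bias >= 0, ph3_apical_bias <= 1)
  if (hinge_range[1] < 0 || hinge_range[2] > 1 ||
      hinge_range[1] >= hinge_range[2])
    stopf("hinge_range must be an increasing pair of fractions in [0, 1]")
  structure(as.list(environment()), class = "cross_section_spec")
}

# Rotated anisotropic Gaussian blob truncated at the ellipse outline
# (semi-axes a >= b, orientation in degrees from the +x axis).
add_ellipse_blob <- function(m, cx, cy, a, b, orientation_deg, amplitude,
                             pixel_size, flat = FALSE) {
  H <- nrow(m); W <- ncol(m)
  wr <- ceiling(a / pixel_size) + 1L
  jc <- floor(cx / pixel_size); ic <- floor(cy / pixel_size)
  j0 <- max(0L, jc - wr); j1 <- min(W - 1L, jc + wr)
  i0 <- max(0L, ic - wr); i1 <- min(H - 1L, ic + wr)
  if (j0 > j1 || i0 > i1) return(m)
  xs <- px_centers_um(W, pixel_size)[(j0 + 1L):(j1 + 1L)] - cx
  ys <- px_centers_um(H, pixel_size)[(i0 + 1L):(i1 + 1L)] - cy
  th <- orientation_deg * pi / 180
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  U <- X * cos(th) + Y * sin(th)       # along major axis
  V <- -X * sin(th) + Y * cos(th)
  Q <- (U / a)^2 + (V / b)^2
  inside <- Q <= 1
  g <- if (flat) amplitude * inside else amplitude * exp(-2 * Q) * inside
  ri <- (i0 + 1L):(i1 + 1L); rj <- (j0 + 1L):(j1 + 1L)
  m[ri, rj] <- m[ri, rj] + g
  m
}

#' Generate a synthetic cross-section image with ground truth
#'
#' Renders a DAPI channel (elongated nuclei) and a PH3 channel (flat disks at
#' mitotic nuclei) of the side view described by the spec. Ground truth
#' carries cell polygons with exact basal:apical length ratios, per-nucleus
#' aspect ratios and orientations, PH3/apical flags, the apical and basal
#' surface polylines and the layer mask. Coordinates in ground truth use
#' z-up micrometres (`z = 0` at the image bottom); the `y_img` column gives
#' the corresponding image y (downward) in µm.
#'
#' @param spec a [cross_section_spec()].
#' @return list of class `cross_section_sim` with `image` and `truth`.
#' @export
generate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "cross_section_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size
    basal_z <- spec$basal_margin
    apical_z <- basal_z + spec$layer_thickness
    Hum <- apical_z + spec$basal_margin
    W <- as.integer(ceiling(spec$width / px))
    H <- as.integer(ceiling(Hum / px))
    n <- spec$n_cells

    mid_frac <- (seq_len(n) - 0.5) / n
    hinge <- mid_frac >= spec$hinge_range[1] & mid_frac <= spec$hinge_range[2]
    # hinge cells are wedged (basal = wedge_ratio x apical at constant
    # mid-height pitch); flank cells absorb the excess so both surfaces
    # span exactly [0, width] -- the flanks of a fold tilt the other way
    w <- spec$wedge_ratio
    pitch <- spec$width / n
    n_h <- sum(hinge); n_f <- n - n_h
    a_h <- pitch * 2 / (1 + w)
    a_f <- if (n_f > 0) (spec$width - n_h * a_h) / n_f else 0
    q <- if (n_f > 0) (spec$width - n_h * a_h * w) / (n_f * a_f) else 1
    wa <- ifelse(hinge, a_h, a_f)
    wb <- ifelse(hinge, a_h * w, a_f * q)
    a_pos <- c(0, cumsum(wa)); b_pos <- c(0, cumsum(wb))

    polys <- vector("list", n)
    cells <- data.frame(id = seq_len(n),
                        apical_length = wa, basal_length = wb,
                        basal_apical_ratio = wb / wa,
                        region = ifelse(hinge, "hinge", "flank"))
    for (i in seq_len(n)) {
      polys[[i]] <- data.frame(
        x = c(a_pos[i], a_pos[i + 1L], b_pos[i + 1L], b_pos[i]),
        z = c(apical_z, apical_z, basal_z, basal_z))
    }

    aspect_mean <- ifelse(hinge, spec$aspect_hinge, spec$aspect_flank)
    aspect <- pmax(1, aspect_mean *
                     (1 + rnorm(n, 0, spec$aspect_jitter_sd)))
    minor_r <- spec$nuc_minor_radius
    major_r <- aspect * minor_r
    ph3 <- runif(n) < spec$ph3_fraction
    apical_side <- ifelse(ph3, runif(n) < spec$ph3_apical_bias, NA)
    frac_z <- ifelse(ph3, ifelse(apical_side, 0.75, 0.25), 0.5)
    nx <- (a_pos[-(n + 1L)] + a_pos[-1L] + b_pos[-(n + 1L)] + b_pos[-1L]) / 4
    # keep the ellipse inside the layer
    zmax_off <- spec$layer_thickness / 2 - major_r
    nz <- basal_z + pmin(pmax(frac_z * spec$layer_thickness,
                              major_r + 0.5),
                         spec$layer_thickness - major_r - 0.5)
    nz <- pmax(basal_z + major_r, pmin(nz, apical_z - major_r))

    dapi <- matrix(0, H, W); ph3ch <- matrix(0, H, W)
    y_img <- H * px - nz
    for (i in seq_len(n)) {
      dapi <- add_ellipse_blob(dapi, nx[i], y_img[i], major_r[i], minor_r,
                               90, spec$dapi_amplitude, px)
      if (ph3[i])
        ph3ch <- add_ellipse_blob(ph3ch, nx[i], y_img[i], minor_r, minor_r,
                                  0, spec$dapi_amplitude, px, flat = TRUE)
    }
    layer_mask <- matrix(0, H, W)
    zs <- H * px - px_centers_um(H, px)    # z of each row
    layer_rows <- zs >= basal_z & zs <= apical_z
    layer_mask[layer_rows, ] <- 1

    channels <- lapply(list(DAPI = dapi, PH3 = ph3ch), apply_noise,
                       noise = spec$noise)
    image <- image_stack(channels, pixel_size = px)

    nuclei <- data.frame(
      id = seq_len(n), x = nx, z = nz, y_img = y_img,
      major_axis = 2 * major_r, minor_axis = 2 * minor_r,
      orientation = rep(90, n), aspect_ratio = aspect,
      region = ifelse(hinge, "hinge", "flank"),
      ph3_positive = ph3, apical_side = apical_side)

    truth <- structure(list(
      nuclei = nuclei, cells = cells, cell_polygons = polys,
      apical_surface = data.frame(x = c(0, spec$width),
                                  z = c(apical_z, apical_z)),
      basal_surface = data.frame(x = c(0, spec$width),
                                 z = c(basal_z, basal_z)),
      layer_mask = layer_mask, spec = spec), class = "ground_truth")
    structure(list(image = image, truth = truth),
              class = "cross_section_sim")
  })
}
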