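# Nuclei segmentation reproducing the classical chain: local contrast
# equalization -> adaptive (Wiener) noise filter -> global Otsu threshold ->
# binary cleanup (opening, minimum-area filter) -> distance-transform-seeded
# watershed -> labeling -> moment-based ellipse geometry.

ebi <- function(m) EBImage::Image(t(m))
unebi <- function(img) t(EBImage::imageData(img))

#' Segmentation settings
#'
#' @param nuclei_channel channel holding the nuclei stain.
#' @param clahe apply local contrast equalization first.
#' @param clahe_tiles CLAHE tile grid (per side).
#' @param wiener apply the adaptive Wiener noise filter.
#' @param wiener_size filter window (odd, px).
#' @param opening_radius_px radius of the morphological opening brush.
#' @param expected_radius_um expected nuclear radius, used for the default
#'   minimum-area cutoff and watershed seed separation.
#' @param min_area_fraction minimum object area as a fraction of the expected
#'   nucleus area.
#' @param watershed split merged blobs by distance-transform watershed.
#' @param watershed_tolerance minimum height (px) of a watershed-surface
#'   object before it is merged into a neighbor.
#' @param watershed_intensity_weight weight (px per normalized intensity
#'   unit) of the image-intensity term added to the distance-transform
#'   watershed surface; touching nuclei dim at their contact interface, so
#'   this deepens the splitting saddle. 0 recovers a pure distance watershed.
#' @param watershed_ext seed-detection neighborhood radius (px); must stay
#'   below half the minimum centroid separation or the weaker of two touching
#'   nuclei is suppressed as a seed.
#' @param guard_k blank-image guard: foreground/background mean separation
#'   must exceed `guard_k` background standard deviations.
#' @param max_fg_fraction blank-image guard: maximum foreground fraction.
#' @return list of settings for [segment_nuclei()].
#' @export
seg_params <- function(nuclei_channel = "DAPI", clahe = TRUE,
                       clahe_tiles = 4L, wiener = TRUE, wiener_size = 5L,
                       opening_radius_px = 2L, expected_radius_um = 3.5,
                       min_area_fraction = 0.25, watershed = TRUE,
                       watershed_tolerance = 0.3, watershed_ext = 1L,
                       watershed_intensity_weight = 3,
                       guard_k = 3, max_fg_fraction = 0.6) {
  as.list(environment())
}

# Adaptive Wiener filter (local mean/variance shrinkage), the standard
# adaptive noise-reduction step for microscopy images.
wiener_filter <- function(m, size = 5L) {
  k <- matrix(1 / (size * size), size, size)
  mu <- unebi(EBImage::filter2(ebi(m), k))
  mu2 <- unebi(EBImage::filter2(ebi(m * m), k))
  v <- pmax(mu2 - mu * mu, 0)
  nu <- mean(v)
  mu + (pmax(v - nu, 0) / pmax(v, nu)) * (m - mu)
}

empty_nucleus_records <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0),
             area = numeric(0), major_axis = numeric(0),
             minor_axis = numeric(0), orientation = numeric(0),
             aspect_ratio = numeric(0))
}

#' Segment nuclei from the nuclei channel
#'
#' Runs the fixed processing chain (contrast equalization, adaptive noise
#' filter, global automatic threshold, opening and minimum-area cleanup,
#' distance-transform-seeded watershed splitting of merged blobs) and returns
#' a label image plus one geometry record per nucleus from an ellipse fit
#' with matched second moments. A blank image (no credible foreground)
#' yields an empty result, not an error.
#'
#' @param image an [image_stack()] containing the nuclei channel.
#' @param params settings from [seg_params()].
#' @return list with `labels` (integer matrix, background 0) and `records`
#'   (data.frame: id, x, y (µm), area (µm²), major_axis, minor_axis (µm),
#'   orientation (degrees in `[0, 180)`), aspect_ratio).
#' @examples
#' sim <- generate_colony(colony_spec(equivalent_diameter = 120,
#'   cell_density = 1500, noise = noise_off(), zone_boundaries = numeric(0),
#'   zone_labels = "SOX2", marker_models = list(), seed = 2))
#' seg <- segment_nuclei(sim$image)
#' nrow(seg$records)
#' @export
segment_nuclei <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "image_stack"))
  m <- get_channel(image, params$nuclei_channel)
  px <- image$pixel_size
  rng <- range(m)
  empty <- list(labels = matrix(0L, nrow(m), ncol(m)),
                records = empty_nucleus_records())
  if (diff(rng) <= 0) return(empty)
  mn <- (m - rng[1]) / diff(rng)

  f <- mn
  if (isTRUE(params$clahe)) {
    tile <- max(2L, as.integer(params$clahe_tiles))
    # CLAHE requires dimensions divisible by the tile grid: pad by edge
    # replication, equalize, crop back
    H <- nrow(f); W <- ncol(f)
    Hp <- tile * ceiling(H / tile); Wp <- tile * ceiling(W / tile)
    fp <- f[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)),
            drop = FALSE]
    fp <- unebi(EBImage::clahe(ebi(fp), nx = tile, ny = tile))
    f <- fp[seq_len(H), seq_len(W), drop = FALSE]
  }
  if (isTRUE(params$wiener)) f <- wiener_filter(f, params$wiener_size)

  th <- EBImage::otsu(ebi(f), range = range(f))
  mask <- f > th
  # blank-image guard: demand genuine bimodal separation, otherwise declare
  # the image background-only (Otsu on pure noise splits at the mean).
  # Judged on the noise-filtered raw image: CLAHE stretches background
  # noise to full range, which would mask the absence of signal
  g <- if (isTRUE(params$clahe)) wiener_filter(mn, params$wiener_size)
       else f
  fg <- g[mask]; bg <- g[!mask]
  if (!length(fg) || mean(mask) > params$max_fg_fraction ||
      (length(bg) > 1 &&
       (mean(fg) - mean(bg)) <= params$guard_k * stats::sd(bg)))
    return(empty)

  br <- EBImage::makeBrush(2L * params$opening_radius_px + 1L, shape = "disc")
  bw <- EBImage::opening(ebi(mask * 1), br)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  r_px <- params$expected_radius_um / px
  min_area <- params$min_area_fraction * pi * r_px^2
  areas <- table(lab[lab > 0])
  drop <- as.integer(names(areas)[areas < min_area])
  if (length(drop)) lab <- EBImage::rmObjects(lab, drop, reenumerate = TRUE)
  if (max(lab) == 0) return(empty)

  if (isTRUE(params$watershed)) {
    ext <- params$watershed_ext %||% max(1L, round(r_px / 2))
    dm <- EBImage::distmap(lab > 0)
    # distance-transform surface augmented with the (normalized) filtered
    # intensity: touching nuclei dip in brightness at the contact interface,
    # which deepens the saddle the distance map alone may miss
    fn <- (f - min(f)) / max(diff(range(f)), .Machine$double.eps)
    surf <- dm + params$watershed_intensity_weight * ebi(fn) * (dm > 0)
    lab <- EBImage::watershed(surf, tolerance = params$watershed_tolerance,
                              ext = ext)
  }

  # intensity-weighted moments (on the raw normalized channel) give
  # subpixel centroids and unbiased axis ratios; binary moments
  # overestimate the minor axis of small nuclei by a sizeable fraction
  # of a pixel
  mom <- EBImage::computeFeatures.moment(lab, ref = ebi(mn))
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1,
                                       dimnames = list(NULL, names(shp)))
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(1 - mom[, "m.eccentricity"]^2, 0))
  records <- data.frame(
    id = seq_len(nrow(mom)),
    x = (mom[, "m.cx"] - 0.5) * px,
    y = (mom[, "m.cy"] - 0.5) * px,
    area = shp[, "s.area"] * px^2,
    major_axis = major * px,
    minor_axis = minor * px,
    orientation = (-mom[, "m.theta"] * 180 / pi) %% 180,
    aspect_ratio = ifelse(minor > 0, major / minor, NA_real_))
  rownames(records) <- NULL
  list(labels = matrix(as.integer(unebi(lab)), nrow(m), ncol(m)),
       records = records)
}

#' Nuclear aspect-ratio summary
#'
#' Aspect ratio is major/minor of the moment-matched ellipse per nucleus;
#' summarized over the optional region of interest.
#'
#' @param records nucleus records from [segment_nuclei()] (or ground truth).
#' @param roi optional polygon (µm) restricting the summary.
#' @return list with `mean`, `sem` (NA when n < 2), `n`.
#' @export
nuclear_aspect_ratios <- function(records, roi = NULL) {
  if (!is.null(roi)) {
    keep <- points_in_polygon(records$x, records$y, roi)
    records <- records[keep, , drop = FALSE]
  }
  ar <- records$aspect_ratio[is.finite(records$aspect_ratio)]
  if (!length(ar)) stopf("no nuclei left after ROI filtering")
  list(mean = mean(ar), sem = sem(ar), n = length(ar))
}
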